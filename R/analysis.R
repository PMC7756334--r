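.as_frames <- function(trajectory) {
  if (inherits(trajectory, "md_run")) trajectory$trajectory else trajectory
}

#' Radial distribution function
#'
#' Histograms minimum-image pair distances between two atom selections over
#' trajectory frames and normalizes per frame by the ideal-gas shell count
#' `N_a N_b 4 pi r^2 dr / V` (unordered pairs, self-pairs excluded when the
#' selections coincide).
#'
#' @param trajectory An `md_run` or list of frames (each with `positions` and
#'   `box`).
#' @param selection_a,selection_b Atom index vectors (1-based).
#' @param bin_width Bin width, nm.
#' @param r_max Histogram range, nm (at most half the smallest box edge).
#' @return Object of class `binned_curve`: data frame with `r` (bin centres),
#'   `value` (g(r)) and `count`; empty bins carry `NA`.
#' @export
rdf <- function(trajectory, selection_a, selection_b = selection_a,
                bin_width = 0.01, r_max = NULL) {
  frames <- .as_frames(trajectory)
  stopifnot(length(frames) > 0)
  half_box <- min(sapply(frames, function(f) min(f$box))) / 2
  if (is.null(r_max)) r_max <- half_box
  if (r_max > half_box + 1e-9)
    stop("r_max exceeds half the smallest box edge")
  nb <- floor(r_max / bin_width + 1e-9)
  same <- length(selection_a) == length(selection_b) &&
    all(sort(selection_a) == sort(selection_b))
  counts <- numeric(nb)
  ideal <- numeric(nb)
  rc <- (seq_len(nb) - 0.5) * bin_width
  for (f in frames) {
    counts <- counts + cpp_pair_hist(f$positions, selection_a - 1L,
                                     selection_b - 1L, same, f$box,
                                     bin_width, nb)
    v <- prod(f$box)
    npair <- if (same) length(selection_a) * (length(selection_a) - 1) / 2
             else length(selection_a) * length(selection_b)
    ideal <- ideal + npair * 4 * pi * rc^2 * bin_width / v
  }
  g <- ifelse(ideal > 0 & counts >= 0, counts / ideal, NA_real_)
  g[counts == 0 & ideal == 0] <- NA_real_
  structure(data.frame(r = rc, value = g, count = counts),
            kind = "rdf", bin_width = bin_width,
            class = c("binned_curve", "data.frame"))
}

# Dipole unit vectors and dipole-centre sites for each molecule of a frame.
.molecular_dipoles <- function(positions, charges, molecule_id) {
  mols <- sort(unique(molecule_id))
  mu <- matrix(0, length(mols), 3)
  for (k in seq_along(mols)) {
    idx <- which(molecule_id == mols[k])
    p <- positions[idx, , drop = FALSE]
    ctr <- colMeans(p)
    m <- colSums(charges[idx] * sweep(p, 2, ctr))
    nrm <- sqrt(sum(m^2))
    if (nrm == 0) stop("apolar molecule in dipole selection")
    mu[k, ] <- m / nrm
  }
  mu
}

#' Dipole-dipole orientation correlation function
#'
#' `C(r)` is the average over frames and molecule pairs of the cosine between
#' molecular dipole directions, binned by the minimum-image distance between
#' designated molecular sites (water oxygens by default; falls back to the
#' molecular centre of geometry).  The dipole of a molecule is the unit vector
#' of `sum q_k (r_k - r_center)`.
#'
#' @inheritParams rdf
#' @param system The [md_system()] the frames belong to (charges, molecules).
#' @param site_name Atom name used as the distance site (default `"OW"`).
#' @return A `binned_curve` with `value` = C(r) in [-1, 1].
#' @export
dipole_correlation <- function(trajectory, system, bin_width = 0.01,
                               r_max = NULL, site_name = "OW") {
  frames <- .as_frames(trajectory)
  stopifnot(length(frames) > 0)
  half_box <- min(sapply(frames, function(f) min(f$box))) / 2
  if (is.null(r_max)) r_max <- half_box
  if (r_max > half_box + 1e-9) stop("r_max exceeds half the smallest box edge")
  nb <- floor(r_max / bin_width + 1e-9)
  mols <- sort(unique(system$molecule_id))
  site_idx <- vapply(mols, function(m) {
    idx <- which(system$molecule_id == m)
    hit <- idx[system$name[idx] == site_name]
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  sums <- numeric(nb); counts <- numeric(nb)
  for (f in frames) {
    mu <- .molecular_dipoles(f$positions, system$charges, system$molecule_id)
    sites <- if (anyNA(site_idx)) {
      t(vapply(mols, function(m)
        colMeans(f$positions[system$molecule_id == m, , drop = FALSE]),
        numeric(3)))
    } else f$positions[site_idx, , drop = FALSE]
    acc <- cpp_dipole_corr_hist(sites, mu, f$box, bin_width, nb)
    sums <- sums + acc$sums
    counts <- counts + acc$counts
  }
  val <- ifelse(counts > 0, sums / counts, NA_real_)
  structure(data.frame(r = (seq_len(nb) - 0.5) * bin_width, value = val,
                       count = counts),
            kind = "dcf", bin_width = bin_width,
            class = c("binned_curve", "data.frame"))
}

#' Mass-weighted radius of gyration
#'
#' `R_gyr = sqrt( sum m_i (r_i - r_com)^2 / M )`.
#'
#' @param positions N x 3 matrix, nm.
#' @param masses Atomic masses, u.
#' @return nm.
#' @export
radius_of_gyration <- function(positions, masses) {
  positions <- as.matrix(positions)
  if (nrow(positions) == 0) stop("empty selection")
  m <- sum(masses)
  stopifnot(m > 0)
  com <- colSums(positions * masses) / m
  sqrt(sum(masses * rowSums(sweep(positions, 2, com)^2)) / m)
}

#' Least-squares superposition RMSD
#'
#' Kabsch rotation after centring; used as input to [rmsd100()].
#'
#' @param x,y N x 3 coordinate matrices (same atoms, nm).
#' @return RMSD in nm.
#' @export
rmsd_fit <- function(x, y) {
  x <- sweep(as.matrix(x), 2, colMeans(x))
  y <- sweep(as.matrix(y), 2, colMeans(y))
  s <- svd(crossprod(y, x))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((x - y %*% rot)^2)))
}

#' Length-normalized RMSD
#'
#' Normalizes an RMSD to a notional 100-residue chain:
#' `RMSD100 = RMSD / (1 + ln sqrt(n / 100))`.  Below the formula's validity
#' range (denominator <= 0, i.e. fewer than ~14 residues) the result is
#' flagged as `NA` rather than extrapolated.
#'
#' @param rmsd RMSD, nm (>= 0).
#' @param n_residues Chain length in residues (>= 1).
#' @return Normalized RMSD, nm (NA if out of the validity range).
#' @export
rmsd100 <- function(rmsd, n_residues) {
  stopifnot(rmsd >= 0, n_residues >= 1)
  denom <- 1 + log(sqrt(n_residues / 100))
  if (denom <= 0) {
    warning("chain too short for RMSD100 normalization; returning NA")
    return(NA_real_)
  }
  rmsd / denom
}

#' Count hydrogen bonds by the geometric criterion
#'
#' A (donor, hydrogen, acceptor) triple is counted when the acceptor-donor
#' minimum-image distance is below `d_max` and the acceptor-hydrogen-donor
#' angle exceeds `angle_min`.  By default the distance threshold applies to
#' the donor-acceptor separation; set `distance_site = "hydrogen"` for the
#' hydrogen-acceptor variant common with 0.25 nm thresholds.
#'
#' @param frame List with `positions` and `box`.
#' @param donors,hydrogens Parallel index vectors (covalent D-H pairs).
#' @param acceptors Acceptor atom indices.
#' @param d_max Distance threshold, nm.
#' @param angle_min Angle threshold, degrees.
#' @param distance_site `"donor"` (default) or `"hydrogen"`.
#' @return Integer count.
#' @export
count_hbonds <- function(frame, donors, hydrogens, acceptors,
                         d_max = 0.25, angle_min = 120,
                         distance_site = c("donor", "hydrogen")) {
  distance_site <- match.arg(distance_site)
  stopifnot(length(donors) == length(hydrogens))
  pos <- frame$positions; box <- frame$box
  mi <- function(d) d - box * round(d / box)
  count <- 0L
  for (k in seq_along(donors)) {
    d <- donors[k]; h <- hydrogens[k]
    for (a in acceptors) {
      if (a == d || a == h) next
      ref <- if (distance_site == "donor") d else h
      dv <- mi(pos[a, ] - pos[ref, ])
      if (sqrt(sum(dv^2)) >= d_max) next
      v1 <- mi(pos[a, ] - pos[h, ])
      v2 <- mi(pos[d, ] - pos[h, ])
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      if (ang > angle_min) count <- count + 1L
    }
  }
  count
}

#' NOE-style distance average
#'
#' `< r^-3 >^(-1/3)`, the averaging convention for comparing simulated
#' interproton distances with NOE upper bounds; weights short distances
#' heavily, so the result never exceeds the arithmetic mean.
#'
#' @param distance_series Positive distances, nm.
#' @return Averaged distance, nm.
#' @export
noe_average <- function(distance_series) {
  if (length(distance_series) == 0) stop("empty distance series")
  if (any(distance_series <= 0)) stop("distances must be positive")
  mean(distance_series^-3)^(-1 / 3)
}

#' Per-bath temperature series from an energy log
#'
#' Extracts the solute / solvent temperature series of a run's energy log and
#' summarizes them over an analysis window.
#'
#' @param energy_log Data frame from [run_simulation()] (`$energy`), needing
#'   `time`, `t_solute` and/or `t_solvent` columns.
#' @param window `c(start, end)` time window in ps (default: full log).
#' @return List with the windowed `series` data frame and a `summary` data
#'   frame of per-bath means and SDs.
#' @export
bath_temperature_series <- function(energy_log, window = NULL) {
  need <- c("time")
  if (!all(need %in% names(energy_log))) stop("missing columns in energy log")
  baths <- intersect(c("t_solute", "t_solvent"), names(energy_log))
  if (length(baths) == 0) stop("missing per-bath temperature columns")
  sel <- if (is.null(window)) rep(TRUE, nrow(energy_log))
         else energy_log$time >= window[1] & energy_log$time <= window[2]
  series <- energy_log[sel, c("time", baths)]
  summary <- do.call(rbind, lapply(baths, function(b) {
    v <- series[[b]]
    v <- v[!is.na(v)]
    data.frame(bath = sub("^t_", "", b), mean = mean(v),
               sd = if (length(v) > 1) sd(v) else 0, n = length(v))
  }))
  list(series = series, summary = summary)
}
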