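#' Configure the two-diatomic cutoff probe
#'
#' Two rigid diatomic molecules, each `bond_length` (default 0.1 nm) in size,
#' are translated along the x axis with their bonds perpendicular to it (atoms
#' at y = +/- bond_length/2).  At each centre-centre separation the
#' electrostatic interaction and the axial force on molecule A are computed
#' under one of three inclusion rules:
#' \describe{
#'   \item{atomistic}{each of the four atom pairs interacts iff its atomic
#'     distance is below R_rf;}
#'   \item{group}{all four pairs interact iff the centre-centre distance is
#'     below R_rf;}
#'   \item{mixed}{molecule A's atoms are tested individually against molecule
#'     B's centre.}
#' }
#' Energies always use the atomic distances (Eq.-3-style reaction-field
#' terms); only list membership differs between the rules.
#'
#' @param charges_a,charges_b Length-2 charge vectors `(q1, q2)` / `(q3, q4)`,
#'   e.  Atom 1 sits at +b/2 along the molecule's orientation axis, atom 2 at
#'   -b/2.
#' @param bond_length Intramolecular distance b, nm.
#' @param scheme `"atomistic"`, `"group"` or `"mixed"`.
#' @param r_rf Reaction-field cutoff, nm.
#' @param eps_rf Reaction-field dielectric constant.
#' @param grid `c(start, stop, step)` centre-centre separations, nm.
#' @param orientation Bond directions of the two molecules, each `"x"`
#'   (collinear with the translation axis), `"y"` or `"z"`.  The default
#'   (both `"y"`) keeps the bonds parallel and perpendicular to the axis;
#'   `c("x", "y")` places molecule B's bond perpendicular to every sight line
#'   from molecule A's atoms, which makes the mixed scheme exactly continuous
#'   at the centre crossings.
#' @return Object of class `probe_config`.
#' @export
probe_config <- function(charges_a, charges_b, bond_length = 0.1,
                         scheme = c("atomistic", "group", "mixed"),
                         r_rf = 1.4, eps_rf = 61,
                         grid = c(0.2, 1.8, 1e-3),
                         orientation = c("y", "y")) {
  scheme <- match.arg(scheme)
  stopifnot(length(charges_a) == 2, length(charges_b) == 2,
            bond_length > 0, grid[3] > 0, grid[1] < grid[2],
            length(orientation) == 2, all(orientation %in% c("x", "y", "z")))
  if (grid[2] > r_rf + 0.5) stop("grid extends beyond R_rf + 0.5 nm")
  structure(list(charges_a = charges_a, charges_b = charges_b,
                 bond_length = bond_length, scheme = scheme,
                 r_rf = r_rf, eps_rf = eps_rf, grid = grid,
                 orientation = orientation),
            class = "probe_config")
}

#' Standard probe presets
#'
#' The three charge distributions of the probe: dipole-dipole
#' `(+q,-q)/(+q,-q)`, dipole-charge `(+q,-q)/(q,0)` and charge-charge
#' `(q,0)/(q,0)`, with `q = 1` e by default.  Profiles scale with the charge
#' products, so the shapes are magnitude-independent.
#'
#' @param q Charge magnitude, e.
#' @param ... Passed to [probe_config()] (e.g. `scheme`, `r_rf`).
#' @return Named list of three [probe_config()]s.
#' @export
standard_configs <- function(q = 1, ...) {
  list(`dipole-dipole` = probe_config(c(q, -q), c(q, -q), ...),
       `dipole-charge` = probe_config(c(q, -q), c(q, 0), ...),
       `charge-charge` = probe_config(c(q, 0), c(q, 0), ...))
}

#' Scan the probe energy and force profile
#'
#' @param config A [probe_config()].
#' @return Object of class `probe_profile`: data frame columns `separation`
#'   (nm), `energy` (kJ/mol), `force` (axial force on molecule A,
#'   kJ mol^-1 nm^-1), plus the config as an attribute.
#' @export
scan_profile <- function(config) {
  b <- config$bond_length
  s <- seq(config$grid[1], config$grid[2], by = config$grid[3])
  if (any(s <= b)) stop("separations must exceed the bond length")
  params <- rf_params(config$eps_rf, config$r_rf)
  h <- b / 2
  axis_vec <- function(k) switch(k, x = c(1, 0, 0), y = c(0, 1, 0),
                                 z = c(0, 0, 1))
  ua <- axis_vec(config$orientation[1])
  ub <- axis_vec(config$orientation[2])
  qa <- config$charges_a; qb <- config$charges_b
  energy <- numeric(length(s))
  force <- numeric(length(s))
  for (i in 1:2) for (j in 1:2) {
    qq <- qa[i] * qb[j]
    off_a <- c(1, -1)[i] * h * ua            # A centred at the origin
    off_b <- c(1, -1)[j] * h * ub            # B centred at (s, 0, 0)
    dx <- off_a[1] - off_b[1] - s
    dyz2 <- sum((off_a[2:3] - off_b[2:3])^2)
    r <- sqrt(dx^2 + dyz2)
    inc <- switch(config$scheme,
                  atomistic = r < config$r_rf,
                  group = s < config$r_rf,
                  # A's atom against B's centre
                  mixed = sqrt((off_a[1] - s)^2 + sum(off_a[2:3]^2)) < config$r_rf)
    if (qq == 0) next
    v <- .f_elec * qq * ((1 / r - 1 / params$r_rf) -
                           0.5 * params$c_rf * (r^2 - params$r_rf^2) / params$r_rf^3)
    # axial (x) component of the pair force on the A atom
    fmag <- .f_elec * qq * (1 / r^2 + params$c_rf * r / params$r_rf^3)
    fx <- fmag * dx / r
    energy <- energy + ifelse(inc, v, 0)
    force <- force + ifelse(inc, fx, 0)
  }
  structure(data.frame(separation = s, energy = energy, force = force),
            config = config, class = c("probe_profile", "data.frame"))
}

#' Detect discontinuities in a scanned profile
#'
#' Flags grid intervals whose value change exceeds 10 times the median
#' absolute neighbouring change within a window (plus a tiny absolute floor so
#' exactly-flat stretches produce no flags).
#'
#' @param profile A [scan_profile()] result (or any data frame with
#'   `separation` and a value column).
#' @param value Column to examine, `"energy"` or `"force"`.
#' @param window Half-width of the comparison window, in grid intervals.
#' @return Data frame with `location` (interval midpoint, nm) and `jump`
#'   (signed value change).
#' @export
find_discontinuities <- function(profile, value = "energy", window = 25L) {
  x <- profile$separation
  v <- profile[[value]]
  if (length(v) < 3) return(data.frame(location = numeric(0), jump = numeric(0)))
  d <- diff(v)
  nd <- length(d)
  floor_abs <- 1e-12 * max(1, max(abs(v)))
  flag <- logical(nd)
  for (k in seq_len(nd)) {
    lo <- max(1, k - window); hi <- min(nd, k + window)
    neigh <- abs(d[setdiff(lo:hi, k)])
    flag[k] <- abs(d[k]) > 10 * median(neigh) + floor_abs
  }
  data.frame(location = (x[-length(x)] + x[-1])[flag] / 2, jump = d[flag])
}

#' Full (cutoff-free) probe interaction energy
#'
#' All four atom pairs with bare Coulomb terms -- the multipole-decay
#' reference (dipole-dipole interactions fall off as r^-3, charge-charge as
#' r^-1).
#'
#' @param config A [probe_config()].
#' @param s Centre-centre separations, nm.
#' @return Energies, kJ/mol.
#' @export
probe_bare_energy <- function(config, s) {
  h <- config$bond_length / 2
  axis_vec <- function(k) switch(k, x = c(1, 0, 0), y = c(0, 1, 0),
                                 z = c(0, 0, 1))
  ua <- axis_vec(config$orientation[1])
  ub <- axis_vec(config$orientation[2])
  qa <- config$charges_a; qb <- config$charges_b
  e <- numeric(length(s))
  for (i in 1:2) for (j in 1:2) {
    off <- c(1, -1)[i] * h * ua - c(1, -1)[j] * h * ub
    r <- sqrt((off[1] - s)^2 + sum(off[2:3]^2))
    e <- e + .f_elec * qa[i] * qb[j] / r
  }
  e
}
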