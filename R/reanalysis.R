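#' Re-evaluate stored frames under an alternative cutoff scheme
#'
#' For every trajectory frame a fresh single-range pairlist is built at
#' `scheme$r_long` and the electrostatic (and optionally Lennard-Jones)
#' energy decomposition is recomputed -- no twin-range caching is ever used on
#' stored frames.
#'
#' @param trajectory An `md_run` or list of frames (`positions`, `box`,
#'   `time`).
#' @param system The matching [md_system()] (topology of the frames).
#' @param scheme The [cutoff_scheme()] to evaluate under.
#' @param eps_rf Reaction-field dielectric constant.
#' @return Data frame, one row per frame: `time`, electrostatic components
#'   `e_el_ss`, `e_el_sv`, `e_el_vv`, `e_el_total`, and the LJ analogues.
#' @export
reevaluate <- function(trajectory, system, scheme, eps_rf = 61) {
  frames <- .as_frames(trajectory)
  stopifnot(length(frames) > 0)
  if (ncol(frames[[1]]$positions) != 3 ||
      nrow(frames[[1]]$positions) != n_atoms(system))
    stop("topology/trajectory mismatch")
  rows <- lapply(frames, function(f) {
    nb <- nonbonded_energy(system, scheme, eps_rf = eps_rf,
                           positions = f$positions, box = f$box)
    data.frame(time = if (is.null(f$time)) NA_real_ else f$time,
               e_el_ss = nb$energy$electrostatic[[1]],
               e_el_sv = nb$energy$electrostatic[[2]],
               e_el_vv = nb$energy$electrostatic[[3]],
               e_el_total = nb$energy$total_electrostatic,
               e_lj_ss = nb$energy$lj[[1]],
               e_lj_sv = nb$energy$lj[[2]],
               e_lj_vv = nb$energy$lj[[3]],
               e_lj_total = nb$energy$total_lj)
  })
  do.call(rbind, rows)
}

#' Summarize a cross-scheme energy change with per-atom normalization
#'
#' Component-wise `dE = alt - orig` per frame, averaged with SDs, and
#' normalized by subsystem size: solute-solute by `N_solute`, solvent-solvent
#' by `N_solvent`, and solute-solvent by `sqrt(N_solute * N_solvent)`.
#' Components whose subsystem is empty are flagged `NA`.
#'
#' @param orig_report,alt_report [reevaluate()] outputs on the same frames
#'   (original and alternative scheme).
#' @param n_atoms_solute,n_atoms_solvent Atom counts of the two subsystems.
#' @param what `"electrostatic"` (the headline quantity) or `"lj"`.
#' @return Data frame with one row per component: raw and normalized mean dE
#'   and SDs, plus the frame count.
#' @export
summarize_reanalysis <- function(orig_report, alt_report,
                                 n_atoms_solute, n_atoms_solvent,
                                 what = c("electrostatic", "lj")) {
  what <- match.arg(what)
  if (nrow(orig_report) != nrow(alt_report)) stop("frame counts differ")
  pre <- if (what == "electrostatic") "e_el_" else "e_lj_"
  comp <- c(ss = "ss", sv = "sv", vv = "vv")
  norm <- c(ss = n_atoms_solute, sv = sqrt(n_atoms_solute * n_atoms_solvent),
            vv = n_atoms_solvent)
  out <- lapply(names(comp), function(k) {
    de <- alt_report[[paste0(pre, k)]] - orig_report[[paste0(pre, k)]]
    ok <- norm[[k]] > 0
    data.frame(component = c(ss = "solute-solute", sv = "solute-solvent",
                             vv = "solvent-solvent")[[k]],
               mean_de = mean(de), sd_de = if (length(de) > 1) sd(de) else 0,
               mean_de_norm = if (ok) mean(de) / norm[[k]] else NA_real_,
               sd_de_norm = if (ok) (if (length(de) > 1) sd(de) else 0) / norm[[k]] else NA_real_,
               n_frames = length(de))
  })
  do.call(rbind, out)
}
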