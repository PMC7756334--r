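# Internal unit system: nm, ps, u, e, kJ/mol.

.f_elec <- 138.935458     # 1/(4 pi eps0), kJ mol^-1 nm e^-2
.k_boltz <- 8.31446e-3    # kJ mol^-1 K^-1
.atm_kj <- 0.0610194      # 1 atm in kJ mol^-1 nm^-3
.u_per_kgm3 <- 1.66053907 # 1 u nm^-3 in kg m^-3

#' Physical constants used by the engine
#'
#' The engine works in nm / ps / u / e / kJ mol^-1 throughout.  In this unit
#' system kinetic energy `0.5 * m * v^2` with `m` in u and `v` in nm/ps comes
#' out directly in kJ/mol.
#'
#' @return Named list with `f_elec` (Coulomb prefactor, kJ mol^-1 nm e^-2),
#'   `k_boltz` (kJ mol^-1 K^-1), `atm` (1 atm in kJ mol^-1 nm^-3) and
#'   `u_per_kgm3` (1 u nm^-3 expressed in kg m^-3).
#' @examples
#' md_constants()$k_boltz
#' @export
md_constants <- function() {
  list(f_elec = .f_elec, k_boltz = .k_boltz, atm = .atm_kj,
       u_per_kgm3 = .u_per_kgm3)
}

# Evaluate fn with a private RNG stream; the caller's .Random.seed is
# untouched.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}
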