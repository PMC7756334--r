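#' Define a nonbonded cutoff scheme
#'
#' A scheme fixes (i) the interaction entities per subsystem -- every atom its
#' own entity (`"atomistic"`) or one entity per charge group (`"group"`), (ii)
#' how a group's centre is measured (`"cog"`, centre of geometry, or `"atom"`,
#' a designated atom such as the water oxygen), and (iii) the twin-range radii
#' and pairlist update cadence.  `r_long` doubles as the reaction-field cutoff
#' R_rf.  `update_interval = 1` makes every step an update, i.e. a
#' single-range scheme.
#'
#' @param solute_rule,solvent_rule `"atomistic"` or `"group"`.
#' @param center_rule `"cog"` or `"atom"` (group entities only).
#' @param designated_atom Atom name used when `center_rule = "atom"`.
#' @param r_short,r_long Short- and long-range cutoff radii, nm
#'   (0 < r_short <= r_long).
#' @param update_interval Pairlist update interval in steps (>= 1).
#' @return An object of class `cutoff_scheme`.
#' @seealso [scheme_preset()] for the schemes compared in the study.
#' @export
cutoff_scheme <- function(solute_rule = c("group", "atomistic"),
                          solvent_rule = c("group", "atomistic"),
                          center_rule = c("cog", "atom"),
                          designated_atom = "OW",
                          r_short = 0.8, r_long = 1.4,
                          update_interval = 5L) {
  solute_rule <- match.arg(solute_rule)
  solvent_rule <- match.arg(solvent_rule)
  center_rule <- match.arg(center_rule)
  stopifnot(r_short > 0, r_short <= r_long, update_interval >= 1)
  structure(list(solute_rule = solute_rule, solvent_rule = solvent_rule,
                 center_rule = center_rule, designated_atom = designated_atom,
                 r_short = r_short, r_long = r_long,
                 update_interval = as.integer(update_interval)),
            class = "cutoff_scheme")
}

#' @export
print.cutoff_scheme <- function(x, ...) {
  cat(sprintf("<cutoff_scheme> solute=%s solvent=%s center=%s%s R=%.2f/%.2f nm, update every %d step(s)%s\n",
              x$solute_rule, x$solvent_rule, x$center_rule,
              if (x$center_rule == "atom") paste0("(", x$designated_atom, ")") else "",
              x$r_short, x$r_long, x$update_interval,
              if (x$r_short == x$r_long || x$update_interval == 1L) " [single-range]" else " [twin-range]"))
  invisible(x)
}

#' Named cutoff-scheme presets
#'
#' The scheme variants compared in the study: `"CG/TR"` (group-based
#' twin-range, 0.8/1.4 nm, update every 5 steps), `"CG/SR"` (single-range),
#' `"AT/TR"` (atomistic twin-range), `"SA/TR"` (solute atomistic, solvent
#' group), and the pure-water variants `"AT"`, `"CG(cog)"`, `"CG(OW)"`.
#'
#' @param name Preset name.
#' @param r_short,r_long,update_interval Optional overrides of the preset
#'   radii / cadence (used for scaled-down boxes).
#' @return A [cutoff_scheme()].
#' @export
scheme_preset <- function(name = c("CG/TR", "CG/SR", "AT/TR", "SA/TR",
                                   "AT", "CG(cog)", "CG(OW)"),
                          r_short = NULL, r_long = NULL,
                          update_interval = NULL) {
  name <- match.arg(name)
  base <- switch(name,
    "CG/TR" = cutoff_scheme("group", "group", "cog"),
    "CG/SR" = cutoff_scheme("group", "group", "cog", update_interval = 1L),
    "AT/TR" = cutoff_scheme("atomistic", "atomistic", "cog"),
    "SA/TR" = cutoff_scheme("atomistic", "group", "cog"),
    "AT" = cutoff_scheme("atomistic", "atomistic", "cog"),
    "CG(cog)" = cutoff_scheme("group", "group", "cog"),
    "CG(OW)" = cutoff_scheme("group", "group", "atom", designated_atom = "OW"))
  if (!is.null(r_short)) base$r_short <- r_short
  if (!is.null(r_long)) base$r_long <- r_long
  if (!is.null(update_interval)) base$update_interval <- as.integer(update_interval)
  stopifnot(base$r_short <= base$r_long)
  base
}

#' Build interaction entities for a system under a scheme
#'
#' Atomistic subsystems yield one single-atom entity per atom; group
#' subsystems yield one entity per charge group, centred on the centre of
#' geometry or on the designated atom.
#'
#' @param system An [md_system()].
#' @param scheme A [cutoff_scheme()].
#' @return An object of class `md_entities`: a list with 0-based CSR-style
#'   member arrays (`ptr`, `atoms`), the per-entity centre atom (`center_atom`,
#'   0-based, -1 = centre of geometry) and per-entity subsystem labels.
#' @export
make_entities <- function(system, scheme) {
  n <- n_atoms(system)
  atoms <- integer(0); ptr <- 0L; center <- integer(0); subsys <- character(0)
  add_atomistic <- function(idx) {
    for (a in idx) {
      atoms <<- c(atoms, a - 1L)
      ptr <<- c(ptr, length(atoms))
      center <<- c(center, a - 1L)
      subsys <<- c(subsys, system$subsystem[a])
    }
  }
  add_groups <- function(idx) {
    for (g in unique(system$charge_group_id[idx])) {
      members <- which(system$charge_group_id == g)
      atoms <<- c(atoms, members - 1L)
      ptr <<- c(ptr, length(atoms))
      if (scheme$center_rule == "atom" && length(members) > 1) {
        hit <- members[system$name[members] == scheme$designated_atom]
        if (length(hit) == 0)
          stop(sprintf("charge group %d has no atom named '%s' for the designated-atom centre rule",
                       g, scheme$designated_atom))
        center <<- c(center, hit[1] - 1L)
      } else if (length(members) == 1) {
        center <<- c(center, members[1] - 1L)
      } else {
        center <<- c(center, -1L)
      }
      subsys <<- c(subsys, system$subsystem[members[1]])
    }
  }
  sol <- which(system$subsystem == "solute")
  wat <- which(system$subsystem == "solvent")
  if (length(sol)) {
    if (scheme$solute_rule == "atomistic") add_atomistic(sol) else add_groups(sol)
  }
  if (length(wat)) {
    if (scheme$solvent_rule == "atomistic") add_atomistic(wat) else add_groups(wat)
  }
  structure(list(ptr = as.integer(ptr), atoms = as.integer(atoms),
                 center_atom = as.integer(center),
                 subsystem = subsys, n_entities = length(center)),
            class = "md_entities")
}

#' Entity centres
#'
#' `entity_centers()` returns the centre of every entity (single-atom entities
#' and designated-atom groups return that atom's position; otherwise the
#' unweighted mean of the members).  `entity_center()` is the single-entity
#' accessor.
#'
#' @param entities An [make_entities()] result.
#' @param positions N x 3 coordinate matrix, nm.
#' @param i Entity index (1-based).
#' @return A matrix of centres (or a length-3 vector for `entity_center`).
#' @export
entity_centers <- function(entities, positions) {
  cpp_entity_centers(positions, entities$ptr, entities$atoms,
                     entities$center_atom)
}

#' @rdname entity_centers
#' @export
entity_center <- function(entities, positions, i) {
  stopifnot(i >= 1, i <= entities$n_entities)
  ca <- entities$center_atom[i]
  if (ca >= 0) return(positions[ca + 1L, ])
  members <- entities$atoms[(entities$ptr[i] + 1L):entities$ptr[i + 1L]] + 1L
  colMeans(positions[members, , drop = FALSE])
}

#' Classify entity pairs into short- and intermediate-range lists
#'
#' Minimum-image centre distances; strictly-less-than inclusion at `r_short`
#' and the half-open shell `[r_short, r_long)` for the intermediate list.
#' A cell list is used when every box dimension admits at least three cells of
#' edge `r_long` and there are at least 200 entities; otherwise the O(N^2)
#' path is taken (both paths agree exactly).
#'
#' @param entities [make_entities()] result.
#' @param positions Coordinates, nm.
#' @param box Box edges, nm (each >= `2 * r_long`).
#' @param scheme [cutoff_scheme()].
#' @param method `"auto"`, `"cell"` or `"brute"`.
#' @return An object of class `pair_structure`: 1-based entity index matrices
#'   `short_pairs` and `intermediate_pairs`, the centres used, and an (empty)
#'   intermediate-range cache slot.
#' @export
build_pairlist <- function(entities, positions, box, scheme,
                           method = c("auto", "cell", "brute")) {
  method <- match.arg(method)
  if (any(box < 2 * scheme$r_long))
    stop("box smaller than twice the long-range cutoff: minimum image would double-count")
  centers <- entity_centers(entities, positions)
  cells_ok <- all(floor(box / scheme$r_long) >= 3)
  use_cell <- switch(method,
                     cell = TRUE,
                     brute = FALSE,
                     auto = cells_ok && entities$n_entities >= 200)
  if (use_cell && !cells_ok) stop("cell list requires at least 3 cells per dimension")
  raw <- if (use_cell)
    cpp_pairlist_cell(centers, box, scheme$r_short, scheme$r_long)
  else
    cpp_pairlist_brute(centers, box, scheme$r_short, scheme$r_long)
  # canonical (i, j) ordering: the cell-list and brute-force paths return the
  # same matrix, and downstream evaluation order is reproducible
  canon <- function(m) {
    if (nrow(m) == 0) return(m)
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  structure(list(short_pairs = canon(raw$short_pairs + 1L),
                 intermediate_pairs = canon(raw$intermediate_pairs + 1L),
                 centers = centers, last_update_step = NA_integer_,
                 cache = NULL),
            class = "pair_structure")
}

#' @export
print.pair_structure <- function(x, ...) {
  cat(sprintf("<pair_structure> %d short-range + %d intermediate-range entity pairs%s\n",
              nrow(x$short_pairs), nrow(x$intermediate_pairs),
              if (is.null(x$cache)) "" else " (cache present)"))
  invisible(x)
}

#' Is the pairlist due for an update at this step?
#'
#' True whenever `step` is a multiple of the scheme's update interval (step 0,
#' the first force evaluation, always updates); an interval of 1 makes every
#' step an update, which is the single-range limit.
#'
#' @param step Step counter, starting at 0.
#' @param scheme [cutoff_scheme()].
#' @return Logical.
#' @export
pairlist_due_for_update <- function(step, scheme) {
  stopifnot(step >= 0)
  step %% scheme$update_interval == 0L
}
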