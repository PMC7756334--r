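#' Write and read GRO-dialect coordinate files
#'
#' Fixed-width coordinate files (positions in nm to 3 decimals, optional
#' velocities in nm/ps to 4 decimals, box line), one frame per call.  Format
#' precision is 1e-3 nm; for bit-sensitive re-analysis use the full-precision
#' sidecar ([write_frames()] / [read_frames()]) instead.
#'
#' @param system An [md_system()].
#' @param path Output file.
#' @param title Title line.
#' @param velocities Write the velocity columns?
#' @param append Append as an additional frame (multi-frame trajectory)?
#' @return `write_gro`: the path, invisibly.  `read_gro`: a list with `name`,
#'   `residue_id`, `residue_name`, `positions`, `velocities`, `box`.
#' @export
write_gro <- function(system, path, title = "cutoffmd frame",
                      velocities = TRUE, append = FALSE) {
  n <- n_atoms(system)
  res_name <- ifelse(system$subsystem == "solvent", "SOL", "TOY")
  lines <- c(title, sprintf("%5d", n))
  fmt <- if (velocities) "%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f"
         else "%5d%-5s%5s%5d%8.3f%8.3f%8.3f"
  for (i in seq_len(n)) {
    args <- list(fmt, system$molecule_id[i] %% 100000L, res_name[i],
                 substr(system$name[i], 1, 5), i %% 100000L,
                 system$positions[i, 1], system$positions[i, 2],
                 system$positions[i, 3])
    if (velocities)
      args <- c(args, list(system$velocities[i, 1], system$velocities[i, 2],
                           system$velocities[i, 3]))
    lines <- c(lines, do.call(sprintf, args))
  }
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", system$box[1], system$box[2],
                            system$box[3]))
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gro
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("truncated GRO file: fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO file at line 2: expected atom count")
  if (length(lines) < n + 3) stop(sprintf("truncated GRO file: expected %d atom lines", n))
  pos <- matrix(0, n, 3); vel <- matrix(0, n, 3)
  name <- character(n); rid <- integer(n); rname <- character(n)
  for (i in seq_len(n)) {
    ln <- lines[i + 2]
    if (nchar(ln) < 44)
      stop(sprintf("malformed fixed-width line %d: too short", i + 2))
    rid[i] <- suppressWarnings(as.integer(substr(ln, 1, 5)))
    rname[i] <- trimws(substr(ln, 6, 10))
    name[i] <- trimws(substr(ln, 11, 15))
    fields <- suppressWarnings(as.numeric(c(substr(ln, 21, 28), substr(ln, 29, 36),
                                            substr(ln, 37, 44))))
    if (anyNA(fields) || is.na(rid[i]))
      stop(sprintf("malformed fixed-width line %d", i + 2))
    pos[i, ] <- fields
    if (nchar(ln) >= 68) {
      vf <- suppressWarnings(as.numeric(c(substr(ln, 45, 52), substr(ln, 53, 60),
                                          substr(ln, 61, 68))))
      if (!anyNA(vf)) vel[i, ] <- vf
    }
  }
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]]))
  if (length(box) < 3 || anyNA(box[1:3]))
    stop(sprintf("malformed box line %d", n + 3))
  list(name = name, residue_id = rid, residue_name = rname,
       positions = pos, velocities = vel, box = box[1:3])
}

#' Write and read the plain-text topology sidecar
#'
#' Everything a coordinate file cannot carry: charges, masses, LJ types,
#' molecule / charge-group / subsystem ids, constraints and exclusions, as
#' tab-separated sections.  Round-trips exactly.
#'
#' @param system An [md_system()].
#' @param path Sidecar file.
#' @return `write_topology`: the path, invisibly; `read_topology` combined
#'   with coordinates from [read_gro()] reconstructs the [md_system()].
#' @export
write_topology <- function(system, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# cutoffmd topology sidecar",
               sprintf("# n_atoms\t%d", n_atoms(system)),
               sprintf("# box\t%.17g\t%.17g\t%.17g", system$box[1],
                       system$box[2], system$box[3]),
               "[atoms]",
               "index\tname\tmass\tcharge\tlj_type\tmolecule\tcharge_group\tsubsystem"),
             con)
  at <- data.frame(seq_len(n_atoms(system)), system$name,
                   sprintf("%.17g", system$masses),
                   sprintf("%.17g", system$charges), system$lj_type,
                   system$molecule_id, system$charge_group_id, system$subsystem)
  write.table(at, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  writeLines("[constraints]", con)
  if (nrow(system$constraints))
    write.table(data.frame(system$constraints[, 1], system$constraints[, 2],
                           sprintf("%.17g", system$constraints[, 3])),
                con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  writeLines("[exclusions]", con)
  if (nrow(system$exclusions))
    write.table(system$exclusions, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_topology
#' @param coordinates A [read_gro()] result (or NULL to use zero coordinates).
#' @export
read_topology <- function(path, coordinates = NULL) {
  lines <- readLines(path)
  box <- as.numeric(strsplit(lines[grep("^# box", lines)], "\t")[[1]][2:4])
  sec <- function(name) {
    i <- grep(sprintf("^\\[%s\\]$", name), lines)
    if (!length(i)) stop(sprintf("missing [%s] section", name))
    j <- i + 1
    out <- character(0)
    while (j <= length(lines) && !grepl("^\\[", lines[j])) {
      if (nzchar(trimws(lines[j])) && !grepl("^#", lines[j]))
        out <- c(out, lines[j])
      j <- j + 1
    }
    out
  }
  at <- sec("atoms")[-1]  # drop header row
  f <- strsplit(at, "\t")
  m <- do.call(rbind, f)
  n <- nrow(m)
  cons <- sec("constraints")
  cons <- if (length(cons))
    do.call(rbind, lapply(strsplit(cons, "\t"), as.numeric)) else NULL
  excl <- sec("exclusions")
  excl <- if (length(excl))
    do.call(rbind, lapply(strsplit(excl, "\t"), as.integer)) else NULL
  pos <- if (is.null(coordinates)) matrix(0, n, 3) else coordinates$positions
  vel <- if (is.null(coordinates)) NULL else coordinates$velocities
  md_system(positions = pos, velocities = vel,
            masses = as.numeric(m[, 3]), charges = as.numeric(m[, 4]),
            lj_type = m[, 5], name = m[, 2],
            molecule_id = as.integer(m[, 6]),
            charge_group_id = as.integer(m[, 7]), subsystem = m[, 8],
            constraints = cons, exclusions = excl, box = box)
}

#' Full-precision columnar trajectory files
#'
#' One `frame` header line (`frame <step> <time> <box x y z>`) followed by one
#' `%.17g` coordinate triple per atom; round-trips doubles exactly, which the
#' GRO dialect (1e-3 nm) cannot.
#'
#' @param trajectory `md_run` or list of frames.
#' @param path File path.
#' @return `write_frames`: the path, invisibly; `read_frames`: list of frames.
#' @export
write_frames <- function(trajectory, path) {
  frames <- .as_frames(trajectory)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    writeLines(sprintf("frame\t%d\t%.17g\t%.17g\t%.17g\t%.17g",
                       f$step, f$time, f$box[1], f$box[2], f$box[3]), con)
    writeLines(sprintf("%.17g\t%.17g\t%.17g", f$positions[, 1],
                       f$positions[, 2], f$positions[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  lines <- readLines(path)
  heads <- grep("^frame\t", lines)
  if (!length(heads)) stop("no frames in file")
  ends <- c(heads[-1] - 1, length(lines))
  lapply(seq_along(heads), function(k) {
    h <- as.numeric(strsplit(lines[heads[k]], "\t")[[1]][-1])
    body <- lines[(heads[k] + 1):ends[k]]
    pos <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
    list(step = as.integer(h[1]), time = h[2], positions = pos, box = h[3:5])
  })
}

#' Write an energy log as TSV
#'
#' Tab-separated with `#`-prefixed metadata lines (scheme, seed, conventions).
#'
#' @param run An `md_run`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_energy_log <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  s <- run$scheme
  writeLines(c(sprintf("# cutoffmd %s energy log",
                       tryCatch(as.character(utils::packageVersion("cutoffmd")),
                                error = function(e) "dev")),
               sprintf("# scheme\tsolute=%s solvent=%s center=%s R=%g/%g update=%d (%s)",
                       s$solute_rule, s$solvent_rule, s$center_rule,
                       s$r_short, s$r_long, s$update_interval,
                       if (s$update_interval == 1L || s$r_short == s$r_long)
                         "single-range" else "twin-range"),
               sprintf("# eps_rf\t%g", run$protocol$eps_rf),
               sprintf("# seed\t%d", run$protocol$seed),
               sprintf("# dof\tsolute=%d solvent=%d", run$dof[["solute"]],
                       run$dof[["solvent"]])), con)
  write.table(format(run$energy, digits = 17, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_energy_log
#' @export
read_energy_log <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}
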