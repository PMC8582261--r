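## Structure file I/O. PDB dialect: fixed-column parsing; first altloc kept;
## insertion codes ignored; HETATM excluded by default. Multi-model files
## become trajectories (one frame per MODEL). A PLUMED-dialect writer for
## reference paths puts alignment weights in the occupancy column and
## displacement weights in the B-factor column, one MODEL per frame.

parse_pdb_atom_ <- function(line, lineno) {
  pad <- function(s, n) formatC(s, width = n, flag = "-")
  line <- pad(line, 80)
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(line, from, to)))
    if (is.na(v)) {
      abort(sprintf("malformed %s field in PDB line %d", what, lineno))
    }
    v
  }
  list(
    name = trimws(substr(line, 13, 16)),
    altloc = substr(line, 17, 17),
    resname = trimws(substr(line, 18, 20)),
    chain = substr(line, 22, 22),
    resid = as.integer(num(23, 26, "residue number")),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    element = trimws(substr(line, 77, 78))
  )
}

build_structure_ <- function(recs) {
  el <- vapply(recs, function(r) r$element, "")
  guess <- function(name) {
    # fall back to the first alphabetic character of the atom name
    sub("^[0-9]*([A-Za-z]).*$", "\\1", name)
  }
  nm <- vapply(recs, function(r) r$name, "")
  el <- ifelse(el == "", guess(nm), el)
  md_structure(
    xyz = cbind(
      vapply(recs, function(r) r$x, 0),
      vapply(recs, function(r) r$y, 0),
      vapply(recs, function(r) r$z, 0)
    ),
    atom_names = nm,
    residue_ids = vapply(recs, function(r) r$resid, 0L),
    residue_names = vapply(recs, function(r) r$resname, ""),
    elements = el,
    chain_ids = vapply(recs, function(r) r$chain, "")
  )
}

read_pdb_ <- function(path, include_het = FALSE) {
  lines <- readLines(path, warn = FALSE)
  models <- list()
  current <- list()
  seen_altloc <- character()
  in_model <- FALSE
  any_model <- FALSE
  flush <- function() {
    if (length(current) > 0L) models[[length(models) + 1L]] <<- current
    current <<- list()
    seen_altloc <<- character()
  }
  for (i in seq_along(lines)) {
    rec <- substr(lines[i], 1, 6)
    if (rec == "MODEL ") {
      any_model <- TRUE
      in_model <- TRUE
    } else if (rec == "ENDMDL") {
      flush()
      in_model <- FALSE
    } else if (rec == "ATOM  " || (include_het && rec == "HETATM")) {
      a <- parse_pdb_atom_(lines[i], i)
      if (a$altloc != " ") {
        key <- paste(a$chain, a$resid, a$name)
        if (key %in% seen_altloc) next
        seen_altloc <- c(seen_altloc, key)
      }
      current[[length(current) + 1L]] <- a
    }
  }
  flush()
  if (length(models) == 0L) abort("no ATOM records found in PDB file")
  structs <- lapply(models, build_structure_)
  counts <- vapply(structs, n_atoms, 0L)
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1L])[1L]
    abort(sprintf(
      "inconsistent atom counts across models: model %d has %d atoms, model 1 has %d",
      bad, counts[bad], counts[1L]
    ))
  }
  if (any_model && length(structs) > 1L) md_trajectory(structs) else structs[[1L]]
}

read_xyz_ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) abort(sprintf("malformed atom count in XYZ line %d", i))
    if (i + 1L + n > length(lines)) abort("truncated XYZ frame")
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "\\s+")
    el <- vapply(toks, `[`, "", 1L)
    co <- t(vapply(toks, function(tk) {
      v <- suppressWarnings(as.numeric(tk[2:4]))
      if (anyNA(v)) abort("malformed coordinate in XYZ file")
      v
    }, numeric(3)))
    frames[[length(frames) + 1L]] <- md_structure(co, elements = el, atom_names = el)
    i <- i + 2L + n
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (length(frames) == 0L) abort("empty XYZ file")
  if (length(frames) == 1L) frames[[1L]] else md_trajectory(frames)
}

#' Read a structure or trajectory from PDB or XYZ
#'
#' Multi-model PDB files (one MODEL per frame) are returned as an
#' `md_trajectory`; single-model files as an `md_structure`. Coordinates are
#' in angstrom. HETATM records are skipped unless `include_het = TRUE`; for
#' alternate locations the first altloc encountered is kept.
#'
#' @param path file path.
#' @param format `"pdb"` or `"xyz"`; guessed from the extension by default.
#' @param include_het keep HETATM records (PDB only).
#' @return `md_structure` or `md_trajectory`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz"),
                           include_het = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  switch(format,
    pdb = read_pdb_(path, include_het = include_het),
    xyz = read_xyz_(path)
  )
}

format_pdb_atom_ <- function(i, name, resname, chain, resid, xyz,
                             occ = 1, bfac = 0, element = "") {
  name_fmt <- if (nchar(name) < 4L) sprintf(" %-3s", name) else substr(name, 1, 4)
  sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    i %% 100000L, name_fmt, substr(resname, 1, 3), substr(chain, 1, 1),
    resid %% 10000L, xyz[1], xyz[2], xyz[3], occ, bfac, substr(element, 1, 2)
  )
}

structure_pdb_lines_ <- function(s, occ = NULL, bfac = NULL) {
  n <- n_atoms(s)
  if (is.null(occ)) occ <- rep(1, n)
  if (is.null(bfac)) bfac <- rep(0, n)
  vapply(seq_len(n), function(i) {
    format_pdb_atom_(
      i, s$atoms$atom_name[i], s$atoms$residue_name[i], s$atoms$chain_id[i],
      s$atoms$residue_id[i], s$xyz[i, ], occ[i], bfac[i], s$atoms$element[i]
    )
  }, "")
}

#' Write a structure or trajectory to PDB or XYZ
#'
#' Trajectories are written as multi-model PDB (MODEL/ENDMDL per frame) or
#' multi-frame XYZ.
#'
#' @param x `md_structure` or `md_trajectory`.
#' @param path output file path.
#' @param format `"pdb"` or `"xyz"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  frames <- if (inherits(x, "md_trajectory")) {
    lapply(seq_len(n_frames(x)), function(i) get_frame(x, i))
  } else {
    list(x)
  }
  lines <- character()
  if (format == "pdb") {
    multi <- length(frames) > 1L
    for (i in seq_along(frames)) {
      if (multi) lines <- c(lines, sprintf("MODEL     %4d", i))
      lines <- c(lines, structure_pdb_lines_(frames[[i]]))
      if (multi) lines <- c(lines, "ENDMDL")
    }
    lines <- c(lines, "END")
  } else {
    for (f in frames) {
      lines <- c(
        lines, as.character(n_atoms(f)), "generated by pathmetad",
        sprintf(
          "%-2s %12.6f %12.6f %12.6f",
          f$atoms$element, f$xyz[, 1], f$xyz[, 2], f$xyz[, 3]
        )
      )
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a reference path as a PLUMED-dialect multi-model PDB
#'
#' One MODEL per path frame; the occupancy column carries the alignment
#' weights and the B-factor column the displacement weights (uniform by
#' default), the convention expected by path-CV implementations.
#'
#' @param path_obj a [reference_path()] object.
#' @param file output file path.
#' @param align_weights,displace_weights per-atom weights recycled to the
#'   selection length; default uniform 1.
#' @return `file`, invisibly.
#' @export
write_path_pdb <- function(path_obj, file, align_weights = 1,
                           displace_weights = 1) {
  stopifnot(inherits(path_obj, "reference_path"))
  n <- nrow(path_obj$frames[[1L]])
  occ <- rep_len(align_weights, n)
  bfac <- rep_len(displace_weights, n)
  atoms <- path_obj$atoms
  lines <- character()
  for (i in seq_along(path_obj$frames)) {
    s <- structure(list(xyz = path_obj$frames[[i]], atoms = atoms),
      class = "md_structure"
    )
    lines <- c(
      lines, sprintf("MODEL     %4d", i),
      structure_pdb_lines_(s, occ = occ, bfac = bfac), "ENDMDL"
    )
  }
  writeLines(c(lines, "END"), file)
  invisible(file)
}
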