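## Plain-text interchange: HILLS-style and COLVAR-style TSV with '#!' field
## headers (the convention enhanced-sampling toolchains expect), plus FES
## and MFEP tables.

write_fields_tsv_ <- function(df, file, fields) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(fields, collapse = " ")), con)
  utils::write.table(df[, fields],
    file = con, sep = "\t", row.names = FALSE,
    col.names = FALSE, quote = FALSE
  )
  invisible(file)
}

read_fields_tsv_ <- function(file) {
  first <- readLines(file, n = 1L)
  if (!startsWith(first, "#! FIELDS")) abort("missing '#! FIELDS' header")
  fields <- strsplit(sub("^#! FIELDS\\s+", "", first), "\\s+")[[1L]]
  df <- utils::read.table(file, sep = "\t", comment.char = "#")
  names(df) <- fields
  as_tibble(df)
}

#' Write / read a HILLS-style hill list
#'
#' Tab-separated with a `#! FIELDS` header:
#' time, center_s, center_z, sigma_s, sigma_z, height, gamma.
#'
#' @param bias a `bias_potential`.
#' @param file path.
#' @return `file` (write); a `bias_potential` (read; `params` beyond gamma
#'   take package defaults).
#' @export
write_hills <- function(bias, file) {
  h <- bias$hills
  h$gamma <- bias$params$gamma
  write_fields_tsv_(h, file, c(
    "time", "center_s", "center_z", "sigma_s",
    "sigma_z", "height", "gamma"
  ))
}

#' @rdname write_hills
#' @param dim,n_path_frames see [bias_potential()].
#' @export
read_hills <- function(file, dim = 2L, n_path_frames = NULL) {
  df <- read_fields_tsv_(file)
  params <- metad_params(gamma = df$gamma[1L])
  b <- bias_potential(params, dim = dim, n_path_frames = n_path_frames)
  b$hills <- df[, c("time", "center_s", "center_z", "sigma_s", "sigma_z", "height")]
  b
}

#' Write / read a COLVAR-style CV log
#'
#' Tab-separated with a `#! FIELDS` header: time, s, s_hat, z, bias.
#'
#' @param cv_log tibble with those columns (e.g. a `metad_run`'s `cv_log`).
#' @param file path.
#' @export
write_colvar <- function(cv_log, file) {
  df <- cv_log
  if (!"time" %in% names(df)) df$time <- df$time_ps
  write_fields_tsv_(df, file, c("time", "s", "s_hat", "z", "bias"))
}

#' @rdname write_colvar
#' @export
read_colvar <- function(file) read_fields_tsv_(file)

#' Write a free-energy surface or MFEP profile as TSV
#'
#' `fes2d` becomes a 3-column (s_hat, z, F) table; an `mfep_profile` a
#' (bin_center, z_min, F) table.
#'
#' @param x a `fes2d`, `fes1d` or `mfep_profile`.
#' @param file path.
#' @export
write_fes_tsv <- function(x, file) {
  if (inherits(x, "fes2d")) {
    df <- tidy(x)
    write_fields_tsv_(df, file, c("s_hat", "z", "F"))
  } else if (inherits(x, "fes1d")) {
    write_fields_tsv_(tidy(x), file, c("x", "F"))
  } else if (inherits(x, "mfep_profile")) {
    df <- tibble(bin_center = x$s_hat_center, z_min = x$z_at_min, F = x$F)
    write_fields_tsv_(df, file, c("bin_center", "z_min", "F"))
  } else {
    abort("unsupported object for TSV export")
  }
}
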