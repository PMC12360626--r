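#' Read and write sweep sets
#'
#' The on-disk layout is plain text: a data CSV with one row per sweep
#' (columns `s1 ... sN`, current in pA) and a sidecar key-value header file
#' at `<path>.meta` carrying `sample_rate_hz`, `stim_time_s`, `cell_id`,
#' `condition`, `drug`, `inter_sweep_interval_s`, `holding_potential_mv`
#' and, when recorded, a comma-separated `series_resistance_mohm` list.
#' `load_sweeps(save_sweeps(x))` reproduces `x` within float tolerance.
#'
#' Only `format = "csv"` is implemented; `"nwb"` and `"hdf5"` are accepted
#' in the signature for forward compatibility and raise an informative
#' error.
#'
#' @param path File path of the data CSV.
#' @param format Storage format; only `"csv"` is available.
#' @param x A [sweep_set()] (for `save_sweeps`).
#' @return `load_sweeps()` returns a validated `sweep_set`; `save_sweeps()`
#'   returns `path` invisibly.
#' @examples
#' x <- sweep_set(matrix(rnorm(200), 2), 20000, 0.002)
#' f <- tempfile(fileext = ".csv")
#' save_sweeps(x, f)
#' y <- load_sweeps(f)
#' @name sweep-io
NULL

meta_path <- function(path) paste0(path, ".meta")

#' @rdname sweep-io
#' @export
save_sweeps <- function(x, path, format = c("csv", "hdf5", "nwb")) {
  format <- match.arg(format)
  if (format != "csv") {
    abort(sprintf("Format '%s' is not supported by this build; use 'csv'.",
                  format))
  }
  stopifnot(inherits(x, "sweep_set"))
  if (n_sweeps(x) == 0L) abort("Refusing to write an empty sweep set.")
  m <- sweep_matrix(x)
  df <- as.data.frame(m)
  names(df) <- paste0("s", seq_len(ncol(m)))
  write.csv(df, path, row.names = FALSE)
  meta <- c(
    sample_rate_hz = format(sample_rate(x), digits = 17),
    stim_time_s = format(stim_time(x), digits = 17),
    cell_id = cell_id(x),
    condition = condition_of(x),
    drug = drug_of(x),
    inter_sweep_interval_s = format(attr(x, "inter_sweep_interval")),
    holding_potential_mv = format(attr(x, "holding_potential")))
  if (!all(is.na(x$series_resistance))) {
    meta["series_resistance_mohm"] <-
      paste(format(x$series_resistance, digits = 17), collapse = ",")
  }
  writeLines(paste0(names(meta), ": ", meta), meta_path(path))
  invisible(path)
}

read_meta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  setNames(as.list(vals), keys)
}

#' @rdname sweep-io
#' @export
load_sweeps <- function(path, format = c("csv", "hdf5", "nwb")) {
  format <- match.arg(format)
  if (format != "csv") {
    abort(sprintf("Format '%s' is not supported by this build; use 'csv'.",
                  format))
  }
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  mp <- meta_path(path)
  if (!file.exists(mp)) {
    abort(sprintf("Sidecar header file not found: %s", mp))
  }
  meta <- read_meta(mp)
  for (req in c("sample_rate_hz", "stim_time_s")) {
    if (is.null(meta[[req]])) {
      abort(sprintf("Header %s is missing required field '%s'.", mp, req))
    }
  }
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) abort(sprintf("No sweeps in %s.", path))
  m <- as.matrix(df)
  if (!is.numeric(m)) abort(sprintf("Non-numeric sweep data in %s.", path))
  rs <- NULL
  if (!is.null(meta$series_resistance_mohm)) {
    rs <- as.numeric(strsplit(meta$series_resistance_mohm, ",")[[1]])
  }
  sweep_set(unname(m),
            sample_rate = as.numeric(meta$sample_rate_hz),
            stim_time = as.numeric(meta$stim_time_s),
            cell_id = meta$cell_id %||% "cell",
            condition = meta$condition %||% "baseline",
            drug = meta$drug %||% "none",
            series_resistance = rs,
            inter_sweep_interval =
              as.numeric(meta$inter_sweep_interval_s %||% 30),
            holding_potential =
              as.numeric(meta$holding_potential_mv %||% -65))
}
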