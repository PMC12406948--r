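#' Write / read a time-domain signal as delimited text
#'
#' The on-disk format is plain text: header lines `# key=value` carrying
#' `sample_id`, `f_ex`, `B_ex`, `sample_rate`, `n_periods`, `voltage_mode`
#' (and `temperature`), followed by one moment sample per line. Samples are
#' serialized with 17 significant digits so a write -> read round trip is
#' bit-exact for doubles.
#'
#' @param signal an [mps_signal()].
#' @param path file path.
#' @return `write_time_signal()` returns `path` invisibly;
#'   `read_time_signal()` returns an [mps_signal()].
#' @export
write_time_signal <- function(signal, path) {
  stopifnot(inherits(signal, "mps_signal"))
  cfg <- signal$config
  header <- c(
    sprintf("# sample_id=%s", signal$sample_id),
    sprintf("# f_ex=%.17g", cfg$f_ex),
    sprintf("# B_ex=%.17g", cfg$B_ex),
    sprintf("# sample_rate=%.17g", cfg$sample_rate),
    sprintf("# n_periods=%d", cfg$n_periods),
    sprintf("# temperature=%.17g", cfg$temperature),
    sprintf("# voltage_mode=%s", if (signal$voltage_mode) "true" else "false"))
  writeLines(c(header, sprintf("%.17g", signal$samples)), path)
  invisible(path)
}

#' @rdname write_time_signal
#' @param path file path.
#' @export
read_time_signal <- function(path) {
  lines <- readLines(path)
  is_head <- startsWith(lines, "# ")
  kv <- sub("^# ", "", lines[is_head])
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  required <- c("sample_id", "f_ex", "B_ex", "sample_rate", "n_periods",
                "voltage_mode")
  missing <- setdiff(required, keys)
  if (length(missing))
    stop("signal file is missing header key(s): ",
         paste(missing, collapse = ", "))
  f_ex <- as.numeric(vals[["f_ex"]])
  sample_rate <- as.numeric(vals[["sample_rate"]])
  n_periods <- as.integer(vals[["n_periods"]])
  samples <- as.numeric(lines[!is_head & nzchar(lines)])
  spp <- sample_rate / f_ex
  if (abs(spp - round(spp)) > 1e-9)
    stop("sample_rate is not an integer multiple of f_ex")
  expected <- round(spp) * n_periods
  if (length(samples) != expected)
    stop("file contains ", length(samples), " samples but the header ",
         "(n_periods = ", n_periods, ", ", round(spp),
         " samples/period) implies ", expected)
  cfg <- excitation_config(
    f_ex = f_ex, B_ex = as.numeric(vals[["B_ex"]]),
    samples_per_period = round(spp), n_periods = n_periods,
    temperature = as.numeric(vals[["temperature"]] %||% "300"))
  mps_signal(samples, cfg, sample_id = vals[["sample_id"]],
             voltage_mode = identical(vals[["voltage_mode"]], "true"))
}

## canonical md5 hash of an R object (via its canonical JSON serialization)
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

## delimited export with provenance comment lines
write_table_with_provenance <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# config_hash=%s", hash),
               sprintf("# seed=%d", seed)), con)
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
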