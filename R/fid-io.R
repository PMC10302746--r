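#' Read and write the native FID container
#'
#' The native container is a small UTF-8 text format: header lines of the
#' form `key = value` (keys `n_points`, `spectrometer_freq_mhz`,
#' `sweep_width_ppm`, `group_delay`, `reference_shift_ppm`, `scans`), a blank
#' line, then CSV rows `real,imag`, one complex sample per row. A write
#' followed by a read reproduces the points bit-exactly (values are written
#' with full double precision).
#'
#' @param path File path.
#' @return `read_fid()` returns an `nmr_fid`; `write_fid()` returns `path`
#'   invisibly.
#' @export
read_fid <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  blank <- which(lines == "")[1]
  if (is.na(blank)) {
    stop("Malformed FID container: no blank line separating header from data.",
         call. = FALSE)
  }
  header <- lines[seq_len(blank - 1)]
  kv <- strsplit(header, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  names(vals) <- keys
  mandatory <- c("n_points", "spectrometer_freq_mhz", "sweep_width_ppm",
                 "group_delay", "reference_shift_ppm")
  missing <- setdiff(mandatory, keys)
  if (length(missing) > 0) {
    stop("FID container is missing mandatory metadata keys: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dat <- utils::read.csv(textConnection(lines[(blank + 1):length(lines)]),
                         header = FALSE, colClasses = "character")
  re <- as.numeric(dat[[1]])
  im <- as.numeric(dat[[2]])
  fid <- new_fid(
    points = complex(real = re, imaginary = im),
    spectrometer_freq = as.numeric(vals[["spectrometer_freq_mhz"]]),
    sweep_width = as.numeric(vals[["sweep_width_ppm"]]),
    group_delay = as.numeric(vals[["group_delay"]]),
    reference_shift = as.numeric(vals[["reference_shift_ppm"]]),
    scans = if ("scans" %in% keys) as.integer(vals[["scans"]]) else 1L
  )
  if (fid$n_points != as.integer(vals[["n_points"]])) {
    stop(sprintf("FID container declares %s points but contains %d rows.",
                 vals[["n_points"]], fid$n_points), call. = FALSE)
  }
  fid
}

#' @rdname read_fid
#' @param fid An `nmr_fid` to serialize.
#' @export
write_fid <- function(fid, path) {
  stopifnot(inherits(fid, "nmr_fid"))
  header <- c(
    sprintf("n_points = %d", fid$n_points),
    sprintf("spectrometer_freq_mhz = %s", format_full(fid$spectrometer_freq)),
    sprintf("sweep_width_ppm = %s", format_full(fid$sweep_width)),
    sprintf("group_delay = %s", format_full(fid$group_delay)),
    sprintf("reference_shift_ppm = %s", format_full(fid$reference_shift)),
    sprintf("scans = %d", fid$scans),
    ""
  )
  rows <- paste(format_full(Re(fid$points)), format_full(Im(fid$points)),
                sep = ",")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

# full-precision decimal representation that round-trips doubles exactly
format_full <- function(x) {
  formatC(x, digits = 17, format = "g")
}

#' Export a spectrum to CSV with a JSON metadata sidecar
#'
#' Writes `ppm,intensity` rows to `path` and, alongside it, a
#' `<path>.meta.json` sidecar holding `noise_sigma` and the acquisition
#' metadata.
#'
#' @param spec An `nmr_spectrum`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  utils::write.csv(as.data.frame(spec[, c("ppm", "intensity")]), path,
                   row.names = FALSE)
  sidecar <- list(noise_sigma = noise_sigma(spec), meta = spectrum_meta(spec))
  jsonlite::write_json(sidecar, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
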