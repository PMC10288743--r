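#' Construct a raw optical recording
#'
#' Holds per-channel, per-wavelength raw light intensity time series together
#' with the montage and sampling metadata. Intensities are strictly positive
#' arbitrary units; the log-ratio is taken later during optical-density
#' conversion.
#'
#' @param subject_id Subject identifier string.
#' @param group One of `"HC"`, `"MCS"`, `"VS"`.
#' @param intensity Numeric array indexed `(channel, wavelength, sample)`.
#' @param montage An `fnirs_montage`; its channels must match the first
#'   dimension of `intensity`.
#' @param sampling_rate_hz Sampling rate in Hz (default 10).
#' @param wavelengths_nm Ordered pair of distinct wavelengths (default
#'   `c(760, 830)`).
#' @param t0_s Start time of sample 1 in seconds (default 0).
#' @param i0_reference Optional `channel x wavelength` matrix of the reference
#'   intensities used by a forward model; kept so an inversion can use the
#'   same reference.
#' @return An object of class `optical_recording`.
#' @export
new_optical_recording <- function(subject_id, group, intensity,
                                  montage = default_montage(),
                                  sampling_rate_hz = 10,
                                  wavelengths_nm = c(760, 830),
                                  t0_s = 0, i0_reference = NULL) {
  rec <- structure(
    list(
      subject_id = as.character(subject_id),
      group = match.arg(group, .groups),
      sampling_rate_hz = sampling_rate_hz,
      wavelengths_nm = wavelengths_nm,
      montage = montage,
      intensity = intensity,
      t0_s = t0_s,
      i0_reference = i0_reference
    ),
    class = "optical_recording"
  )
  validate_recording(rec)
}

#' @rdname new_optical_recording
#' @param rec An `optical_recording`.
#' @export
validate_recording <- function(rec) {
  validate_montage(rec$montage)
  dims <- dim(rec$intensity)
  if (length(dims) != 3) stop("intensity must be a 3-d (channel, wavelength, sample) array")
  if (dims[1] != nrow(rec$montage$channels)) {
    stop("intensity has ", dims[1], " channels but montage defines ",
         nrow(rec$montage$channels))
  }
  if (length(rec$wavelengths_nm) != 2 ||
      rec$wavelengths_nm[1] == rec$wavelengths_nm[2]) {
    stop("wavelengths_nm must be two distinct wavelengths")
  }
  if (dims[2] != 2) stop("intensity must carry exactly two wavelengths")
  if (!is.finite(rec$sampling_rate_hz) || rec$sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be positive")
  }
  bad <- which(!is.finite(rec$intensity) | rec$intensity <= 0)
  if (length(bad) > 0) {
    idx <- arrayInd(bad[1], dims)
    stop(sprintf(
      "non-positive intensity at channel %s, wavelength %g nm, sample %d",
      rec$montage$channels$channel[idx[1]], rec$wavelengths_nm[idx[2]], idx[3]
    ))
  }
  rec
}

#' @export
print.optical_recording <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "<optical_recording> subject %s (%s): %d channels x %d wavelengths x %d samples @ %g Hz\n",
    x$subject_id, x$group, d[1], d[2], d[3], x$sampling_rate_hz
  ))
  invisible(x)
}

rec_channel_labels <- function(rec) rec$montage$channels$channel

# Column names of the TSV dialect: time_s then <channel>@<wavelength>.
rec_column_names <- function(channels, wavelengths) {
  grid <- expand.grid(wl = wavelengths, ch = channels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  paste0(grid$ch, "@", grid$wl)
}

#' Write a raw optical recording to disk
#'
#' The canonical `tsv` dialect is a tab-separated table with one header row:
#' a `time_s` column followed by one `<channel>@<wavelength>` column per
#' channel-wavelength combination. Values are written with 17 significant
#' digits so a read/write round trip is lossless at double precision.
#'
#' @param rec An `optical_recording`.
#' @param path Output file path.
#' @param dialect File dialect; only `"tsv"` is implemented.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path, dialect = "tsv") {
  dialect <- match.arg(dialect, "tsv")
  validate_recording(rec)
  d <- dim(rec$intensity)
  n <- d[3]
  time_s <- rec$t0_s + (seq_len(n) - 1) / rec$sampling_rate_hz
  # flatten to sample x (channel*wavelength), wavelength fastest
  flat <- matrix(aperm(rec$intensity, c(2, 1, 3)), nrow = d[1] * d[2], ncol = n)
  cols <- rec_column_names(rec_channel_labels(rec), rec$wavelengths_nm)
  header <- paste(c("time_s", cols), collapse = "\t")
  body <- apply(rbind(time_s, flat), 2, function(v) {
    paste(sprintf("%.17g", v), collapse = "\t")
  })
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a raw optical recording from disk
#'
#' @param path File written by [write_recording()] (or following the same
#'   layout).
#' @param dialect File dialect; only `"tsv"` is implemented.
#' @param subject_id,group Metadata to attach (the TSV dialect stores only the
#'   numeric content).
#' @param montage Montage whose channel labels must match the file header.
#' @return An `optical_recording`.
#' @export
read_recording <- function(path, dialect = "tsv", subject_id = "unknown",
                           group = "HC", montage = default_montage()) {
  dialect <- match.arg(dialect, "tsv")
  if (!file.exists(path)) stop("file not found: ", path)
  tbl <- utils::read.delim(path, check.names = FALSE)
  if (!"time_s" %in% names(tbl)) stop("format error: missing time_s column")
  sig <- names(tbl)[names(tbl) != "time_s"]
  parts <- strsplit(sig, "@", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("format error: signal columns must be named <channel>@<wavelength>")
  }
  channels <- unique(vapply(parts, `[[`, "", 1))
  wavelengths <- sort(unique(as.numeric(vapply(parts, `[[`, "", 2))))
  expected <- rec_column_names(channels, wavelengths)
  if (!setequal(sig, expected)) {
    stop("format error: incomplete channel x wavelength grid in header")
  }
  if (!setequal(channels, montage$channels$channel)) {
    stop("format error: file channels do not match montage channels")
  }
  n <- nrow(tbl)
  intensity <- array(
    NA_real_, dim = c(length(channels), 2, n),
    dimnames = list(channels, wavelengths, NULL)
  )
  for (i in seq_along(channels)) {
    for (j in seq_along(wavelengths)) {
      col <- paste0(channels[i], "@", wavelengths[j])
      v <- tbl[[col]]
      bad <- which(!is.finite(v) | v <= 0)
      if (length(bad) > 0) {
        stop(sprintf(
          "validation error: non-positive intensity in column %s at line %d",
          col, bad[1] + 1L
        ))
      }
      intensity[i, j, ] <- v
    }
  }
  fs <- if (n > 1) 1 / stats::median(diff(tbl$time_s)) else 10
  # reorder channels to the montage order
  ord <- match(montage$channels$channel, channels)
  new_optical_recording(
    subject_id = subject_id, group = group,
    intensity = intensity[ord, , , drop = FALSE], montage = montage,
    sampling_rate_hz = fs, wavelengths_nm = wavelengths, t0_s = tbl$time_s[1]
  )
}
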