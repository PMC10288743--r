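#' Construct an optode montage
#'
#' A montage describes the scalp layout of an fNIRS probe: labelled source and
#' detector positions (schematic 2-D coordinates, arbitrary units), the ordered
#' source-detector pairs that form measurement channels, and the
#' source-detector separation of each channel in centimetres.
#'
#' @param sources,detectors Tibbles with columns `label`, `x`, `y`.
#' @param channels Tibble with columns `channel`, `source`, `detector`,
#'   `separation_cm`.
#' @return An object of class `fnirs_montage`.
#' @export
new_montage <- function(sources, detectors, channels) {
  sources <- tibble::as_tibble(sources)
  detectors <- tibble::as_tibble(detectors)
  channels <- tibble::as_tibble(channels)
  m <- structure(
    list(sources = sources, detectors = detectors, channels = channels),
    class = "fnirs_montage"
  )
  validate_montage(m)
}

#' @rdname new_montage
#' @param m An `fnirs_montage`.
#' @export
validate_montage <- function(m) {
  ch <- m$channels
  if (nrow(ch) == 0) stop("montage must define at least one channel")
  if (anyDuplicated(ch[c("source", "detector")]) > 0) {
    stop("montage channels contain duplicate source-detector pairs")
  }
  if (!all(ch$source %in% m$sources$label)) {
    stop("montage channel references unknown source: ",
         paste(setdiff(ch$source, m$sources$label), collapse = ", "))
  }
  if (!all(ch$detector %in% m$detectors$label)) {
    stop("montage channel references unknown detector: ",
         paste(setdiff(ch$detector, m$detectors$label), collapse = ", "))
  }
  if (!all(is.finite(ch$separation_cm)) || any(ch$separation_cm <= 0)) {
    stop("montage separation_cm must be positive for every channel")
  }
  m
}

#' Default prefrontal 5-channel montage
#'
#' Three sources and two detectors placed along the FP1-FP2 line, paired into
#' five measurement channels, each with a 3 cm source-detector separation.
#' The probe sketch fixes only which optodes exist; the exact five pairings are
#' a convention of this package (each detector paired with its two adjacent
#' sources, plus the S1-D2 line), recorded here rather than inferred from a
#' drawing. Coordinates are schematic and carry arbitrary units; the
#' physically meaningful quantity is `separation_cm`.
#'
#' @return An `fnirs_montage` with 5 channels.
#' @export
#' @examples
#' m <- default_montage()
#' nrow(m$channels)
default_montage <- function() {
  sources <- tibble::tibble(
    label = c("S1", "S2", "S3"),
    x = c(0, 3, 6), y = c(0, 0, 0)
  )
  detectors <- tibble::tibble(
    label = c("D1", "D2"),
    x = c(1.5, 4.5), y = c(1.5, 1.5)
  )
  channels <- tibble::tibble(
    channel = paste0("CH", 1:5),
    source = c("S1", "S2", "S2", "S3", "S1"),
    detector = c("D1", "D1", "D2", "D2", "D2"),
    separation_cm = rep(3, 5)
  )
  new_montage(sources, detectors, channels)
}
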