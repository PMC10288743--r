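#' Clinical characteristics of the patient cohort
#'
#' The 18-patient table of the study population this package emulates:
#' diagnosis (vegetative state or minimally conscious state), gender, age,
#' duration of impaired consciousness, etiology, and Coma Recovery
#' Scale-Revised score. Used for the demographic computations and as fixture
#' metadata for worked examples.
#'
#' @return Tibble with one row per patient.
#' @export
#' @examples
#' demographic_summary(pdoc_demographics())
pdoc_demographics <- function() {
  tibble::tibble(
    patient = paste("Patient", 1:18),
    diagnosis = c("VS", "VS", "VS", "VS", "VS", "VS", "VS", "VS", "VS",
                  "MCS", "MCS", "VS", "MCS", "VS", "VS", "VS", "VS", "MCS"),
    gender = c("M", "M", "M", "M", "M", "M", "M", "M", "F",
               "M", "M", "F", "F", "M", "M", "F", "M", "M"),
    age = c(57, 55, 60, 64, 47, 41, 60, 31, 45,
            65, 48, 23, 45, 44, 59, 50, 46, 21),
    duration_months = c(2.8, 3.4, 2.3, 2.2, 2.8, 19.9, 2.8, 25.2, 15.5,
                        4.0, 1.7, 7.6, 6.4, 3.1, 8.2, 2.3, 4.1, 14.2),
    etiology = c("Stroke", "TBI", "Anoxic", "Stroke", "Stroke", "Stroke",
                 "Anoxic", "Anoxic", "Anoxic", "TBI", "Stroke", "TBI",
                 "TBI", "TBI", "Stroke", "Stroke", "TBI", "Anoxic"),
    crs_r = c(6, 6, 6, 5, 4, 5, 5, 7, 7, 16, 14, 7, 14, 6, 7, 7, 5, 11)
  )
}
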