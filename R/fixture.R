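# pinned SHA-256 of the transcribed verification table; any drift in the
# packaged file is a hard error
.table2_sha256 <- "db1a57f5cb7ba123707393bf96d2ae567701dc251dd207789dcf4042c63e3515"

#' Load the packaged 20-patient verification cohort
#'
#' The verification cohort of 20 ultrasound-confirmed fistulas with flow
#' volume, resistance index and HVSI per patient, transcribed verbatim from
#' the published table. Its checksum is pinned so transcription drift fails
#' loudly. The `flagged_by_cutoff` and two `matching_*` columns are kept as
#' annotations only — the cutoffs that generated them are not fully specified
#' at the source, so no computation in this package consumes them.
#'
#' @return A 20-row data frame with columns `id`, `age`, `sex`,
#'   `anastomosis_type`, `bifurcation`, `flow_volume`, `resistance_index`,
#'   `hvsi`, plus the verbatim annotation columns.
#' @examples
#' v <- load_verification_fixture()
#' range(v$hvsi)
#' @export
load_verification_fixture <- function() {
  path <- system.file("extdata", "table2_verification.csv", package = "hvsi",
                      mustWork = TRUE)
  if (!identical(digest::digest(readLines(path), algo = "sha256"),
                 .table2_sha256))
    stop("verification fixture checksum mismatch - file has been altered",
         call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(raw) == 20L)
  data.frame(
    id = raw$number,
    age = raw$age,
    sex = factor(tolower(raw$gender), levels = c("female", "male")),
    anastomosis_type = raw$anastomosis_type,
    bifurcation = raw$vessel_bifurcation == "Yes",
    flow_volume = raw$flow_volume,
    resistance_index = raw$resistance_index,
    hvsi = raw$hvsi,
    flagged_by_cutoff = raw$flagged_by_cutoff == "Yes",
    matching_fv_hvsi = raw$matching_fv_hvsi == "Yes",
    matching_vaivt_hvsi = raw$matching_vaivt_hvsi == "Yes",
    stringsAsFactors = FALSE
  )
}

#' Run the verification-cohort reproduction
#'
#' Applies the predefined screening cutoff (HVSI <= 121) against the
#' ultrasound reference FV < 400 mL/min on the packaged cohort and reports
#' the resulting confusion counts, accuracy metrics and concordance.
#'
#' @param cutoff Predefined decision cutoff (score units).
#' @param reference Reference rule string.
#' @return List with `counts`, `metrics` (percent), `concordance`, `cutoff`,
#'   `reference`.
#' @export
verify_cutoff <- function(cutoff = 121, reference = "fv<400") {
  recs <- load_verification_fixture()
  test <- as.logical(classify_hvsi(recs$hvsi, cutoff))
  counts <- confusion(recs, test, reference)
  list(counts = counts,
       metrics = accuracy_metrics(counts),
       concordance = concordance(recs, test, reference),
       cutoff = cutoff, reference = reference)
}
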