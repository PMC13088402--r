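.cohort_required_cols <- c("id", "flow_volume", "resistance_index", "hvsi",
                           "bifurcation", "group")

#' Read a patient-cohort CSV
#'
#' Requires the schema columns `id`, `flow_volume`, `resistance_index`,
#' `hvsi`, `bifurcation`, `group`; unknown columns pass through untouched.
#' HVSI range and RI bounds are validated with row numbers in the message.
#'
#' @param path CSV path (UTF-8, comma separator, header row).
#' @return Data frame of patient records.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.cohort_required_cols, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(df$hvsi < 0 | df$hvsi > 999)
  if (length(bad))
    stop("hvsi out of [0, 999] in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- which(df$resistance_index < 0 | df$resistance_index > 1)
  if (length(bad))
    stop("resistance_index out of [0, 1] in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(df$flow_volume <= 0)
  if (length(bad))
    stop("flow_volume must be > 0 in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.character(df$bifurcation))
    df$bifurcation <- tolower(df$bifurcation) %in% c("true", "yes", "1")
  df$group <- factor(df$group, levels = c("control", "stenosis"))
  if (anyNA(df$group))
    stop("group must be 'control' or 'stenosis'", call. = FALSE)
  df
}

#' Write a patient-cohort CSV
#'
#' Round-trip stable with [read_cohort_csv()] on the schema fields.
#'
#' @param records Patient-record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' Serializes any report list together with provenance (package version,
#' timestamp, and whatever `config`/`seed`/`calibration_id` the caller
#' supplies inside the report).
#'
#' @param report Named list.
#' @param path Output path (`""` for stdout).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  report$provenance <- c(report$provenance,
                         list(package = "hvsi",
                              version = as.character(
                                utils::packageVersion("hvsi"))))
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
  if (identical(path, "")) cat(json, "\n") else writeLines(json, path)
  invisible(path)
}
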