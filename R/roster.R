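#' Read a breast roster table
#'
#' Reads the per-breast clinical roster (CSV, UTF-8, header required)
#' with columns `breast_index`, `patient_index`, `age`, `side`,
#' `breast_type`, `inclusion_position`, `inclusion_dimension`,
#' `final_assessment`.  Dash placeholders (en/em dash or `-`) and empty
#' cells are normalized to `NA`; the literal strings `"Not Available"`
#' and `"More Areas"` are kept (they carry information for zone
#' comparison: present but unusable).
#'
#' The packaged fixture `system.file("extdata", "roster.csv", package =
#' "mwibreast")` transcribes the 61-breast feasibility-study roster.
#'
#' @param path CSV file path.
#' @return A `data.frame` of class `mwi_roster`, one row per breast.
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  required <- c("breast_index", "patient_index", "age", "side",
                "breast_type", "inclusion_position",
                "inclusion_dimension", "final_assessment")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("roster is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  dashes <- c("-", "–", "—", "")
  for (col in c("inclusion_position", "inclusion_dimension",
                "final_assessment")) {
    v <- trimws(df[[col]])
    v[v %in% dashes] <- NA
    df[[col]] <- v
  }

  for (col in c("breast_index", "patient_index", "age")) {
    v <- suppressWarnings(as.integer(trimws(df[[col]])))
    bad <- which(is.na(v))
    if (length(bad) > 0)
      stop(sprintf("roster row %d: unparseable %s '%s'",
                   bad[1], col, df[[col]][bad[1]]), call. = FALSE)
    df[[col]] <- v
  }
  if (anyDuplicated(df$breast_index))
    stop("duplicate breast_index in roster", call. = FALSE)
  if (any(df$age < 18 | df$age > 100))
    stop(sprintf("roster row %d: age out of range",
                 which(df$age < 18 | df$age > 100)[1]), call. = FALSE)
  bad_type <- which(!df$breast_type %in% c("NF", "WF"))
  if (length(bad_type) > 0)
    stop(sprintf("roster row %d: breast_type must be NF or WF", bad_type[1]),
         call. = FALSE)
  class(df) <- c("mwi_roster", "data.frame")
  df
}

#' Summary statistics of a roster
#'
#' Totals, the rounded mean age, per-band row counts (the published
#' summary labels the bands "patients" but its counts sum to the number
#' of breasts, so bands count roster rows here), and the malignant
#' count.
#'
#' @param roster A roster from [read_roster()].
#' @return List with `n_breasts`, `n_patients`, `mean_age`,
#'   `age_20_49`, `age_50_80`, `n_nf`, `n_wf`, `n_malignant`,
#'   `n_benign`.
#' @export
roster_stats <- function(roster) {
  if (nrow(roster) == 0) stop("empty roster", call. = FALSE)
  list(
    n_breasts = nrow(roster),
    n_patients = length(unique(roster$patient_index)),
    mean_age = round(mean(roster$age)),
    age_20_49 = sum(roster$age >= 20 & roster$age <= 49),
    age_50_80 = sum(roster$age >= 50 & roster$age <= 80),
    n_nf = sum(roster$breast_type == "NF"),
    n_wf = sum(roster$breast_type == "WF"),
    n_malignant = sum(roster$final_assessment == "Malignant", na.rm = TRUE),
    n_benign = sum(roster$final_assessment == "Benign", na.rm = TRUE)
  )
}

#' Gold labels of a roster
#'
#' `"MF"` for breasts whose final assessment is malignant, `"NF+BF"`
#' otherwise.
#'
#' @param roster A roster from [read_roster()].
#' @return Character vector aligned with the roster rows.
#' @export
roster_labels <- function(roster) {
  ifelse(!is.na(roster$final_assessment) &
           roster$final_assessment == "Malignant", "MF", "NF+BF")
}
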