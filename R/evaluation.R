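#' Confusion matrix with MF as the positive class
#'
#' @param pred,gold Aligned character vectors of labels, values `"MF"`
#'   or `"NF+BF"`.
#' @return Object of class `mwi_confusion`: list with `tp`, `fn`, `fp`,
#'   `tn`.
#' @export
confusion <- function(pred, gold) {
  if (length(pred) != length(gold))
    stop("pred and gold lengths differ", call. = FALSE)
  ok <- c("MF", "NF+BF")
  if (!all(pred %in% ok) || !all(gold %in% ok))
    stop("labels must be 'MF' or 'NF+BF'", call. = FALSE)
  structure(list(
    tp = sum(pred == "MF" & gold == "MF"),
    fn = sum(pred == "NF+BF" & gold == "MF"),
    fp = sum(pred == "MF" & gold == "NF+BF"),
    tn = sum(pred == "NF+BF" & gold == "NF+BF")
  ), class = "mwi_confusion")
}

#' @export
print.mwi_confusion <- function(x, ...) {
  cat(sprintf("          gold MF  gold NF+BF\npred MF      %4d        %4d\npred NF+BF   %4d        %4d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Sensitivity and specificity in percent
#'
#' `sensitivity = 100 * TP / (TP + FN)`,
#' `specificity = 100 * TN / (TN + FP)`; both classes must be
#' represented in the gold standard.
#'
#' @param cm An [confusion()] matrix.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
sensitivity_specificity <- function(cm) {
  stopifnot(inherits(cm, "mwi_confusion"))
  if (cm$tp + cm$fn == 0 || cm$tn + cm$fp == 0)
    stop("metric undefined: a gold class is empty", call. = FALSE)
  c(sensitivity = 100 * cm$tp / (cm$tp + cm$fn),
    specificity = 100 * cm$tn / (cm$tn + cm$fp))
}

#' Lesion-zone agreement
#'
#' Fraction of comparable breasts whose predicted upper/lower zone
#' matches the reference zone.  Reference entries other than
#' `"upper"`/`"lower"` (e.g. "More Areas", "Not Available", missing) are
#' excluded from the comparison.
#'
#' @param pred_zones Character vector of predicted zones (`"upper"`,
#'   `"lower"`, or `NA`).
#' @param gold_zones Aligned reference zones; `"Upper Zone"`/
#'   `"Lower Zone"` are accepted and normalized.
#' @return List with `agreement` (fraction in \[0, 1\]), `matched` and
#'   `comparable` counts.
#' @export
zone_agreement <- function(pred_zones, gold_zones) {
  if (length(pred_zones) != length(gold_zones))
    stop("zone vectors differ in length", call. = FALSE)
  norm <- function(z) {
    z <- tolower(trimws(as.character(z)))
    z[z == "upper zone"] <- "upper"
    z[z == "lower zone"] <- "lower"
    z[!z %in% c("upper", "lower")] <- NA
    z
  }
  g <- norm(gold_zones)
  p <- norm(pred_zones)
  comparable <- !is.na(g) & !is.na(p)
  if (!any(comparable))
    stop("no comparable zone entries", call. = FALSE)
  matched <- sum(p[comparable] == g[comparable])
  list(agreement = matched / sum(comparable),
       matched = matched, comparable = sum(comparable))
}
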