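#' Gaussian smoothing parameters
#'
#' @param sigma Kernel standard deviation in pixels (default 30, i.e.
#'   30 mm on the 1 mm grid).
#' @param truncation Kernel half-width in sigmas (default 4).
#' @param padding Boundary handling; only `"replicate"` (edge-value)
#'   padding is provided.
#' @export
smoothing_params <- function(sigma = 30, truncation = 4,
                             padding = "replicate") {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (truncation < 2) stop("truncation must be >= 2", call. = FALSE)
  padding <- match.arg(padding, "replicate")
  structure(list(sigma = sigma, truncation = truncation, padding = padding),
            class = "mwi_smoothing")
}

## 1D convolution along matrix columns with replicate padding,
## implemented as a dense band-matrix product (the kernel half-width,
## 120 px at the defaults, is comparable to the image itself, so FFT
## tricks with circular padding are not applicable)
.conv_cols_replicate <- function(x, kernel) {
  h <- (length(kernel) - 1L) / 2L
  n <- nrow(x)
  idx <- c(rep(1L, h), seq_len(n), rep(n, h))
  xp <- x[idx, , drop = FALSE]
  K <- matrix(0, n, n + 2L * h)
  for (i in seq_len(n)) K[i, i:(i + 2L * h)] <- kernel
  K %*% xp
}

#' Smooth an intensity map with a 2D Gaussian kernel
#'
#' Separable Gaussian convolution with replicate (edge-value) padding;
#' the kernel is normalized so constant images are fixed points.
#' Non-negativity is preserved.
#'
#' @param map Cartesian `mwi_map` or plain matrix.
#' @param params A [smoothing_params()].
#' @return Same type as the input, smoothed.
#' @export
gaussian_smooth <- function(map, params = smoothing_params()) {
  m <- if (inherits(map, "mwi_map")) map$values else map
  stopifnot(is.matrix(m), all(is.finite(m)))
  h <- as.integer(ceiling(params$truncation * params$sigma))
  kernel <- stats::dnorm(-h:h, sd = params$sigma)
  kernel <- kernel / sum(kernel)
  sm <- .conv_cols_replicate(m, kernel)
  sm <- t(.conv_cols_replicate(t(sm), kernel))
  sm <- pmax(sm, 0)   # guard against tiny negative round-off
  if (inherits(map, "mwi_map")) {
    out <- map
    out$values <- sm
    out
  } else sm
}

#' Quartile summary of a map's pixel intensities
#'
#' Q1/Q2/Q3 of the masked pixel multiset using the linear-interpolation
#' quantile estimator (`stats::quantile` type 7), plus Tukey 1.5 IQR
#' whiskers.
#'
#' @param map Cartesian `mwi_map` or matrix.
#' @param mask Logical matrix of pixels to summarize; defaults to the
#'   in-disc pixels for an `mwi_map`.
#' @param breast_id Identifier copied into the summary.
#' @return Object of class `mwi_boxplot`: list with `breast_id`, `q1`,
#'   `q2`, `q3`, `whisker_low`, `whisker_high`.
#' @examples
#' intensity_quartiles(matrix(1:5, 1))  # q1 = 2, q2 = 3, q3 = 4
#' @export
intensity_quartiles <- function(map, mask = NULL, breast_id = NULL) {
  if (inherits(map, "mwi_map")) {
    if (is.null(mask)) mask <- disc_mask(map)
    if (is.null(breast_id)) breast_id <- map$breast_id
    v <- map$values[mask]
  } else {
    v <- if (is.null(mask)) c(map) else map[mask]
  }
  if (length(v) == 0) stop("empty pixel mask", call. = FALSE)
  q <- unname(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo <- min(v[v >= q[1] - 1.5 * iqr])
  hi <- max(v[v <= q[3] + 1.5 * iqr])
  structure(list(breast_id = breast_id, q1 = q[1], q2 = q[2], q3 = q[3],
                 whisker_low = lo, whisker_high = hi),
            class = "mwi_boxplot")
}

#' Cohort quartile threshold
#'
#' The decision threshold is the average of the two group means of Q3:
#' `theta = (mean(Q3 | NF+BF) + mean(Q3 | MF)) / 2`.
#'
#' @param summaries List of [intensity_quartiles()] summaries.
#' @param labels Character vector of gold labels, `"MF"` or `"NF+BF"`,
#'   aligned with `summaries`; both groups must be non-empty.
#' @param direction `"above"` (default): a breast is called MF when its
#'   median exceeds the threshold; `"below"` flips the rule.
#' @return Object of class `mwi_threshold` with `theta`,
#'   `mean_q3_nfbf`, `mean_q3_mf` and `direction`.
#' @export
cohort_threshold <- function(summaries, labels, direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (length(summaries) != length(labels))
    stop("summaries and labels lengths differ", call. = FALSE)
  if (!all(labels %in% c("MF", "NF+BF")))
    stop("labels must be 'MF' or 'NF+BF'", call. = FALSE)
  q3 <- vapply(summaries, `[[`, numeric(1), "q3")
  if (!any(labels == "MF") || !any(labels == "NF+BF"))
    stop("both groups must be non-empty", call. = FALSE)
  m_nfbf <- mean(q3[labels == "NF+BF"])
  m_mf <- mean(q3[labels == "MF"])
  structure(list(theta = (m_nfbf + m_mf) / 2,
                 mean_q3_nfbf = m_nfbf, mean_q3_mf = m_mf,
                 direction = direction),
            class = "mwi_threshold")
}

#' Classify one breast from its quartile summary
#'
#' Under the default direction a breast is labeled `"MF"` when its
#' median intensity Q2 strictly exceeds the threshold; ties go to
#' `"NF+BF"`.
#'
#' @param summary An [intensity_quartiles()] summary.
#' @param threshold An [cohort_threshold()] object (or a number, taken
#'   as theta with direction `"above"`).
#' @return `"MF"` or `"NF+BF"`.
#' @export
classify_breast <- function(summary, threshold) {
  q2 <- if (inherits(summary, "mwi_boxplot")) summary$q2 else summary
  if (inherits(threshold, "mwi_threshold")) {
    theta <- threshold$theta
    direction <- threshold$direction
  } else {
    theta <- threshold
    direction <- "above"
  }
  mf <- if (direction == "above") q2 > theta else q2 < theta
  if (mf) "MF" else "NF+BF"
}

#' Smooth, summarize and classify a cohort of intensity maps
#'
#' The full non-parametric thresholding chain: each map is smoothed
#' (Gaussian, replicate padding), summarized by its in-disc quartiles,
#' the Q3-average threshold is fitted on the gold labels (supervised, as
#' in the source protocol) or taken from `threshold`, and each breast is
#' classified by the median rule.
#'
#' @param maps List of Cartesian `mwi_map` objects (or matrices).
#' @param labels Gold labels ("MF" / "NF+BF"), required when fitting.
#' @param smoothing A [smoothing_params()].
#' @param direction Decision direction, see [cohort_threshold()].
#' @param threshold Optional fixed `mwi_threshold` for held-out
#'   application; when given, `labels` are not used for fitting.
#' @return List with `summaries`, `threshold`, and `predicted` labels.
#' @export
classify_cohort <- function(maps, labels = NULL,
                            smoothing = smoothing_params(),
                            direction = "above", threshold = NULL) {
  summaries <- lapply(seq_along(maps), function(i) {
    m <- maps[[i]]
    sm <- gaussian_smooth(m, smoothing)
    intensity_quartiles(sm, breast_id = if (inherits(m, "mwi_map"))
      m$breast_id else i)
  })
  if (is.null(threshold)) {
    if (is.null(labels))
      stop("labels are required to fit the threshold", call. = FALSE)
    threshold <- cohort_threshold(summaries, labels, direction = direction)
  }
  predicted <- vapply(summaries, classify_breast, character(1),
                      threshold = threshold)
  list(summaries = summaries, threshold = threshold, predicted = predicted)
}
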