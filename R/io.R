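#' Write / read an S21 dataset as CSV
#'
#' Plain tabular interchange format: one row per sample with columns
#' `n` (receiver), `m` (section), `p` (doublet position), `f_hz`
#' (frequency) and the complex value split into `re`/`im`.  Values are
#' written with full double precision so a round trip is exact.
#'
#' @param s21 An `mwi_s21` dataset.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_s21_csv <- function(s21, path) {
  stopifnot(inherits(s21, "mwi_s21"))
  d <- dim(s21$values)
  g <- expand.grid(n = seq_len(d[1]), m = seq_len(d[2]),
                   p = seq_len(d[3]), i = seq_len(d[4]))
  df <- data.frame(n = g$n, m = g$m, p = g$p,
                   f_hz = s21$geometry$frequencies[g$i],
                   re = Re(c(s21$values)), im = Im(c(s21$values)))
  utils::write.csv(format(df, digits = 17, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_s21_csv
#' @param geometry The acquisition geometry the file was recorded with
#'   (the CSV itself only stores indices and frequencies).
#' @export
read_s21_csv <- function(path, geometry) {
  df <- utils::read.csv(path)
  d <- c(max(df$n), max(df$m), max(df$p),
         length(unique(df$f_hz)))
  vals <- array(0 + 0i, dim = d)
  fidx <- match(df$f_hz, sort(unique(df$f_hz)))
  vals[cbind(df$n, df$m, df$p, fidx)] <- complex(real = df$re,
                                                 imaginary = df$im)
  structure(list(values = vals, geometry = geometry), class = "mwi_s21")
}

#' Write / read an intensity map as CSV
#'
#' The matrix is stored as plain CSV (no header); polar axes or the
#' Cartesian pixel size go to a small YAML sidecar `<path>.meta.yaml`.
#'
#' @param map An `mwi_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "mwi_map"))
  utils::write.table(format(map$values, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(kind = map$kind, max_radius = map$max_radius,
               pixel = map$pixel, conductivity = map$conductivity,
               breast_id = map$breast_id,
               radii = map$radii, az_deg = map$az_deg)
  yaml::write_yaml(meta[!vapply(meta, is.null, logical(1))],
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  vals <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(vals) <- NULL
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else
    list(kind = "cartesian", max_radius = 0.07, pixel = 0.001)
  intensity_map_new(vals, kind = meta$kind,
                    radii = unlist(meta$radii), az_deg = unlist(meta$az_deg),
                    max_radius = meta$max_radius %||% 0.07,
                    pixel = meta$pixel %||% 0.001,
                    conductivity = meta$conductivity %||% NA_real_,
                    breast_id = meta$breast_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an intensity map as 32-bit float TIFF
#'
#' @param map An `mwi_map` (Cartesian).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(map, path) {
  stopifnot(inherits(map, "mwi_map"))
  tiff::writeTIFF(map$values / max(max(map$values), .Machine$double.eps),
                  path, bits.per.sample = 32L)
  invisible(path)
}

#' Write a PCNN mask stack as a multi-page TIFF
#'
#' One 8-bit page per iteration.
#'
#' @param stack A `pcnn_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "pcnn_stack"))
  tiff::writeTIFF(stack$masks, path, bits.per.sample = 8L)
  invisible(path)
}

#' Export cohort summaries and labels as CSV
#'
#' @param result A [classify_cohort()] result.
#' @param labels Optional gold labels to include.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summaries_csv <- function(result, path, labels = NULL) {
  df <- data.frame(
    breast_id = vapply(result$summaries, function(s)
      as.character(s$breast_id %||% NA), character(1)),
    q1 = vapply(result$summaries, `[[`, numeric(1), "q1"),
    q2 = vapply(result$summaries, `[[`, numeric(1), "q2"),
    q3 = vapply(result$summaries, `[[`, numeric(1), "q3"),
    predicted = result$predicted,
    theta = result$threshold$theta
  )
  if (!is.null(labels)) df$gold <- labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
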