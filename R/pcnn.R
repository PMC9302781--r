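#' Parameters of the simplified pulse-coupled neural network
#'
#' One neuron per pixel.  Each iteration computes the feeding channel
#' `F = S` (the normalized stimulus), the linking channel
#' `L = W * O_prev` (weighted sum of the neighbors' previous firings),
#' the internal activity `U = F * (1 + beta * L)`, fires `O = 1` where
#' `U > T_prev`, and updates the threshold
#' `T = exp(-alpha_t) * T_prev + v_t * O`.  A fired neuron's threshold
#' jumps by `v_t` and then decays exponentially, so firing sweeps from
#' the brightest structures to progressively dimmer ones.
#'
#' With the default `v_t = 20`, `alpha_t = 0.2` and a stimulus in
#' \[0, 1\], the initial threshold `t0 = 2` decays to 0.90 at iteration 5:
#' the fifth binary mask is the first firing wave and captures the
#' highest-intensity structure, which is the iteration used for lesion
#' localization.  Setting `t0 = 0` instead makes every positive-stimulus
#' neuron fire at iteration 1.
#'
#' @param beta Linking strength (>= 0), default 3.
#' @param alpha_t Threshold decay constant (> 0), default 0.2.
#' @param v_t Threshold normalization constant (> 0), default 20.
#' @param w 3x3 linking kernel; default inverse Euclidean distance to
#'   each neighbor with a zero center.
#' @param n_iter Number of iterations, default 32.
#' @param t0 Initial threshold (>= 0), default 2.
#' @param selected_iteration Iteration whose mask is used downstream
#'   (1-based), default 5.
#' @return Object of class `pcnn_params`.
#' @export
pcnn_params <- function(beta = 3, alpha_t = 0.2, v_t = 20,
                        w = NULL, n_iter = 32, t0 = 2,
                        selected_iteration = min(5, n_iter)) {
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (alpha_t <= 0) stop("alpha_t must be > 0", call. = FALSE)
  if (v_t <= 0) stop("v_t must be > 0", call. = FALSE)
  if (t0 < 0) stop("t0 must be >= 0", call. = FALSE)
  if (n_iter < 1 || selected_iteration < 1 || selected_iteration > n_iter)
    stop("need n_iter >= selected_iteration >= 1", call. = FALSE)
  if (is.null(w)) {
    d <- sqrt(outer((-1:1)^2, (-1:1)^2, "+"))
    w <- ifelse(d > 0, 1 / d, 0)
  }
  if (!is.matrix(w) || nrow(w) %% 2 != 1 || ncol(w) %% 2 != 1 || any(w < 0))
    stop("w must be an odd-sized non-negative matrix", call. = FALSE)
  structure(list(beta = beta, alpha_t = alpha_t, v_t = v_t, w = w,
                 n_iter = as.integer(n_iter), t0 = t0,
                 selected_iteration = as.integer(selected_iteration)),
            class = "pcnn_params")
}

#' Normalize an intensity map into a PCNN stimulus
#'
#' Min-max normalization of the in-disc pixels to \[0, 1\];
#' outside-disc pixels are set to 0.  A constant map has zero range and
#' yields an all-zero stimulus with a warning.
#'
#' @param map Cartesian `mwi_map`, or a plain matrix (then `mask` is
#'   required or defaults to all pixels).
#' @param mask Optional logical matrix of pixels to normalize over.
#' @return Numeric matrix in \[0, 1\].
#' @export
normalize_input <- function(map, mask = NULL) {
  if (inherits(map, "mwi_map")) {
    if (is.null(mask)) mask <- disc_mask(map)
    m <- map$values
  } else {
    m <- map
    if (is.null(mask)) mask <- matrix(TRUE, nrow(m), ncol(m))
  }
  stopifnot(all(is.finite(m)))
  v <- m[mask]
  rng <- range(v)
  out <- matrix(0, nrow(m), ncol(m))
  if (diff(rng) <= 0) {
    warning("constant map: stimulus is identically zero")
    return(out)
  }
  out[mask] <- (v - rng[1]) / diff(rng)
  out
}

#' Linking field
#'
#' `L[i,j] = sum_{(k,l) in N(i,j)} w[k,l] * o_prev[k,l]`; border neurons
#' use only their in-bounds neighbors (zero padding).
#'
#' @param o_prev Binary matrix of previous firings.
#' @param params A [pcnn_params()].
#' @return Numeric matrix of the same shape.
#' @export
linking_field <- function(o_prev, params = pcnn_params()) {
  w <- params$w
  hr <- (nrow(w) - 1L) / 2L
  hc <- (ncol(w) - 1L) / 2L
  nr <- nrow(o_prev); nc <- ncol(o_prev)
  L <- matrix(0, nr, nc)
  for (di in -hr:hr) {
    for (dj in -hc:hc) {
      wt <- w[di + hr + 1L, dj + hc + 1L]
      if (wt == 0) next
      ri <- max(1L, 1L - di):min(nr, nr - di)
      ci <- max(1L, 1L - dj):min(nc, nc - dj)
      L[ri, ci] <- L[ri, ci] + wt * o_prev[ri + di, ci + dj]
    }
  }
  L
}

#' Initialize the PCNN state
#'
#' @param s Stimulus matrix in \[0, 1\] (see [normalize_input()]).
#' @param params A [pcnn_params()].
#' @return Object of class `pcnn_state` with lattices `s`, `f`, `l`,
#'   `u`, `t`, `o` and the iteration counter `n = 0`.
#' @export
pcnn_init <- function(s, params = pcnn_params()) {
  stopifnot(is.matrix(s), all(is.finite(s)), all(s >= 0), all(s <= 1))
  z <- matrix(0, nrow(s), ncol(s))
  structure(list(s = s, f = s, l = z, u = z,
                 t = matrix(params$t0, nrow(s), ncol(s)),
                 o = z, n = 0L),
            class = "pcnn_state")
}

#' Advance the PCNN by one iteration
#'
#' @param state A `pcnn_state`.
#' @param params A [pcnn_params()].
#' @return The state at iteration `n + 1`.
#' @export
pcnn_step <- function(state, params = pcnn_params()) {
  stopifnot(inherits(state, "pcnn_state"))
  f <- state$s
  l <- linking_field(state$o, params)
  u <- f * (1 + params$beta * l)
  o <- (u > state$t) * 1
  t_new <- exp(-params$alpha_t) * state$t + params$v_t * o
  structure(list(s = state$s, f = f, l = l, u = u, t = t_new, o = o,
                 n = state$n + 1L),
            class = "pcnn_state")
}

#' Run the PCNN over an intensity map
#'
#' Normalizes the map, iterates the network `n_iter` times and collects
#' one binary mask per iteration.  The network has no randomness:
#' identical inputs give identical stacks.
#'
#' @param map Cartesian `mwi_map` or a stimulus matrix already in
#'   \[0, 1\].
#' @param params A [pcnn_params()].
#' @param mask Optional normalization mask (see [normalize_input()]).
#' @return Object of class `pcnn_stack`: list with `masks` (list of
#'   binary matrices, one per iteration), `selected` (index), `params`
#'   and the stimulus `s`.
#' @export
run_pcnn <- function(map, params = pcnn_params(), mask = NULL) {
  s <- if (inherits(map, "mwi_map")) normalize_input(map, mask)
       else { stopifnot(is.matrix(map)); map }
  st <- pcnn_init(s, params)
  masks <- vector("list", params$n_iter)
  for (k in seq_len(params$n_iter)) {
    st <- pcnn_step(st, params)
    masks[[k]] <- st$o
  }
  structure(list(masks = masks, selected = params$selected_iteration,
                 params = params, s = s),
            class = "pcnn_stack")
}

#' Select a mask from a PCNN stack
#'
#' Iterations are numbered 1-based; the default selection is the fifth
#' iteration.
#'
#' @param stack A `pcnn_stack`.
#' @param k Iteration index; defaults to the stack's selected iteration.
#' @return Binary matrix.
#' @export
select_mask <- function(stack, k = stack$selected) {
  stopifnot(inherits(stack, "pcnn_stack"))
  if (k < 1 || k > length(stack$masks))
    stop("iteration index out of range", call. = FALSE)
  stack$masks[[k]]
}

#' Connected lesion regions of a binary mask
#'
#' 8-connected component labeling (two-pass union-find).  Components
#' smaller than `min_area` are discarded; the rest are returned sorted
#' by area, largest first.
#'
#' @param mask Binary matrix.
#' @param min_area Minimum component area in pixels (default 5,
#'   suppressing single-pixel speckle).
#' @return List of regions; each a list with `pixels` (two-column
#'   row/col matrix), `centroid` (row, col), and `area`.
#' @export
extract_regions <- function(mask, min_area = 5) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  lab <- .label8(mask)
  ids <- setdiff(unique(c(lab)), 0L)
  regs <- lapply(ids, function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    list(pixels = unname(px),
         centroid = c(row = mean(px[, 1]), col = mean(px[, 2])),
         area = nrow(px))
  })
  regs <- Filter(function(r) r$area >= min_area, regs)
  regs[order(vapply(regs, `[[`, numeric(1), "area"), decreasing = TRUE)]
}

## two-pass 8-connected labeling with union-find
.label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (mask[i, j] == 0) next
      nb <- integer(0)
      if (i > 1L && mask[i - 1L, j] == 1) nb <- c(nb, lab[i - 1L, j])
      if (j > 1L) {
        if (mask[i, j - 1L] == 1) nb <- c(nb, lab[i, j - 1L])
        if (i > 1L && mask[i - 1L, j - 1L] == 1) nb <- c(nb, lab[i - 1L, j - 1L])
        if (i < nr && mask[i + 1L, j - 1L] == 1) nb <- c(nb, lab[i + 1L, j - 1L])
      }
      if (length(nb) == 0) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[i, j] <- nxt
      } else {
        roots <- vapply(nb, find, integer(1))
        r <- min(roots)
        lab[i, j] <- r
        for (q in roots) parent[q] <- r
      }
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    dense <- match(roots, sort(unique(roots)))
    pos <- lab > 0L
    lab[pos] <- dense[lab[pos]]
  }
  lab
}

#' Assign a lesion region to the upper or lower zone
#'
#' The coronal map is split at the center row: a region whose centroid
#' row is above the center (smaller row index) is "upper", below is
#' "lower"; a centroid exactly on the center row counts as upper.
#'
#' @param region A region from [extract_regions()].
#' @param image_shape Integer vector (rows, cols) of the mask.
#' @return `"upper"` or `"lower"`.
#' @export
assign_zone <- function(region, image_shape) {
  ctr <- (image_shape[1] + 1) / 2
  if (region$centroid[["row"]] <= ctr) "upper" else "lower"
}

#' Localize the lesion region of an intensity map
#'
#' Runs the PCNN, takes the selected-iteration mask, extracts its
#' 8-connected regions and picks the region containing the strongest
#' stimulus (among regions of at least `min_area` pixels; if none
#' reaches `min_area`, the largest region is used).  Returns the region
#' with its zone, or `NULL` for an empty mask.
#'
#' @param map Cartesian `mwi_map`.
#' @param params A [pcnn_params()].
#' @param min_area Minimum region area in pixels.
#' @return A region list with an added `zone` element, or `NULL`.
#' @export
localize_lesion <- function(map, params = pcnn_params(), min_area = 5) {
  stack <- run_pcnn(map, params)
  msk <- select_mask(stack)
  regs <- extract_regions(msk, min_area = min_area)
  if (length(regs) == 0) regs <- extract_regions(msk, min_area = 1)
  if (length(regs) == 0) return(NULL)
  peak <- vapply(regs, function(r) max(stack$s[r$pixels]), numeric(1))
  reg <- regs[[which.max(peak)]]
  reg$zone <- assign_zone(reg, dim(msk))
  reg
}
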