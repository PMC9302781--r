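## Independent reference implementations used as oracles.

## Scalar, loop-based PCNN reference: one neuron at a time, no
## vectorization.  Kernel contributions accumulate in (row offset,
## column offset) order so floating-point sums are comparable exactly.
pcnn_reference <- function(s, params) {
  nr <- nrow(s); nc <- ncol(s)
  w <- params$w
  hr <- (nrow(w) - 1) / 2
  o <- matrix(0, nr, nc)
  tt <- matrix(params$t0, nr, nc)
  out <- vector("list", params$n_iter)
  for (iter in seq_len(params$n_iter)) {
    l <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      acc <- 0
      for (di in -hr:hr) for (dj in -hr:hr) {
        wt <- w[di + hr + 1, dj + hr + 1]
        if (wt == 0) next
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
          acc <- acc + wt * o[ii, jj]
      }
      l[i, j] <- acc
    }
    u <- s * (1 + params$beta * l)
    o_new <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc))
      if (u[i, j] > tt[i, j]) o_new[i, j] <- 1
    tt <- exp(-params$alpha_t) * tt + params$v_t * o_new
    o <- o_new
    out[[iter]] <- list(f = s, l = l, u = u, t = tt, o = o_new)
  }
  out
}

## Naive stack-based flood fill, 8-connectivity.
floodfill_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (mask[i0, j0] == 0 || seen[i0, j0]) next
    stack <- list(c(i0, j0))
    seen[i0, j0] <- TRUE
    px <- NULL
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      px <- rbind(px, p)
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] == 1 && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1]] <- c(ii, jj)
        }
      }
    }
    comps[[length(comps) + 1]] <- px
  }
  comps
}

## Frozen reference values from an independent implementation of the
## Hankel functions (SciPy 1.17 special.hankel1 / hankel2).
hankel_reference <- list(
  list(z = 0.1 + 0i,
       h1 = complex(real = 0.9975015620660401, imaginary = -1.5342386513503667),
       h2 = complex(real = 0.9975015620660401, imaginary = 1.5342386513503667)),
  list(z = 1.5 + 0i,
       h1 = complex(real = 0.5118276717359181, imaginary = 0.38244892379775886),
       h2 = complex(real = 0.5118276717359181, imaginary = -0.38244892379775886)),
  list(z = 7.3 + 0i,
       h1 = complex(real = 0.2882169476350144, imaginary = 0.0627738863740376),
       h2 = complex(real = 0.2882169476350144, imaginary = -0.0627738863740376)),
  list(z = 12 + 0i,
       h1 = complex(real = 0.04768931079683357, imaginary = -0.2252373126343615),
       h2 = complex(real = 0.04768931079683357, imaginary = 0.2252373126343615)),
  list(z = 25 + 0i,
       h1 = complex(real = 0.09626678327595814, imaginary = -0.12724943226800617),
       h2 = complex(real = 0.09626678327595814, imaginary = 0.12724943226800617)),
  list(z = 80 + 0i,
       h1 = complex(real = -0.06974216551221005, imaginary = -0.055620339089770016),
       h2 = complex(real = -0.06974216551221005, imaginary = 0.055620339089770016)),
  list(z = 0.5 - 0.4i,
       h1 = complex(real = 1.4919326210031671, imaginary = -0.1908381013066641),
       h2 = complex(real = 0.45835761242153283, imaginary = 0.38854128063001486)),
  list(z = 3 - 2.5i,
       h1 = complex(real = -4.111578134200581, imaginary = 2.863705411569171),
       h2 = complex(real = -0.008826014583227473, imaginary = -0.031244368710897544)),
  list(z = 10 - 8i,
       h1 = complex(real = -663.8821887012033, imaginary = -79.50450053660515),
       h2 = complex(real = -6.318562643725524e-05, imaginary = -3.91589697998893e-05)),
  list(z = 20 - 15i,
       h1 = complex(real = 405944.51278972934, imaginary = 330087.8500010745),
       h2 = complex(real = 4.862978862572966e-08, imaginary = -1.91650768199256e-09)),
  list(z = 2 - 11i,
       h1 = complex(real = -4779.900868690522, imaginary = 13639.508548309122),
       h2 = complex(real = 3.427565312659922e-06, imaginary = -1.950160307458275e-06))
)

## Small decimated geometry used by reconstruction tests.
test_geometry <- function(freq_step = 2e9, ...) {
  build_geometry(freq_step = freq_step, ...)
}

roster_path <- function() {
  system.file("extdata", "roster.csv", package = "mwibreast")
}
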