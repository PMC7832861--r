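# Internal image utilities shared by the tracker and the coating analysis.

# Otsu's threshold on a numeric vector (256-bin histogram between min and max).
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) stop("cannot threshold a constant image")
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)),
                nbins = nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[nbins]
  # between-class variance for each candidate split
  bc <- (mt * w0 - m0)^2 / (w0 * (1 - w0))
  bc[!is.finite(bc)] <- 0
  mids[which.max(bc)]
}

# Connected-component labelling of a logical 2D or 3D mask with
# face-connectivity (4-neighbour in 2D, 6-neighbour in 3D). Breadth-first
# flood fill on coordinate matrices; masks in this package are small.
label_components <- function(mask) {
  dims <- dim(mask)
  nd <- length(dims)
  stopifnot(nd %in% c(2L, 3L))
  labels <- array(0L, dims)
  idx <- which(mask)
  if (length(idx) == 0L) return(labels)
  offs <- if (nd == 2L) {
    rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
          c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  }
  lab <- 0L
  for (seed in idx) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    labels[seed] <- lab
    frontier <- arrayInd(seed, dims)
    while (nrow(frontier) > 0L) {
      cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(j)
        sweep(frontier, 2L, offs[j, ], "+")))
      keep <- rep(TRUE, nrow(cand))
      for (d in seq_len(nd)) {
        keep <- keep & cand[, d] >= 1L & cand[, d] <= dims[d]
      }
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand) == 0L) break
      lin <- cand[, 1L]
      if (nd >= 2L) lin <- lin + (cand[, 2L] - 1L) * dims[1L]
      if (nd == 3L) lin <- lin + (cand[, 3L] - 1L) * dims[1L] * dims[2L]
      new <- !duplicated(lin) & mask[lin] & labels[lin] == 0L
      cand <- cand[new, , drop = FALSE]
      lin <- lin[new]
      labels[lin] <- lab
      frontier <- cand
    }
  }
  labels
}

# Interquartile range with the default (type 7) linearly interpolated
# order statistics; the convention matters for small cells and is stated
# in the docs of the functions that report IQRs.
iqr7 <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] - q[1]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
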