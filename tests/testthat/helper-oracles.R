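# Independent brute-force oracles used to cross-check the grid primitives,
# plus small fixture builders. All fixtures are generated in code.

# Pure-R flood-fill labeling; returns the largest component as a 0/1 array,
# ties broken by smallest linear index (seeds visited in linear order).
flood_fill_largest <- function(arr, connectivity = 26) {
  d <- dim(arr)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  man <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[man == 1, , drop = FALSE],
                 "18" = offs[man >= 1 & man <= 2, , drop = FALSE],
                 "26" = offs[man >= 1, , drop = FALSE])
  lab <- array(0L, d)
  nextlab <- 0L
  for (seed in which(arr == 1L)) {
    if (lab[seed] != 0L) next
    nextlab <- nextlab + 1L
    queue <- seed
    lab[seed] <- nextlab
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- arrayInd(v, d)
      for (i in seq_len(nrow(offs))) {
        nb <- co + offs[i, ]
        if (any(nb < 1L) || any(nb > d)) next
        w <- nb[1] + d[1] * (nb[2] - 1) + d[1] * d[2] * (nb[3] - 1)
        if (arr[w] == 1L && lab[w] == 0L) {
          lab[w] <- nextlab
          queue <- c(queue, w)
        }
      }
    }
  }
  if (nextlab == 0L) stop("empty mask")
  sizes <- tabulate(lab[lab > 0])
  array(as.integer(lab == which.max(sizes)), d)
}

# Brute-force dilation: union of per-voxel structuring-element translates.
dilate_oracle <- function(arr, element = "cross6") {
  d <- dim(arr)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  if (element == "cross6") offs <- offs[rowSums(abs(offs)) <= 1, , drop = FALSE]
  out <- array(0L, d)
  for (v in which(arr == 1L)) {
    co <- arrayInd(v, d)
    for (i in seq_len(nrow(offs))) {
      nb <- co + offs[i, ]
      if (any(nb < 1L) || any(nb > d)) next
      out[nb] <- 1L
    }
  }
  out
}

# Linear-interpolation percentile from its definition.
percentile_oracle <- function(values, q) {
  v <- sort(values)
  n <- length(v)
  if (n == 1L) return(v)
  idx <- (n - 1) * q / 100
  lo <- floor(idx)
  hi <- ceiling(idx)
  v[lo + 1] + (idx - lo) * (v[hi + 1] - v[lo + 1])
}

random_mask <- function(d, p = 0.3) {
  array(as.integer(stats::runif(prod(d)) < p), d)
}

# Small, fast phantom for unit tests (32^3 grid).
tiny_phantom_params <- function(seed = 1L, ...) {
  phantom_params(grid_shape = c(32, 32, 32), chiasm_width = 5,
                 nerve_width = 3.5, seed = seed, ...)
}
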