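# internal helpers

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards (so package randomness never perturbs
# the user's RNG stream).
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Translate a matrix by integer pixel offsets, zero-filling exposed borders.
# dx > 0 moves content right (toward higher columns); dy > 0 moves content up
# (toward lower row indices, since row 1 is the top).
.shift_matrix <- function(m, dx, dy, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  dr <- -as.integer(dy)  # +dy (up) decreases row index of content
  dc <- as.integer(dx)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  if (any(ok_r) && any(ok_c))
    out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

# 3x3 convolution with edge-replication padding (constant frames are fixed
# points; interior impulse response sums to the kernel sum).
.conv3x3 <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  # pad by edge replication
  p <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  out <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2)
    out <- out + k[di + 1, dj + 1] * p[di + seq_len(nr), dj + seq_len(nc)]
  out
}

.norm2 <- function(v) sqrt(sum(v^2))
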