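# Exact Euclidean distance transform on the cell lattice (Felzenszwalb &
# Huttenlocher two-pass lower-envelope algorithm). Distances are between
# cell centres, returned squared and in cell units, so comparisons across
# class-wise transforms are exact integer arithmetic.

.BIG <- 1e12

.dt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (p in 1:n) {
    while (z[k + 1L] < p) k <- k + 1L
    d[p] <- (p - v[k])^2 + f[v[k]]
  }
  d
}

# mask: logical matrix; TRUE = source cell. Returns squared cell distance
# to the nearest TRUE cell (0 on sources, >= .BIG when no source exists).
.edt_squared <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  f <- matrix(.BIG, nr, nc)
  f[mask] <- 0
  for (j in seq_len(nc)) f[, j] <- .dt1d(f[, j])
  for (i in seq_len(nr)) f[i, ] <- .dt1d(f[i, ])
  f
}
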