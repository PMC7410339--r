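# Exact rational arithmetic on num/den pairs stored as doubles.
#
# Network compression (row reduction, lump scaling) is brittle in floating
# point, so stoichiometric coefficients are rationalized once (tolerance
# 1e-9) and all compression arithmetic is exact. Numerators/denominators of
# desk-scale models stay far below 2^53, where doubles are exact integers.

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- b; b <- a %% b; a <- t }
  a
}

# continued-fraction rational approximation of a scalar
rat_approx <- function(x, tol = 1e-9, max_den = 1e9) {
  if (!is.finite(x)) stop("cannot rationalize a non-finite value")
  sign <- if (x < 0) -1 else 1
  x <- abs(x)
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1; b <- x
  repeat {
    a <- floor(b)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > max_den) break
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    if (abs(x - h / k) < tol * max(1, abs(x))) break
    if (abs(b - a) < 1e-15) break
    b <- 1 / (b - a)
  }
  list(num = sign * h1, den = k1)
}

# reduce num/den vectors in place
rat_reduce <- function(n, d) {
  stopifnot(all(d != 0))
  s <- ifelse(d < 0, -1, 1)
  n <- n * s; d <- d * s
  g <- mapply(rat_gcd, abs(n), d)
  g[g < 0.5] <- 1
  list(n = n / g, d = d / g)
}

rat_add <- function(n1, d1, n2, d2) rat_reduce(n1 * d2 + n2 * d1, d1 * d2)
rat_mul <- function(n1, d1, n2, d2) rat_reduce(n1 * n2, d1 * d2)
rat_div <- function(n1, d1, n2, d2) {
  stopifnot(all(n2 != 0))
  rat_reduce(n1 * d2, d1 * n2)
}

# rational matrix: list(n = numerators, d = denominators), both matrices
rmat <- function(M, tol = 1e-9) {
  fr <- lapply(as.vector(M), rat_approx, tol = tol)
  list(n = matrix(vapply(fr, `[[`, 0, "num"), nrow(M), ncol(M), dimnames = dimnames(M)),
       d = matrix(vapply(fr, `[[`, 0, "den"), nrow(M), ncol(M), dimnames = dimnames(M)))
}

rmat_to_numeric <- function(R) R$n / R$d

# indices of rows of a rational matrix that are linear combinations of
# earlier rows (conservation relations), by exact Gauss-Jordan elimination
dependent_rows <- function(R) {
  n <- R$n; d <- R$d
  m <- nrow(n); nc <- ncol(n)
  pivot_of_row <- rep(NA_integer_, m)
  dep <- logical(m)
  prow_idx <- integer(0)
  for (i in seq_len(m)) {
    # eliminate existing pivots from row i
    for (pi in prow_idx) {
      pc <- pivot_of_row[pi]
      if (n[i, pc] == 0) next
      f <- rat_div(n[i, pc], d[i, pc], n[pi, pc], d[pi, pc])
      for (j in seq_len(nc)) {
        if (n[pi, j] == 0) next
        t <- rat_mul(f$n, f$d, n[pi, j], d[pi, j])
        s <- rat_add(n[i, j], d[i, j], -t$n, t$d)
        n[i, j] <- s$n; d[i, j] <- s$d
      }
    }
    nz <- which(n[i, ] != 0)
    if (length(nz) == 0L) {
      dep[i] <- TRUE
    } else {
      pivot_of_row[i] <- nz[1]
      prow_idx <- c(prow_idx, i)
    }
  }
  which(dep)
}
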