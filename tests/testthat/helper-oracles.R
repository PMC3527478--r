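# Independent brute-force oracles, kept deliberately naive: direct formula
# evaluation with loops, no shared code with the package internals.

oracle_shannon <- function(x) {
  p <- x / sum(x)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi)
  h
}

oracle_bray <- function(a, b) {
  num <- 0
  den <- 0
  for (i in seq_along(a)) {
    num <- num + abs(a[i] - b[i])
    den <- den + a[i] + b[i]
  }
  num / den
}

oracle_hellinger_dist <- function(a, b) {
  pa <- a / sum(a)
  pb <- b / sum(b)
  s <- 0
  for (i in seq_along(a)) s <- s + (sqrt(pa[[i]]) - sqrt(pb[[i]]))^2
  sqrt(s)
}

# closed-form simple OLS
oracle_ols <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  b <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  a <- my - b * mx
  yhat <- a + b * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - my)^2)
  list(slope = b, intercept = a, r_squared = r2)
}

# CCA oracle: forms the weighted projection explicitly (dense hat matrix via
# solve()) and eigen-decomposes crossprod of the fitted chi-square matrix
# with a generic dense solver.
oracle_cca_eigenvalues <- function(Y, X) {
  P <- Y / sum(Y)
  r <- rowSums(P)
  cm <- colSums(P)
  Q <- matrix(0, nrow(Y), ncol(Y))
  for (i in seq_len(nrow(Y))) {
    for (j in seq_len(ncol(Y))) {
      Q[i, j] <- (P[i, j] - r[i] * cm[j]) / sqrt(r[i] * cm[j])
    }
  }
  Xc <- sweep(X, 2, colSums(X * r))
  Xc <- sweep(Xc, 2, sqrt(colSums(Xc^2 * r)), "/")
  Xw <- Xc * sqrt(r)
  H <- Xw %*% solve(t(Xw) %*% Xw) %*% t(Xw)
  Qhat <- H %*% Q
  ev <- eigen(t(Qhat) %*% Qhat, symmetric = TRUE)$values
  sort(ev[ev > 1e-10], decreasing = TRUE)
}

# random valid fingerprint fixture
random_fingerprint <- function(n_samples, n_bands, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rexp(n_samples * n_bands), n_samples, n_bands)
  m[m < 0.3] <- 0
  m[rowSums(m) == 0, 1] <- 1
  rownames(m) <- sprintf("s%02d", seq_len(n_samples))
  colnames(m) <- sprintf("b%02d", seq_len(n_bands))
  as_fingerprint(m)
}

# minimal metadata for a one-site series
series_metadata <- function(sample_ids, dates, site = "A", texture = "sandy") {
  tibble::tibble(
    sample_id = sample_ids,
    site_id = site,
    date = as.Date(dates),
    replicate = 1L,
    texture = texture
  )
}
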