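test_that("hellinger transform yields unit-norm rows of sqrt relative abundance", {
  h <- band_matrix(hellinger_transform(as_fingerprint(rbind(
    s1 = c(4, 0),
    s2 = c(1, 1)
  ))))
  expect_equal(unname(h["s1", ]), c(1, 0))
  u <- band_matrix(hellinger_transform(as_fingerprint(rbind(s = c(1, 1, 1, 1)))))
  expect_equal(unname(u[1, ]), rep(0.5, 4))
  expect_equal(rowSums(h^2), c(s1 = 1, s2 = 1))
  expect_error(
    hellinger_transform(as_fingerprint(rbind(s = c(0, 0)))),
    class = "lagbeta_domain_error"
  )
})

test_that("distance matrices are symmetric, zero-diagonal, and match the pair oracle", {
  fp <- random_fingerprint(5, 7, seed = 11)
  for (metric in c("hellinger", "bray_curtis")) {
    d <- community_distance(fp, metric)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 5))
    m <- band_matrix(fp)
    oracle <- if (metric == "hellinger") oracle_hellinger_dist else oracle_bray
    mm <- if (metric == "hellinger") m else m / rowSums(m)
    for (i in 1:4) {
      for (j in (i + 1):5) {
        ref <- if (metric == "hellinger") oracle(m[i, ], m[j, ]) else oracle(mm[i, ], mm[j, ])
        expect_equal(d[i, j], unname(ref), tolerance = 1e-12)
      }
    }
  }
  # disjoint profiles reach the Hellinger maximum sqrt(2)
  disj <- as_fingerprint(rbind(s1 = c(1, 0, 0), s2 = c(0, 1, 0)))
  expect_equal(community_distance(disj)["s1", "s2"], sqrt(2))
  # duplicated profile rows are at distance zero
  dup <- as_fingerprint(rbind(a = c(1, 2), b = c(2, 4), c = c(1, 5)))
  expect_equal(community_distance(dup)["a", "b"], 0)
})

test_that("lag pairs enumerate unordered date pairs on the sqrt scale", {
  d4 <- matrix(1, 4, 4) - diag(4)
  dates4 <- as.Date(c("2009-04-15", "2009-06-15", "2009-09-15", "2009-11-15"))
  p <- lag_pairs(d4, dates4)
  expect_equal(nrow(p), 6)

  d11 <- matrix(1, 11, 11) - diag(11)
  p11 <- lag_pairs(d11, seq(as.Date("2009-04-15"), by = "month", length.out = 11))
  expect_equal(nrow(p11), 55)

  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  jan_apr <- as.Date(c("2010-01-15", "2010-04-15"))
  p2 <- lag_pairs(d2, jan_apr, time_unit = "months")
  expect_equal(p2$sqrt_lag, sqrt(as.numeric(diff(jan_apr)) / 30.44))
  expect_equal(p2$distance, 0.3)

  expect_error(lag_pairs(d2, rep(as.Date("2010-01-15"), 2)),
    class = "lagbeta_validation_error"
  )
})

test_that("time-lag regression recovers exact lines and matches the OLS oracle", {
  x <- sqrt(c(1, 2, 3, 5, 8, 13))
  pairs <- tibble::tibble(sqrt_lag = x, distance = 0.2 + 0.5 * x)
  fit <- fit_tla(pairs)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  flat <- tibble::tibble(sqrt_lag = x, distance = rep(0.4, 6))
  ffit <- fit_tla(flat)
  expect_equal(ffit$slope, 0, tolerance = 1e-12)
  expect_equal(ffit$r_squared, 0, tolerance = 1e-12)

  set.seed(21)
  for (i in 1:10) {
    px <- sqrt(runif(8, 0.5, 20))
    py <- runif(8)
    f <- fit_tla(tibble::tibble(sqrt_lag = px, distance = py))
    o <- oracle_ols(px, py)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(f$r_squared, o$r_squared, tolerance = 1e-10)
  }

  expect_error(fit_tla(pairs[1:2, ]), class = "lagbeta_insufficient_data_error")
  expect_error(
    fit_tla(tibble::tibble(sqrt_lag = rep(1, 4), distance = runif(4))),
    class = "lagbeta_degenerate_design_error"
  )
})

test_that("rescaling distances rescales slope/intercept and preserves R2 and p-values", {
  set.seed(31)
  pairs <- tibble::tibble(sqrt_lag = sqrt(1:10), distance = runif(10))
  f1 <- fit_tla(pairs, n_perm = 99, seed = 7)
  pairs2 <- dplyr::mutate(pairs, distance = distance * 3.7)
  f2 <- fit_tla(pairs2, n_perm = 99, seed = 7)
  expect_equal(f2$slope, 3.7 * f1$slope, tolerance = 1e-12)
  expect_equal(f2$intercept, 3.7 * f1$intercept, tolerance = 1e-12)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
  expect_equal(f2$p_parametric, f1$p_parametric, tolerance = 1e-12)
  expect_equal(f2$p_permutation, f1$p_permutation)
})

test_that("TLA output is invariant under reversing the time axis", {
  sim <- simulate_dataset(scenario_presets()$desk_small, seed = 4)
  t1 <- tla(sim$fingerprint, sim$metadata)
  md_rev <- sim$metadata
  # reflect dates about the series midpoint (reverses temporal order)
  md_rev$date <- as.Date(max(md_rev$date) - as.numeric(md_rev$date - min(md_rev$date)))
  t2 <- tla(sim$fingerprint, md_rev)
  expect_equal(t1$slope, t2$slope, tolerance = 1e-10)
  expect_equal(t1$r_squared, t2$r_squared, tolerance = 1e-10)
})

test_that("pooled overall TLA equals OLS on the concatenated pairs", {
  sim <- simulate_dataset(scenario_presets()$directional, seed = 8)
  res <- tla(sim$fingerprint, sim$metadata)
  pairs <- tla_pairs(sim$fingerprint, sim$metadata)
  o <- oracle_ols(pairs$sqrt_lag, pairs$distance)
  ov <- res[res$group == "overall", ]
  expect_equal(ov$slope, o$slope, tolerance = 1e-10)
  expect_equal(ov$r_squared, o$r_squared, tolerance = 1e-10)
  expect_equal(ov$n_pairs, sum(res$n_pairs[res$group != "overall"]))

  # a single site pools to itself
  one_site <- sim$metadata[sim$metadata$site_id == "S1", ]
  fp1 <- sim$fingerprint[sim$fingerprint$sample_id %in% one_site$sample_id, ]
  r1 <- tla(fp1, one_site)
  expect_equal(r1$slope[r1$group == "S1"], r1$slope[r1$group == "overall"])
})

test_that("permutation p is uniform on its support for exchangeable pairs", {
  # iid pairs: both schemes reduce to an exact test; check the empirical CDF
  set.seed(77)
  n_rep <- 400
  n_perm <- 39
  p <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    pr <- tibble::tibble(sqrt_lag = sqrt(1:8), distance = rnorm(8))
    p[i] <- fit_tla(pr, n_perm = n_perm, scheme = "shuffle")$p_permutation
  }
  # support is k/(n_perm+1); mean should be near (1 + support)/2
  expect_gt(mean(p), 0.45)
  expect_lt(mean(p), 0.60)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 1e-3)
})

test_that("tla_fit methods expose tidy, glance and a plot", {
  pairs <- tibble::tibble(sqrt_lag = sqrt(1:6), distance = 0.1 + 0.2 * sqrt(1:6))
  fit <- fit_tla(pairs)
  td <- generics::tidy(fit)
  expect_equal(td$estimate[td$term == "sqrt_lag"], 0.2, tolerance = 1e-12)
  gl <- generics::glance(fit)
  expect_equal(gl$n_pairs, 6)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
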