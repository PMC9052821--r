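test_that("Friedman test matches the rank formula and a permutation null", {
  ## constant matrix: no rank variation
  flat <- friedman_test(matrix(5, 4, 3))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  ## perfect concordance, k = 3, n = 3: chi2 = 12n/(k(k+1)) * sum((Rbar-2)^2) = 6
  m <- rbind(c(1, 5, 9), c(2, 4, 8), c(0.5, 3, 7))
  r <- friedman_test(m)
  expect_equal(r$statistic, 6)
  expect_equal(r$dof, 2)
  expect_equal(r$p_value, pchisq(6, 2, lower.tail = FALSE))

  ## permutation-null oracle on 5 x 4 matrices.  In the decision-relevant
  ## tail the chi-squared p agrees with the permutation null to better than
  ## 0.01 absolute; in the middle of the null the agreement is bounded by
  ## the discreteness of the exact distribution at this sample size.
  perm_p <- function(x, nperm = 1e5) {
    ranks <- t(apply(x, 1, rank))
    perms <- matrix(unlist(combinat_perms(4)), ncol = 4, byrow = TRUE)
    idx <- matrix(sample.int(nrow(perms), 5 * nperm, replace = TRUE), nperm, 5)
    total <- matrix(0, nperm, 4)
    for (i in 1:5) {
      contrib_i <- matrix(ranks[i, t(perms)], ncol = 4, byrow = TRUE)
      total <- total + contrib_i[idx[, i], ]
    }
    stats <- 12 * 5 / (4 * 5) * rowSums((total / 5 - 2.5)^2)
    obs <- 12 * 5 / (4 * 5) * sum((colMeans(ranks) - 2.5)^2)
    mean(stats >= obs - 1e-12)
  }
  strong <- with_fixed_seed(9, matrix(rnorm(20, sd = 1.2), 5, 4) +
                              matrix(rep(c(0, 1, 2, 3), each = 5), 5, 4))
  obs_s <- friedman_test(strong)
  p_s <- with_fixed_seed(22, perm_p(strong))
  expect_lt(abs(p_s - obs_s$p_value), 0.01)
  x <- with_fixed_seed(21, matrix(rnorm(20), 5, 4))
  obs <- friedman_test(x)
  p_m <- with_fixed_seed(23, perm_p(x))
  expect_lt(abs(p_m - obs$p_value), 0.12)

  ## invariance under monotone transforms of each subject's row
  y <- t(apply(x, 1, function(row) exp(2 * row) + 1))
  expect_equal(friedman_test(y)$statistic, obs$statistic)
  expect_error(friedman_test(matrix(1, 1, 3)), "subjects")
})

test_that("Wilcoxon signed-rank p-values match enumeration; Holm adjusts correctly", {
  ## n = 5, all differences positive (tie-free): two-sided exact p = 2/32
  r1 <- wilcoxon_holm(list(list(c(3, 5, 2.5, 6, 4.5), c(1, 2, 1, 2, 2))))
  expect_equal(r1[[1]]$p_value, 0.0625)
  expect_equal(r1[[1]]$adjusted_p, r1[[1]]$p_value)  # Holm with m = 1

  ## enumeration oracle for a random n = 8 pattern
  d <- c(1.3, -0.4, 2.1, 0.9, -1.7, 0.6, 3.0, -0.2)
  got <- wilcoxon_holm(list(list(d, numeric(8))))[[1]]
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
  v_all <- signs %*% rk
  ev <- sum(rk) / 2
  p_enum <- mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-12)
  expect_equal(got$p_value, p_enum)

  ## Holm step-down arithmetic across a family
  fam <- with_fixed_seed(23, lapply(1:3, function(i)
    list(rnorm(12, mean = 0.8 * i), rnorm(12))))
  res <- wilcoxon_holm(fam)
  raw <- vapply(res, `[[`, numeric(1), "p_value")
  o <- order(raw)
  manual <- raw
  manual[o] <- cummax(pmin(1, (3:1) * raw[o]))
  expect_equal(vapply(res, `[[`, numeric(1), "adjusted_p"), manual)
  ## Holm never decreases a p-value and preserves order
  expect_true(all(manual >= raw))
  expect_true(all(diff(manual[o]) >= 0))

  expect_error(wilcoxon_holm(list(list(1:4, 1:4))), "undefined-test")
  ## zero differences are dropped per convention
  rz <- wilcoxon_holm(list(list(c(5, 5, 7, 9, 6), c(5, 5, 2, 3, 2))))
  expect_equal(rz[[1]]$n_nonzero, 3)
})

test_that("model-versus-measured regression matches closed-form OLS", {
  ex <- regress_model_vs_measured(c(-1, 0, 2), c(-1, 0, 2))
  expect_equal(ex$r_squared, 1)
  expect_equal(ex$rmse, 0)

  x <- c(0, 1, 2); y <- c(0, 1, 2.1)
  got <- regress_model_vs_measured(x, y)
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  res <- y - (ic + sl * x)
  expect_equal(got$slope, sl, tolerance = 1e-9)
  expect_equal(got$intercept, ic, tolerance = 1e-9)
  expect_equal(got$rmse, sqrt(mean(res^2)), tolerance = 1e-9)
  expect_equal(got$r_squared, 1 - sum(res^2) / sum((y - mean(y))^2),
               tolerance = 1e-9)

  ## iid noise of SD s around a perfect fit: residual RMSE approaches s
  s <- 0.7
  big <- with_fixed_seed(24, {
    xm <- rnorm(5000)
    regress_model_vs_measured(xm, xm + rnorm(5000, 0, s))
  })
  expect_lt(abs(big$rmse - s) / s, 0.05)
  expect_error(regress_model_vs_measured(rep(1, 5), rnorm(5)), "undefined-fit")
})
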