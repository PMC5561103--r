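test_that("Wald ratio and its delta SE behave in the exact and simulated regimes", {
  # exact when the exposure is noiseless
  w <- wald_ratio(1, 0, 0.5, 0.1)
  expect_equal(w$estimate, 0.5)
  expect_equal(w$se, 0.1)
  # null numerator
  w2 <- wald_ratio(0.1, 0.02, 0, 0.01)
  expect_equal(w2$estimate, 0)
  expect_equal(w2$se, 0.01 / 0.1)
  expect_error(wald_ratio(0, 0.02, 0.1, 0.01), "undefined")

  # simulation oracle: the delta SE matches the Monte-Carlo sd of the
  # ratio of normals when the instrument is strong, and the approximation
  # error shrinks as F grows
  set.seed(101)
  mc_sd <- function(bx, sx, by, sy, n = 1e6)
    sd(rnorm(n, by, sy) / rnorm(n, bx, sx))
  rel_err <- sapply(c(100, 400), function(F) {
    sx <- 0.1 / sqrt(F)
    abs(mc_sd(0.1, sx, 0.03, 0.01) / wald_ratio(0.1, sx, 0.03, 0.01)$se - 1)
  })
  expect_lt(rel_err[1], 0.03)
  expect_lt(rel_err[2], 0.01)
  expect_lt(rel_err[2], rel_err[1])
})

test_that("Fieller sets match a numeric root oracle and classify degenerate cases", {
  # strong-denominator limit reduces to the normal interval
  fs <- fieller_interval(0.1, 1e-9, 0.03, 0.01)
  expect_equal(fs$type, "finite")
  expect_equal(fs$low, 0.3 - qnorm(0.975) * 0.1, tolerance = 1e-6)
  expect_equal(fs$high, 0.3 + qnorm(0.975) * 0.1, tolerance = 1e-6)

  # weak denominator: A = bx^2 - z^2 sx^2 < 0 forces a non-finite set
  fs2 <- fieller_interval(0.05, 0.05, 0.02, 0.01)
  expect_lt(fs2$A, 0)
  expect_true(fs2$type %in% c("exclusive", "whole_line"))

  # numeric root oracle: the set boundary solves
  # (by - theta bx)^2 = z^2 (sy^2 + theta^2 sx^2)
  z <- qnorm(0.975)
  g <- function(theta, bx, sx, by, sy)
    (by - theta * bx)^2 - z^2 * (sy^2 + theta^2 * sx^2)
  set.seed(202)
  n_checked <- 0
  for (i in 1:100) {
    bx <- rnorm(1, 0, 0.1); sx <- runif(1, 0.002, 0.05)
    by <- rnorm(1, 0, 0.05); sy <- runif(1, 0.002, 0.05)
    fs <- fieller_interval(bx, sx, by, sy)
    th <- seq(-10, 10, length.out = 4001)
    gv <- g(th, bx, sx, by, sy)
    flips <- which(gv[-1] * gv[-length(gv)] < 0)
    roots <- sort(vapply(flips, function(k)
      uniroot(g, c(th[k], th[k + 1]), bx = bx, sx = sx, by = by, sy = sy,
              tol = 1e-12)$root, numeric(1)))
    if (fs$type == "whole_line") {
      expect_equal(length(roots), 0)
    } else if (length(roots) == 2) {
      expect_equal(c(fs$low, fs$high), roots, tolerance = 1e-7)
      # membership semantics: inside for finite, outside for exclusive
      mid <- mean(roots)
      expect_equal(g(mid, bx, sx, by, sy) <= 0, fs$type == "finite")
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 50)
})

test_that("fixed-effect IVW reduces to the Wald ratio and equals the WLS oracle", {
  h1 <- make_h(0.08, 0.006, 0.02, 0.012)
  e1 <- ivw_fixed(h1)
  expect_equal(e1$estimate, 0.02 / 0.08)
  expect_equal(e1$se, 0.012 / 0.08)

  h0 <- make_h(c(0.05, 0.08, 0.1), 0.006, c(0, 0, 0), 0.012)
  expect_equal(ivw_fixed(h0)$estimate, 0)

  # through-origin weighted regression oracle
  set.seed(33)
  h <- random_h(5)
  fit <- lm(beta_y ~ 0 + beta_x, data = h, weights = 1 / h$se_y^2)
  expect_equal(ivw_fixed(h)$estimate, unname(coef(fit)), tolerance = 1e-12)
})

test_that("correlated-variant IVW reduces to fixed-effect IVW and matches matrix algebra", {
  set.seed(44)
  h <- random_h(6)
  id <- diag(6)
  e_fix <- ivw_fixed(h)
  e_cor <- ivw_correlated(h, id)
  expect_equal(e_cor$estimate, e_fix$estimate, tolerance = 1e-12)
  expect_equal(e_cor$se, e_fix$se, tolerance = 1e-12)

  # two (nearly) duplicate variants are not double counted
  hd <- make_h(c(0.08, 0.08), 0.006, c(0.02, 0.02), 0.012)
  rho <- matrix(c(1, 0.9999, 0.9999, 1), 2)
  ed <- ivw_correlated(hd, rho)
  e1 <- ivw_fixed(make_h(0.08, 0.006, 0.02, 0.012))
  expect_equal(ed$estimate, e1$estimate, tolerance = 1e-3)
  expect_gte(ed$se, e1$se * 0.999)

  # direct matrix-algebra oracle on random valid instances
  for (i in 1:20) {
    m <- 6
    h <- random_h(m)
    A <- matrix(rnorm(m * m), m)
    rho <- cov2cor(crossprod(A) + diag(m))
    Omega <- outer(h$se_y, h$se_y) * rho
    oi <- solve(Omega)
    est <- drop(solve(t(h$beta_x) %*% oi %*% h$beta_x) %*%
                t(h$beta_x) %*% oi %*% h$beta_y)
    se <- sqrt(drop(solve(t(h$beta_x) %*% oi %*% h$beta_x)))
    got <- ivw_correlated(h, rho)
    expect_equal(got$estimate, est, tolerance = 1e-10)
    expect_equal(got$se, se, tolerance = 1e-10)
  }

  bad <- matrix(c(1, 1.5, 1.5, 1), 2)
  expect_error(ivw_correlated(make_h(c(0.1, 0.1), 0.006, c(0, 0), 0.01),
                              bad), "eigenvalue")
})

test_that("weighted median interpolates the weighted ratio distribution", {
  # equal weights: the plain median
  h <- make_h(c(1, 1, 1), 0, c(0.1, 0.2, 0.9), 1)
  expect_equal(weighted_median(h, n_boot = 10, seed = 1)$estimate, 0.2)

  # breakdown: one variant carrying almost all the weight dominates
  hw <- make_h(c(1, 1, 1), 0, c(0.1, 0.2, 0.9), c(10, 10, 0.01))
  expect_equal(weighted_median(hw, n_boot = 10, seed = 1)$estimate, 0.9,
               tolerance = 0.01)

  expect_error(weighted_median(make_h(c(1, 1), 0, c(0.1, 0.2), 1)),
               "at least 3")

  # CDF-scan oracle: grid search over the interpolated weighted CDF
  set.seed(55)
  for (i in 1:10) {
    m <- 10
    h <- random_h(m)
    ratio <- h$beta_y / h$beta_x
    w <- h$beta_x^2 / (h$se_y^2 + ratio^2 * h$se_x^2)
    o <- order(ratio); ratio <- ratio[o]; w <- w[o] / sum(w)
    pj <- cumsum(w) - w / 2
    grid <- seq(min(ratio), max(ratio), length.out = 200001)
    cdf <- approx(ratio, pj, xout = grid, rule = 2, ties = "ordered")$y
    oracle <- grid[which.min(abs(cdf - 0.5))]
    got <- weighted_median(h, n_boot = 2, seed = 1)$estimate
    # agreement up to the scan resolution of the grid oracle
    expect_lt(abs(got - oracle), 2 * diff(range(ratio)) / 2e5)
  }

  # the bootstrap SE is seed-reproducible
  h <- random_h(8)
  e1 <- weighted_median(h, n_boot = 200, seed = 9)
  e2 <- weighted_median(h, n_boot = 200, seed = 9)
  expect_identical(e1$se, e2$se)
})

test_that("MR-Egger recovers a noiseless slope/intercept and matches the WLS oracle", {
  # exact interpolation of a noiseless pleiotropic model
  bx <- c(0.03, 0.05, 0.08, 0.1, 0.12)
  h <- make_h(bx, 0.005, 0.3 * bx + 0.02, 0.01)
  eg <- mr_egger(h)
  expect_equal(eg$slope$estimate, 0.3, tolerance = 1e-12)
  expect_equal(eg$intercept$estimate, 0.02, tolerance = 1e-12)

  # weighted-least-squares normal-equations oracle on a fixed instance
  set.seed(66)
  h2 <- random_h(5)
  sgn <- sign(h2$beta_x)
  fit <- lm(I(sgn * beta_y) ~ I(sgn * beta_x), data = h2,
            weights = 1 / h2$se_y^2)
  eg2 <- mr_egger(h2)
  expect_equal(eg2$intercept$estimate, unname(coef(fit)[1]),
               tolerance = 1e-12)
  expect_equal(eg2$slope$estimate, unname(coef(fit)[2]), tolerance = 1e-12)

  # orientation step makes results invariant to per-variant allele flips
  flip <- c(1, -1, 1, -1, 1)
  h3 <- h2
  h3$beta_x <- h3$beta_x * flip; h3$beta_y <- h3$beta_y * flip
  eg3 <- mr_egger(h3)
  expect_equal(eg3$slope$estimate, eg2$slope$estimate)
  expect_equal(eg3$intercept$estimate, eg2$intercept$estimate)

  expect_error(mr_egger(make_h(c(0.1, 0.1, -0.1), 0.005,
                               c(0.01, 0.02, 0.01), 0.01)), "singular")
})

test_that("Cochran's Q has its closed forms and pairs with the IVW estimate", {
  # identical ratios: no heterogeneity
  h <- make_h(c(0.05, 0.1, 0.2), 0.005, c(0.015, 0.03, 0.06), 0.01)
  q <- cochran_q(h)
  expect_equal(q$Q, 0)
  expect_equal(q$pvalue, 1)
  expect_equal(q$df, 2L)

  # two equal-weight variants with ratios d apart: Q = w d^2 / 2
  s <- 0.02; d <- 0.15
  h2 <- make_h(c(1, 1), 0, c(0.1, 0.1 + d), s)
  expect_equal(cochran_q(h2)$Q, (1 / s^2) * d^2 / 2, tolerance = 1e-12)
})

test_that("estimators are scale- and sign-equivariant", {
  set.seed(77)
  h <- random_h(8)
  c_ <- 3.7
  hs <- h; hs$beta_y <- c_ * hs$beta_y; hs$se_y <- c_ * hs$se_y
  hf <- h; hf$beta_x <- -hf$beta_x
  for (f in list(function(x) ivw_fixed(x)$estimate,
                 function(x) weighted_median(x, 50, seed = 2)$estimate,
                 function(x) mr_egger(x)$slope$estimate)) {
    expect_equal(f(hs), c_ * f(h), tolerance = 1e-9)
    expect_equal(f(hf), -f(h), tolerance = 1e-9)
  }
  # scaling leaves Q (a pure heterogeneity statistic) unchanged
  expect_equal(cochran_q(hs)$Q, cochran_q(h)$Q, tolerance = 1e-9)
})

test_that("estimate_all assembles the method grid appropriate to the variant count", {
  set.seed(88)
  h <- random_h(8)
  res <- estimate_all(h, seed = 4, n_boot = 50)
  expect_setequal(res$method, c("ivw_fixed", "weighted_median",
                                "egger_slope", "egger_intercept"))
  expect_false(any(is.na(res$Q[res$method == "ivw_fixed"])))

  # two variants: pooled estimate plus Q only
  res2 <- estimate_all(random_h(2), seed = 4)
  expect_equal(res2$method, "ivw_fixed")
  # one variant: the Wald ratio with its Fieller interval where finite
  res1 <- estimate_all(make_h(0.08, 0.006, 0.02, 0.012))
  expect_equal(res1$method, "wald")
  fs <- fieller_interval(0.08, 0.006, 0.02, 0.012)
  expect_equal(res1$ci_low, fs$low)
  # with an LD matrix the pooled method switches to the GLS form
  rho <- simulate_ld_matrix(8, 2, 0.3)
  res3 <- estimate_all(h, rho = unname(rho), seed = 4, n_boot = 50)
  expect_true("ivw_correlated" %in% res3$method)
})
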