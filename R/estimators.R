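# Causal-effect estimators and diagnostics for two-sample MR:
# per-variant Wald ratios with delta-method SEs and Fieller confidence
# sets, fixed-effect IVW, generalized weighted regression for correlated
# variants, the weighted median, MR-Egger regression, and Cochran's Q.

.new_mr_estimate <- function(method, estimate, se, ci_low, ci_high, pvalue,
                             n_snps, ci_type = "finite", extra = NULL) {
  out <- c(list(method = method, estimate = estimate, se = se,
                ci_low = ci_low, ci_high = ci_high, ci_type = ci_type,
                pvalue = pvalue, n_snps = n_snps), extra)
  class(out) <- "mr_estimate"
  out
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: estimate %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g, %d SNP(s)\n",
              x$method, x$estimate, x$se, x$ci_low, x$ci_high, x$pvalue,
              x$n_snps))
  invisible(x)
}

.z_p <- function(estimate, se) {
  2 * stats::pnorm(-abs(estimate / se))
}

#' Wald ratio estimate for a single variant
#'
#' The per-variant causal estimate beta_Y / beta_X with the first-order
#' delta-method standard error
#' `|1/beta_X| * sqrt(se_Y^2 + estimate^2 * se_X^2)`.
#'
#' @param beta_x,se_x SNP-exposure effect and standard error (se_x >= 0)
#' @param beta_y,se_y SNP-outcome effect and positive standard error
#' @param alpha two-sided level for the normal CI; default 0.05
#' @return `mr_estimate` with method `"wald"`
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y, alpha = 0.05) {
  if (beta_x == 0) stop("wald_ratio(): beta_x = 0 gives an undefined ratio")
  if (se_y <= 0 || se_x < 0) stop("wald_ratio(): standard errors invalid")
  est <- beta_y / beta_x
  se <- sqrt(se_y^2 + est^2 * se_x^2) / abs(beta_x)
  z <- stats::qnorm(1 - alpha / 2)
  .new_mr_estimate("wald", est, se, est - z * se, est + z * se,
                   .z_p(est, se), 1L)
}

#' Fieller confidence set for a ratio of normal means
#'
#' The exact level-(1-alpha) confidence set
#' `{theta : (beta_Y - theta beta_X)^2 <= z^2 (se_Y^2 + theta^2 se_X^2)}`.
#' With `A = beta_X^2 - z^2 se_X^2`, `B = beta_X beta_Y`,
#' `C = beta_Y^2 - z^2 se_Y^2` and discriminant `B^2 - A C`:
#' a positive A with a nonnegative discriminant gives the familiar finite
#' interval `(B +/- sqrt(B^2 - A C)) / A`; a negative A with a nonnegative
#' discriminant gives the complement of an interval (an "exclusive"
#' unbounded set, arising when the denominator is not significantly
#' different from zero); a negative discriminant gives the whole real
#' line.
#'
#' @param beta_x,se_x numerator-side (exposure) mean and SE
#' @param beta_y,se_y denominator... outcome-side mean and SE
#' @param alpha two-sided level; default 0.05
#' @return list of class `fieller_set`: `type` in `"finite"`,
#'   `"exclusive"`, `"whole_line"`, `"half_line"`; `low`, `high` (the
#'   interval bounds for `"finite"`; the excluded open interval for
#'   `"exclusive"`; `-Inf`/`Inf` for `"whole_line"`), plus `A` and
#'   `discriminant`
#' @export
fieller_interval <- function(beta_x, se_x, beta_y, se_y, alpha = 0.05) {
  stopifnot(se_x > 0, se_y > 0, alpha > 0, alpha < 1)
  z2 <- stats::qnorm(1 - alpha / 2)^2
  A <- beta_x^2 - z2 * se_x^2
  B <- beta_x * beta_y
  C <- beta_y^2 - z2 * se_y^2
  disc <- B^2 - A * C
  out <- list(A = A, discriminant = disc)
  if (A == 0) {
    # boundary case: the quadratic degenerates to a linear inequality
    if (B == 0) {
      out$type <- "whole_line"; out$low <- -Inf; out$high <- Inf
    } else if (B > 0) {
      out$type <- "half_line"; out$low <- C / (2 * B); out$high <- Inf
    } else {
      out$type <- "half_line"; out$low <- -Inf; out$high <- C / (2 * B)
    }
  } else if (disc < 0) {
    out$type <- "whole_line"; out$low <- -Inf; out$high <- Inf
  } else {
    r <- sort(c((B - sqrt(disc)) / A, (B + sqrt(disc)) / A))
    if (A > 0) {
      out$type <- "finite"; out$low <- r[1]; out$high <- r[2]
    } else {
      out$type <- "exclusive"; out$low <- r[1]; out$high <- r[2]
    }
  }
  class(out) <- "fieller_set"
  out
}

#' @export
print.fieller_set <- function(x, ...) {
  msg <- switch(x$type,
    finite = sprintf("[%.4f, %.4f]", x$low, x$high),
    exclusive = sprintf("(-Inf, %.4f] U [%.4f, Inf) (weak denominator)",
                        x$low, x$high),
    half_line = sprintf("[%.4f, %.4f]", x$low, x$high),
    whole_line = "whole real line (uninformative)")
  cat("Fieller confidence set:", msg, "\n")
  invisible(x)
}

.ivw_weights <- function(h, second_order = FALSE) {
  if (second_order) {
    ratio <- h$beta_y / h$beta_x
    h$beta_x^2 / (h$se_y^2 + ratio^2 * h$se_x^2)
  } else {
    h$beta_x^2 / h$se_y^2
  }
}

#' Fixed-effect inverse-variance-weighted estimate
#'
#' Combines per-variant Wald ratios with weights
#' `w_j = beta_X_j^2 / se_Y_j^2` (first-order precision, the fixed-effect
#' IVW convention).  Equivalent to a weighted through-origin regression of
#' beta_Y on beta_X with weights `1/se_Y^2`.
#'
#' @param h harmonized table (see [harmonize()]), or any data.frame with
#'   `beta_x`, `se_x`, `beta_y`, `se_y`
#' @param alpha two-sided level; default 0.05
#' @param second_order use second-order (delta) Wald-ratio precision in the
#'   weights instead of the first-order convention; default FALSE
#' @return `mr_estimate` with method `"ivw_fixed"`
#' @export
ivw_fixed <- function(h, alpha = 0.05, second_order = FALSE) {
  if (nrow(h) < 1) stop("ivw_fixed(): at least one variant required")
  if (any(h$beta_x == 0))
    stop("ivw_fixed(): beta_x = 0 for ",
         paste(h$SNP[h$beta_x == 0], collapse = ", "),
         "; filter undefined ratios first")
  w <- .ivw_weights(h, second_order)
  ratio <- h$beta_y / h$beta_x
  est <- sum(w * ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- stats::qnorm(1 - alpha / 2)
  .new_mr_estimate("ivw_fixed", est, se, est - z * se, est + z * se,
                   .z_p(est, se), nrow(h))
}

#' IVW for correlated variants by generalized weighted regression
#'
#' Generalized least squares of beta_Y on beta_X through the origin with
#' error covariance `Omega_jk = se_Y_j se_Y_k rho_jk`, where rho is the
#' between-variant LD correlation:
#' `estimate = (bX' Omega^-1 bX)^-1 bX' Omega^-1 bY`,
#' `se = sqrt((bX' Omega^-1 bX)^-1)`.  Reduces to [ivw_fixed()] when rho is
#' the identity.
#'
#' @param h harmonized table
#' @param rho LD correlation matrix; if it has dimnames it is aligned to
#'   `h$SNP`, otherwise it must already be in row order
#' @param alpha two-sided level; default 0.05
#' @return `mr_estimate` with method `"ivw_correlated"`
#' @export
ivw_correlated <- function(h, rho, alpha = 0.05) {
  m <- nrow(h)
  if (!is.matrix(rho) || nrow(rho) != ncol(rho))
    stop("ivw_correlated(): rho must be a square matrix")
  if (!is.null(rownames(rho))) {
    if (!all(h$SNP %in% rownames(rho)))
      stop("ivw_correlated(): rho is missing variants: ",
           paste(setdiff(h$SNP, rownames(rho)), collapse = ", "))
    rho <- rho[h$SNP, h$SNP, drop = FALSE]
  } else if (nrow(rho) != m) {
    stop("ivw_correlated(): dimension mismatch: ", nrow(rho), " vs ", m,
         " variants")
  }
  if (max(abs(rho - t(rho))) > 1e-8)
    stop("ivw_correlated(): rho is not symmetric")
  Omega <- outer(h$se_y, h$se_y) * rho
  ch <- tryCatch(chol(Omega), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values)
    stop("ivw_correlated(): Omega not positive definite (smallest eigenvalue ",
         format(ev, digits = 4), ")")
  }
  # GLS through the Cholesky factor: whiten then ordinary least squares
  u <- backsolve(ch, cbind(h$beta_x, h$beta_y), transpose = TRUE)
  xtx <- sum(u[, 1]^2)
  est <- sum(u[, 1] * u[, 2]) / xtx
  se <- sqrt(1 / xtx)
  z <- stats::qnorm(1 - alpha / 2)
  .new_mr_estimate("ivw_correlated", est, se, est - z * se, est + z * se,
                   .z_p(est, se), m)
}

# weighted-median point estimate from ratios and (unnormalized) weights
.weighted_median_point <- function(ratio, w) {
  o <- order(ratio)
  ratio <- ratio[o]
  w <- w[o] / sum(w)
  cum <- cumsum(w) - w / 2
  if (0.5 <= cum[1]) return(ratio[1])
  if (0.5 >= cum[length(cum)]) return(ratio[length(ratio)])
  stats::approx(cum, ratio, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' The 50% point of the inverse-variance-weighted empirical distribution
#' of the per-variant Wald ratios: ratios are ordered, cumulative weight
#' midpoints `p_j = (S_j - w_j/2) / S_m` computed, and the ratio linearly
#' interpolated at p = 0.5.  Consistent even when up to half the weight
#' comes from invalid instruments.  The standard error is the standard
#' deviation of the estimate over `n_boot` parametric-bootstrap resamples
#' of (beta_X, beta_Y) from independent normals at their stated standard
#' errors.
#'
#' @param h harmonized table with at least 3 variants
#' @param n_boot bootstrap resamples for the SE; default 1000
#' @param seed integer seed for the bootstrap (required for
#'   reproducibility)
#' @param alpha two-sided level; default 0.05
#' @return `mr_estimate` with method `"weighted_median"`
#' @export
weighted_median <- function(h, n_boot = 1000, seed = NULL, alpha = 0.05) {
  m <- nrow(h)
  if (m < 3)
    stop("weighted_median(): at least 3 variants are required (got ", m, ")")
  stopifnot(n_boot >= 1)
  ratio <- h$beta_y / h$beta_x
  v <- (h$se_y^2 + ratio^2 * h$se_x^2) / h$beta_x^2
  est <- .weighted_median_point(ratio, 1 / v)
  if (!is.null(seed)) {
    # a seeded bootstrap must not disturb the caller's RNG stream
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  boot <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(m, h$beta_x, h$se_x)
    by <- stats::rnorm(m, h$beta_y, h$se_y)
    r <- by / bx
    vv <- (h$se_y^2 + r^2 * h$se_x^2) / bx^2
    .weighted_median_point(r, 1 / vv)
  }, numeric(1))
  se <- stats::sd(boot)
  z <- stats::qnorm(1 - alpha / 2)
  .new_mr_estimate("weighted_median", est, se, est - z * se, est + z * se,
                   .z_p(est, se), m)
}

#' MR-Egger regression
#'
#' Weighted linear regression of beta_Y on beta_X with a free intercept
#' and weights `1/se_Y^2`, after orienting every variant so beta_X > 0.
#' The slope estimates the causal effect under the InSIDE assumption
#' (pleiotropic effects independent of instrument strength); the intercept
#' estimates the average directional pleiotropic effect, and an intercept
#' p-value below 0.05 indicates directional pleiotropy.
#'
#' Coefficient standard errors use unit residual dispersion by default
#' (`dispersion = "fixed"`), consistent with the fixed-effect weighting of
#' the rest of the analysis; `dispersion = "estimated"` rescales them by
#' the multiplicative overdispersion factor `max(1, sigma_hat)`.  P-values
#' use the standard-normal reference by default; `reference = "t"` uses
#' Student's t with m - 2 degrees of freedom.
#'
#' @param h harmonized table with at least 3 variants
#' @param alpha two-sided level; default 0.05
#' @param dispersion `"fixed"` (default) or `"estimated"`
#' @param reference `"normal"` (default) or `"t"`
#' @return list with elements `slope` and `intercept`, both `mr_estimate`
#'   objects (methods `"egger_slope"`, `"egger_intercept"`)
#' @export
mr_egger <- function(h, alpha = 0.05, dispersion = c("fixed", "estimated"),
                     reference = c("normal", "t")) {
  dispersion <- match.arg(dispersion)
  reference <- match.arg(reference)
  m <- nrow(h)
  if (m < 3) stop("mr_egger(): at least 3 variants are required (got ", m, ")")
  sgn <- sign(h$beta_x)
  x <- h$beta_x * sgn
  y <- h$beta_y * sgn
  w <- 1 / h$se_y^2
  # weighted normal equations for (intercept, slope)
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  if (det <= .Machine$double.eps * sw * swxx)
    stop("mr_egger(): singular design (no spread in |beta_x|)")
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  var_slope <- sw / det
  var_int <- swxx / det
  scale2 <- 1
  if (dispersion == "estimated") {
    resid <- y - intercept - slope * x
    sigma2 <- sum(w * resid^2) / (m - 2)
    scale2 <- max(1, sigma2)
  }
  se_slope <- sqrt(var_slope * scale2)
  se_int <- sqrt(var_int * scale2)
  if (reference == "normal") {
    crit <- stats::qnorm(1 - alpha / 2)
    pfun <- function(est, se) 2 * stats::pnorm(-abs(est / se))
  } else {
    crit <- stats::qt(1 - alpha / 2, df = m - 2)
    pfun <- function(est, se) 2 * stats::pt(-abs(est / se), df = m - 2)
  }
  list(
    slope = .new_mr_estimate("egger_slope", slope, se_slope,
                             slope - crit * se_slope, slope + crit * se_slope,
                             pfun(slope, se_slope), m),
    intercept = .new_mr_estimate("egger_intercept", intercept, se_int,
                                 intercept - crit * se_int,
                                 intercept + crit * se_int,
                                 pfun(intercept, se_int), m))
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (ratio_j - theta_ivw)^2` with the fixed-effect IVW
#' weights `w_j = beta_X_j^2 / se_Y_j^2`; under homogeneity Q is
#' chi-squared with m - 1 degrees of freedom.
#'
#' @param h harmonized table with at least 2 variants
#' @param theta_ivw pooled estimate to test against; computed by
#'   [ivw_fixed()] when NULL
#' @return list of class `mr_heterogeneity`: `Q`, `df`, `pvalue`
#' @export
cochran_q <- function(h, theta_ivw = NULL) {
  m <- nrow(h)
  if (m < 2) stop("cochran_q(): at least 2 variants are required")
  if (is.null(theta_ivw)) theta_ivw <- ivw_fixed(h)$estimate
  w <- .ivw_weights(h)
  ratio <- h$beta_y / h$beta_x
  Q <- sum(w * (ratio - theta_ivw)^2)
  out <- list(Q = Q, df = m - 1L,
              pvalue = stats::pchisq(Q, df = m - 1, lower.tail = FALSE))
  class(out) <- "mr_heterogeneity"
  out
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.2f on %d df (p = %.3g)\n", x$Q, x$df,
              x$pvalue))
  invisible(x)
}

#' Run all applicable estimators on a harmonized table
#'
#' Applies the estimators a summary-data MR analysis reports side by side:
#' fixed-effect IVW (or generalized weighted regression when an LD matrix
#' is supplied), weighted median and MR-Egger where enough variants exist,
#' the single-variant Wald ratio with its Fieller set when only one
#' variant is available, plus Cochran's Q.
#'
#' @param h harmonized table
#' @param rho optional LD correlation matrix for correlated variants
#' @param alpha two-sided level; default 0.05
#' @param n_boot weighted-median bootstrap resamples; default 1000
#' @param seed seed for the weighted-median bootstrap
#' @return data.frame with one row per method: `method`, `n_snps`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `ci_type`, `pvalue`, `Q`,
#'   `Q_df`, `Q_pvalue` (Q columns populated on the pooled rows only)
#' @export
estimate_all <- function(h, rho = NULL, alpha = 0.05, n_boot = 1000,
                         seed = NULL) {
  m <- nrow(h)
  if (m == 0) stop("estimate_all(): empty harmonized table")
  ests <- list()
  if (m == 1) {
    wd <- wald_ratio(h$beta_x, h$se_x, h$beta_y, h$se_y, alpha)
    fs <- fieller_interval(h$beta_x, h$se_x, h$beta_y, h$se_y, alpha)
    if (fs$type == "finite") {
      wd$ci_low <- fs$low; wd$ci_high <- fs$high
    } else {
      wd$ci_type <- fs$type
    }
    ests <- list(wd)
  } else {
    ests <- list(if (is.null(rho)) ivw_fixed(h, alpha)
                 else ivw_correlated(h, rho, alpha))
    if (m >= 3) {
      ests <- c(ests, list(weighted_median(h, n_boot, seed, alpha)))
      eg <- mr_egger(h, alpha)
      ests <- c(ests, list(eg$slope, eg$intercept))
    }
  }
  out <- do.call(rbind, lapply(ests, function(e) {
    data.frame(method = e$method, n_snps = e$n_snps, estimate = e$estimate,
               se = e$se, ci_low = e$ci_low, ci_high = e$ci_high,
               ci_type = e$ci_type, pvalue = e$pvalue,
               stringsAsFactors = FALSE)
  }))
  out$Q <- NA_real_; out$Q_df <- NA_integer_; out$Q_pvalue <- NA_real_
  if (m >= 2) {
    q <- cochran_q(h)
    pooled <- out$method %in% c("ivw_fixed", "ivw_correlated")
    out$Q[pooled] <- q$Q
    out$Q_df[pooled] <- q$df
    out$Q_pvalue[pooled] <- q$pvalue
  }
  rownames(out) <- NULL
  out
}
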