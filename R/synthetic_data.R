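# Simulation of two-sample summary statistics: per-variant exposure
# effects, outcome effects under a specified causal effect and pleiotropy
# regime, sampling noise at stated standard errors, optional LD, and full
# canonical tables that round-trip through the I/O layer.

#' Construct a simulation configuration
#'
#' The generative model, on the summary-statistic scale: true per-variant
#' exposure effects `gamma_j ~ |N(0, gamma_scale^2)|` (half-normal: every
#' variant is oriented to its exposure-increasing allele, the standard
#' instrument convention, under which directional pleiotropy biases the
#' ratio estimators in its own direction); observed
#' `beta_X_j = gamma_j + eps_X_j` with `eps_X_j ~ N(0, se_X_j^2)`;
#' per-variant pleiotropic effects `alpha_j` drawn by regime (see below);
#' observed `beta_Y_j = theta gamma_j + alpha_j + eps_Y_j`.  Binary-outcome
#' effects are simulated directly on the log-odds scale.  When an LD
#' matrix is supplied, each side's noise vector is drawn jointly with that
#' correlation (the two sides stay independent, as in separate samples).
#'
#' Pleiotropy regimes (`alpha_j` for a fraction `invalid_fraction` of
#' variants, 0 for the rest):
#' \describe{
#'   \item{none}{alpha_j = 0.}
#'   \item{balanced}{alpha_j ~ N(0, alpha_sd^2): pleiotropy with no
#'     preferred direction.}
#'   \item{directional}{alpha_j ~ N(alpha_mean, alpha_sd^2), independent
#'     of gamma_j, so the InSIDE condition holds.}
#'   \item{inside_violating}{alpha_j = alpha_mean + 0.3 gamma_j +
#'     N(0, alpha_sd^2): pleiotropy correlated with instrument strength.}
#' }
#'
#' Defaults emulate a thyroid-function-style design: ~20 instruments with
#' exposure-side standard errors of a GWAS of ~26k individuals
#' (`se_X ~ 0.006` per SD) and effect spread giving a mean per-variant F
#' near 60, and outcome-side log-odds standard errors of a case-control
#' sample of ~195k (`se_Y ~ 0.012`).
#'
#' @param m number of variants; default 20
#' @param theta true causal effect (log odds per SD exposure); default 0
#' @param gamma_scale SD of true exposure effects; default 0.046
#' @param se_x_scale exposure-side sampling SE; default 0.006
#' @param se_y_scale outcome-side sampling SE; default 0.012
#' @param pleiotropy_mode one of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violating"`; default `"none"`
#' @param alpha_mean mean pleiotropic effect (directional modes); default 0
#' @param alpha_sd SD of pleiotropic effects; default 0.01
#' @param invalid_fraction fraction of variants given pleiotropy; default 1
#' @param rho optional LD correlation matrix (m x m)
#' @param n_exposure,n_outcome sample sizes stamped into the tables;
#'   defaults 26420 and 195055
#' @param seed integer seed; NULL leaves the RNG state alone
#' @return list of class `mr_sim_config`
#' @export
simulation_config <- function(m = 20, theta = 0, gamma_scale = 0.046,
                              se_x_scale = 0.006, se_y_scale = 0.012,
                              pleiotropy_mode = c("none", "balanced",
                                                  "directional",
                                                  "inside_violating"),
                              alpha_mean = 0, alpha_sd = 0.01,
                              invalid_fraction = 1, rho = NULL,
                              n_exposure = 26420, n_outcome = 195055,
                              seed = NULL) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(m >= 1, gamma_scale > 0, se_x_scale > 0, se_y_scale > 0,
            invalid_fraction >= 0, invalid_fraction <= 1)
  if (!is.null(rho)) {
    if (!is.matrix(rho) || nrow(rho) != m || ncol(rho) != m)
      stop("rho must be an m x m matrix")
    ev <- min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0)
      stop("rho is not positive definite (smallest eigenvalue ",
           format(ev, digits = 4), ")")
  }
  out <- list(m = m, theta = theta, gamma_scale = gamma_scale,
              se_x_scale = se_x_scale, se_y_scale = se_y_scale,
              pleiotropy_mode = pleiotropy_mode, alpha_mean = alpha_mean,
              alpha_sd = alpha_sd, invalid_fraction = invalid_fraction,
              rho = rho, n_exposure = n_exposure, n_outcome = n_outcome,
              seed = seed)
  class(out) <- "mr_sim_config"
  out
}

# non-palindromic allele pairs only, so strand handling never drops a
# simulated variant by default
.ALLELE_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                       c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

#' Simulate two-sample GWAS summary statistics
#'
#' Draws one realization of the generative model in
#' [simulation_config()] and emits exposure and outcome tables with the
#' canonical columns (alleles, allele frequencies, two-sided normal
#' p-values implied by beta/se, sample sizes), plus the ground truth.  The
#' outcome table is emitted with a random per-variant allele orientation
#' (alleles swapped, beta negated, eaf complemented) so harmonization is
#' genuinely exercised.
#'
#' @param cfg an `mr_sim_config`
#' @return list with `exposure` and `outcome` (canonical association
#'   tables) and `truth` (list: `theta`, `gamma`, `alpha`, `snps`,
#'   `flipped`)
#' @export
simulate_two_sample <- function(cfg) {
  stopifnot(inherits(cfg, "mr_sim_config"))
  if (!is.null(cfg$seed)) {
    # seeded draws leave the caller's RNG stream untouched
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(cfg$seed)
  }
  m <- cfg$m
  snps <- sprintf("rs%07d", seq_len(m))
  gamma <- abs(stats::rnorm(m, 0, cfg$gamma_scale))
  se_x <- rep(cfg$se_x_scale, m)
  se_y <- rep(cfg$se_y_scale, m)
  draw_noise <- function(se) {
    if (is.null(cfg$rho)) stats::rnorm(m, 0, se)
    else as.numeric(MASS::mvrnorm(1, rep(0, m), outer(se, se) * cfg$rho))
  }
  alpha <- rep(0, m)
  if (cfg$pleiotropy_mode != "none") {
    n_inv <- round(cfg$invalid_fraction * m)
    inv <- if (n_inv > 0) sample.int(m, n_inv) else integer()
    alpha[inv] <- switch(cfg$pleiotropy_mode,
      balanced = stats::rnorm(n_inv, 0, cfg$alpha_sd),
      directional = stats::rnorm(n_inv, cfg$alpha_mean, cfg$alpha_sd),
      inside_violating = cfg$alpha_mean + 0.3 * gamma[inv] +
        stats::rnorm(n_inv, 0, cfg$alpha_sd))
  }
  beta_x <- gamma + draw_noise(se_x)
  beta_y <- cfg$theta * gamma + alpha + draw_noise(se_y)
  pairs <- .ALLELE_PAIRS[sample.int(nrow(.ALLELE_PAIRS), m, replace = TRUE), ,
                         drop = FALSE]
  eaf <- stats::runif(m, 0.1, 0.9)
  mk_table <- function(beta, se, n) {
    validate_associations(data.frame(stringsAsFactors = FALSE,
      SNP = snps, effect_allele = pairs[, 1], other_allele = pairs[, 2],
      eaf = eaf, beta = beta, se = se,
      pval = 2 * stats::pnorm(-abs(beta / se)), n = n))
  }
  exposure <- mk_table(beta_x, se_x, cfg$n_exposure)
  outcome <- mk_table(beta_y, se_y, cfg$n_outcome)
  flipped <- stats::runif(m) < 0.5
  outcome$effect_allele[flipped] <- pairs[flipped, 2]
  outcome$other_allele[flipped] <- pairs[flipped, 1]
  outcome$beta[flipped] <- -outcome$beta[flipped]
  outcome$eaf[flipped] <- 1 - outcome$eaf[flipped]
  list(exposure = exposure, outcome = outcome,
       truth = list(theta = cfg$theta, gamma = gamma, alpha = alpha,
                    snps = snps, flipped = flipped))
}

#' Simulate a block-diagonal exchangeable LD correlation matrix
#'
#' Variants are grouped into consecutive blocks of `block_size`; within a
#' block every pair has correlation `within_block_r`, between blocks zero.
#' An exchangeable block of size b has eigenvalues `1 + (b-1) r` and
#' `1 - r`, so positive definiteness requires `-1/(b-1) < r < 1`.
#'
#' @param m number of variants
#' @param block_size variants per block (the last block may be smaller)
#' @param within_block_r within-block correlation, |r| < 1
#' @param seed unused (the matrix is deterministic); kept for interface
#'   symmetry with the other generators
#' @return m x m correlation matrix with rsID dimnames matching
#'   [simulate_two_sample()]
#' @export
simulate_ld_matrix <- function(m, block_size, within_block_r, seed = NULL) {
  stopifnot(m >= 1, block_size >= 1, abs(within_block_r) < 1)
  if (block_size > 1 && within_block_r <= -1 / (block_size - 1))
    stop("within_block_r = ", within_block_r,
         " makes a block of size ", block_size, " non-positive-definite")
  rho <- diag(m)
  block <- (seq_len(m) - 1) %/% block_size
  same <- outer(block, block, "==")
  rho[same & !diag(m)] <- within_block_r
  snps <- sprintf("rs%07d", seq_len(m))
  dimnames(rho) <- list(snps, snps)
  rho
}

#' Named scenario presets mirroring the study designs
#'
#' Instrument counts follow the four analysis arms: 20 variants
#' (TSH-style, Metabochip outcome), 22 (TSH-style, 1000-Genomes outcome),
#' 5 (FT4-style) and 2 (TPOAb-style), with exposure-side noise tuned for
#' the reported mean instrument strengths (F near 60 for TSH/FT4, near 33
#' for TPOAb).
#'
#' @param name one of `"tsh_like_20snp"`, `"tsh_like_22snp"`,
#'   `"ft4_like_5snp"`, `"tpoab_like_2snp"`
#' @param theta true causal effect; default 0
#' @param seed integer seed
#' @return an `mr_sim_config`
#' @export
scenario_preset <- function(name = c("tsh_like_20snp", "tsh_like_22snp",
                                     "ft4_like_5snp", "tpoab_like_2snp"),
                            theta = 0, seed = NULL) {
  name <- match.arg(name)
  switch(name,
    tsh_like_20snp = simulation_config(m = 20, theta = theta, seed = seed),
    tsh_like_22snp = simulation_config(m = 22, theta = theta, seed = seed),
    ft4_like_5snp = simulation_config(m = 5, theta = theta,
                                      n_exposure = 17520, seed = seed),
    tpoab_like_2snp = simulation_config(m = 2, theta = theta,
                                        gamma_scale = 0.14,
                                        se_x_scale = 0.025,
                                        n_exposure = 18297, seed = seed))
}
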