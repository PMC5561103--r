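# shared builders for association and harmonized tables

make_assoc <- function(snp, ea, oa, beta, se, pval = NULL, eaf = NA,
                       n = NA) {
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  data.frame(SNP = snp, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}

# harmonized-table shell straight from effect vectors (already aligned)
make_h <- function(beta_x, se_x, beta_y, se_y) {
  m <- length(beta_x)
  structure(
    data.frame(SNP = sprintf("rs%07d", seq_len(m)),
               beta_x = beta_x, se_x = se_x, beta_y = beta_y, se_y = se_y,
               stringsAsFactors = FALSE),
    class = c("mr_harmonized", "data.frame"))
}

random_h <- function(m, theta = 0.2, gamma_scale = 0.05, se_x = 0.006,
                     se_y = 0.012) {
  gx <- rnorm(m, 0, gamma_scale)
  make_h(gx + rnorm(m, 0, se_x), rep(se_x, m),
         theta * gx + rnorm(m, 0, se_y), rep(se_y, m))
}

# simulate, harmonize, return the analysis-ready table
sim_h <- function(cfg) {
  sim <- simulate_two_sample(cfg)
  harmonize(sim$exposure, sim$outcome)
}
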