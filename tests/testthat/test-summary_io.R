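test_that("association tables survive a write/read round trip, with and without a column map", {
  tab <- make_assoc(c("rs1", "rs2", "rs3"),
                    c("A", "T", "G"), c("G", "C", "A"),
                    beta = c(0.05, -0.03, 0.12), se = c(0.01, 0.008, 0.02),
                    eaf = c(0.3, 0.7, 0.45), n = 26420)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_association_table(tab, f)
  back <- read_association_table(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$beta, tab$beta)
  expect_equal(back$SNP, tab$SNP)
  expect_equal(nrow(attr(back, "rejections")), 0)

  # same content under non-canonical headers and a user column map
  f2 <- withr::local_tempfile(fileext = ".tsv")
  renamed <- tab
  names(renamed) <- c("rsid", "A1", "A2", "freq", "b", "stderr", "p", "N")
  write.table(renamed, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_association_table(f2, column_map = c(
    SNP = "rsid", effect_allele = "A1", other_allele = "A2", eaf = "freq",
    beta = "b", se = "stderr", pval = "p", n = "N"))
  expect_equal(as.data.frame(back2), as.data.frame(back))
})

test_that("malformed rows are rejected with line numbers, missing columns error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
               "rs1\tA\tG\t0.3\t0.05\t0.01\t1e-9\t1000",
               "rs2\tT\tC\t0.4\t0.02\tNA\t1e-8\t1000",
               "rs3\tG\tA\t0.5\t0.01\t0.005\t1e-7\t1000"), f)
  got <- read_association_table(f)
  expect_equal(nrow(got), 2)
  rej <- attr(got, "rejections")
  expect_equal(rej$SNP, "rs2")
  expect_equal(rej$line, 3)  # file line, counting the header
  expect_match(rej$reason, "se")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\teffect_allele\tother_allele\teaf\tbeta\tpval\tn",
               "rs1\tA\tG\t0.3\t0.05\t1e-9\t1000"), f3)
  expect_error(read_association_table(f3), "mandatory column")
})

test_that("delimiter auto-detection reads comma and whitespace dialects", {
  tab <- make_assoc("rs1", "A", "G", 0.05, 0.01, eaf = 0.3, n = 10)
  for (sep in c(",", " ")) {
    f <- withr::local_tempfile()
    write.table(tab, f, sep = sep, quote = FALSE, row.names = FALSE)
    expect_equal(read_association_table(f)$beta, 0.05)
  }
})

test_that("proxy substitution follows the published footnote pattern", {
  # table lacks the target but carries the proxy: proxy row is used with
  # provenance
  tab <- make_assoc(c("rs12523579", "rs1000"), c("A", "T"), c("G", "C"),
                    c(0.02, 0.01), c(0.005, 0.004))
  pm <- proxy_map("rs2928167", "rs12523579")
  got <- apply_proxy_map(tab, pm)
  expect_equal(got$proxy_for[got$SNP == "rs12523579"], "rs2928167")
  expect_equal(attr(got, "unavailable"), character(0))

  # target present in the table: untouched
  tab2 <- rbind(tab, make_assoc("rs2928167", "A", "G", 0.03, 0.006))
  tab2$proxy_for <- NULL
  got2 <- apply_proxy_map(tab2, pm)
  expect_true(all(is.na(got2$proxy_for)))

  # empty map is the identity
  got3 <- apply_proxy_map(tab, proxy_map())
  expect_equal(got3$SNP, tab$SNP)

  # proxy also absent: recorded unavailable, instrument count drops by one
  pm2 <- proxy_map(c("rs2928167", "rs999"), c("rs12523579", "rs998"))
  got4 <- apply_proxy_map(tab, pm2)
  expect_equal(attr(got4, "unavailable"), "rs999")
  avail <- resolve_availability(c("rs1000", "rs999"), got4, pm2)
  expect_equal(length(avail$available) + nrow(avail$substituted), 1)
  expect_equal(avail$unavailable, "rs999")
})

test_that("proxy map invariants are enforced", {
  expect_error(proxy_map("rs1", "rs1"), "proxy itself")
  expect_error(proxy_map(c("rs1", "rs2"), c("rs3", "rs3")), "two targets")
})

test_that("harmonization flips swapped alleles and applies the palindrome policy", {
  ex <- make_assoc("rs1", "A", "G", 0.1, 0.01)
  ou <- make_assoc("rs1", "G", "A", -0.05, 0.02)
  h <- harmonize(ex, ou)
  expect_equal(h$beta_y, 0.05)
  expect_equal(h$orientation, "flipped")

  # palindromic with ambiguous frequency is dropped under infer-by-eaf
  ex2 <- make_assoc("rs2", "A", "T", 0.1, 0.01, eaf = 0.50)
  ou2 <- make_assoc("rs2", "A", "T", 0.05, 0.02, eaf = 0.52)
  h2 <- harmonize(ex2, ou2, palindrome_policy = "infer-by-eaf",
                  eaf_window = 0.08)
  expect_equal(nrow(h2), 0)
  expect_match(attr(h2, "report")$reason, "eaf")

  # and always dropped under the default policy, even when eaf is clear
  ex3 <- make_assoc("rs3", "C", "G", 0.1, 0.01, eaf = 0.1)
  ou3 <- make_assoc("rs3", "C", "G", 0.05, 0.02, eaf = 0.12)
  expect_equal(nrow(harmonize(ex3, ou3)), 0)
  # but oriented by frequency when unambiguous under infer-by-eaf
  h3 <- harmonize(ex3, ou3, palindrome_policy = "infer-by-eaf")
  expect_equal(h3$beta_y, 0.05)
  # discordant frequencies imply a strand flip, i.e. a sign flip
  ou4 <- make_assoc("rs3", "C", "G", 0.05, 0.02, eaf = 0.88)
  h4 <- harmonize(ex3, ou4, palindrome_policy = "infer-by-eaf")
  expect_equal(h4$beta_y, -0.05)

  # incompatible allele pairs are dropped with the mismatch reason
  ou5 <- make_assoc("rs1", "A", "C", 0.05, 0.02)
  h5 <- harmonize(ex, ou5)
  expect_equal(nrow(h5), 0)
  expect_equal(attr(h5, "report")$reason, "allele mismatch")
})

test_that("harmonization recovers the true orientation in all four allele presentations", {
  # orientation-enumeration oracle: the outcome is presented in one of the
  # four equivalent encodings (direct, swapped, strand-complemented,
  # complemented and swapped); harmonization must recover the same beta_y
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  set.seed(42)
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  for (rep in 1:5) {
    m <- 50
    k <- pairs[sample(4, m, TRUE), , drop = FALSE]
    true_by <- rnorm(m, 0, 0.05)
    ex <- make_assoc(sprintf("rs%d", 1:m), k[, 1], k[, 2],
                     rnorm(m, 0, 0.05), 0.01, eaf = runif(m, 0.1, 0.9))
    mode <- sample(4, m, TRUE)
    ea <- k[, 1]; oa <- k[, 2]; by <- true_by; eaf <- ex$eaf
    swap <- mode %in% c(2, 4)
    ea[swap] <- k[swap, 2]; oa[swap] <- k[swap, 1]
    by[swap] <- -by[swap]; eaf[swap] <- 1 - eaf[swap]
    strand <- mode %in% c(3, 4)
    ea[strand] <- comp[ea[strand]]; oa[strand] <- comp[oa[strand]]
    ou <- make_assoc(ex$SNP, ea, oa, by, 0.02, eaf = eaf)
    h <- harmonize(ex[sample(m), ], ou[sample(m), ])
    expect_equal(nrow(h), m)
    expect_equal(h$beta_y[match(ex$SNP, h$SNP)], true_by, tolerance = 1e-12)
  }
})

test_that("harmonization is idempotent and invariant to wholesale outcome re-encoding", {
  set.seed(7)
  sim <- simulate_two_sample(simulation_config(m = 30, theta = 0.1, seed = 3))
  h <- harmonize(sim$exposure, sim$outcome)
  # feed the harmonized outcome back: nothing changes
  ou2 <- make_assoc(h$SNP, h$effect_allele, h$other_allele, h$beta_y, h$se_y,
                    pval = h$pval_y, eaf = h$eaf_y, n = h$n_y)
  h2 <- harmonize(sim$exposure, ou2)
  expect_equal(h2$beta_y, h$beta_y)
  expect_true(all(h2$orientation == "unchanged"))

  # flipping alleles, beta sign and eaf of every outcome row is a no-op
  ou3 <- sim$outcome
  tmp <- ou3$effect_allele
  ou3$effect_allele <- ou3$other_allele; ou3$other_allele <- tmp
  ou3$beta <- -ou3$beta; ou3$eaf <- 1 - ou3$eaf
  h3 <- harmonize(sim$exposure, ou3)
  expect_equal(h3$beta_y, h$beta_y)
  expect_equal(h3$eaf_y, h$eaf_y)
})
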