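# Regenerates the instrument-accounting fixtures under inst/extdata/.
# rsIDs on the exclusion lists, LD pairs and proxy maps are the published
# thyroid-function instruments; variants the source tables do not name are
# synthetic placeholders (rs9xxxxx), and association statistics are
# synthetic throughout (files are suffixed _synthetic accordingly).
set.seed(20260921)
out <- file.path("inst", "extdata")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ld_excluded <- c("rs12410532", "rs28435578", "rs2046045", "rs6923866",
                 "rs2396084", "rs3008034", "rs116552240", "rs17767742")
ld_partner  <- c("rs10799824", "rs10032216", "rs6885099", "rs11755845",
                 "rs9472138", "rs753760", "rs657152", "rs3813582")
pleio_tsh <- data.frame(
  SNP = c("rs13015993", "rs7568039", "rs657152"),
  reason = "pleiotropy",
  annotation = c("IGFBP5_CAD_association", "IGFBP2_CAD_association",
                 "ABO_IHD_association"))
tsh_named <- unique(c(ld_excluded, ld_partner, pleio_tsh$SNP, "rs2928167"))
tsh_extra <- sprintf("rs%07d", 9000001:(9000000 + 34 - length(tsh_named)))
tsh_snps <- c(tsh_named, tsh_extra)

make_table <- function(snps, f, se = 0.006, n = 26420) {
  pairs <- rbind(c("A", "G"), c("T", "C"), c("G", "A"), c("C", "T"))
  k <- pairs[(seq_along(snps) - 1) %% 4 + 1, , drop = FALSE]
  data.frame(SNP = snps, effect_allele = k[, 1], other_allele = k[, 2],
             eaf = round(runif(length(snps), 0.15, 0.85), 3),
             beta = round(sqrt(f) * se, 6), se = se,
             pval = signif(2 * pnorm(-sqrt(f)), 4), n = n)
}

# per-variant F: spread around 60; within each LD pair the discarded
# member gets the weaker association (larger p), as the pruning rule wants
f_tsh <- setNames(round(runif(34, 40, 85), 1), tsh_snps)
f_tsh[ld_partner] <- round(runif(8, 55, 85), 1)
f_tsh[ld_excluded] <- round(f_tsh[ld_partner] - runif(8, 5, 15), 1)
tsh <- make_table(tsh_snps, f_tsh)
write.table(tsh, file.path(out, "tsh_instruments_synthetic.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ld <- diag(34); dimnames(ld) <- list(tsh_snps, tsh_snps)
for (i in seq_along(ld_excluded)) {
  a <- ld_excluded[i]; b <- ld_partner[i]
  ld[a, b] <- ld[b, a] <- 0.9
}
write.table(round(ld, 3), file.path(out, "tsh_ld_synthetic.txt"),
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
writeLines(tsh_snps, file.path(out, "tsh_ld_index_synthetic.txt"))
write.table(pleio_tsh, file.path(out, "tsh_pleiotropy_exclusions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(target = "rs2928167", proxy = "rs12523579"),
            file.path(out, "tsh_proxy_map.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# outcome-side variant availability: the Metabochip arm lacks the proxied
# variant plus three placeholders with no proxy (34 -> 20 after LD and
# pleiotropy exclusions); the 1000-Genomes arm lacks the proxied variant
# plus one placeholder (-> 22)
meta_avail <- c(setdiff(tsh_snps,
                        c("rs2928167", tsh_extra[1:3])), "rs12523579")
g1000_avail <- c(setdiff(tsh_snps, c("rs2928167", tsh_extra[1])),
                 "rs12523579")

ft4_ld_excluded <- c("rs11103377", "rs7694879")
ft4_ld_partner  <- c("rs7860634", "rs11726248")
ft4_snps <- c(ft4_ld_partner, ft4_ld_excluded, "rs113107469", "rs7045138",
              "rs9100001")
f_ft4 <- setNames(round(runif(7, 45, 80), 1), ft4_snps)
f_ft4[ft4_ld_partner] <- round(runif(2, 60, 80), 1)
f_ft4[ft4_ld_excluded] <- round(f_ft4[ft4_ld_partner] - runif(2, 5, 15), 1)
ft4 <- make_table(ft4_snps, f_ft4, n = 17520)
write.table(ft4, file.path(out, "ft4_instruments_synthetic.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
ld_ft4 <- diag(7); dimnames(ld_ft4) <- list(ft4_snps, ft4_snps)
for (i in 1:2) {
  a <- ft4_ld_excluded[i]; b <- ft4_ld_partner[i]
  ld_ft4[a, b] <- ld_ft4[b, a] <- 0.88
}
write.table(round(ld_ft4, 3), file.path(out, "ft4_ld_synthetic.txt"),
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
writeLines(ft4_snps, file.path(out, "ft4_ld_index_synthetic.txt"))
write.table(data.frame(target = "rs113107469", proxy = "rs4799592"),
            file.path(out, "ft4_proxy_map_metabochip.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(target = "rs7045138", proxy = "rs4297160"),
            file.path(out, "ft4_proxy_map_1000g.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
meta_avail <- c(meta_avail, setdiff(ft4_snps, "rs113107469"), "rs4799592")
g1000_avail <- c(g1000_avail, setdiff(ft4_snps, "rs7045138"), "rs4297160")

tpoab_snps <- c("rs653178", "rs9200001", "rs9200002")
tpoab <- make_table(tpoab_snps, c(35, 34, 31), se = 0.025, n = 18297)
write.table(tpoab, file.path(out, "tpoab_instruments_synthetic.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(SNP = "rs653178", reason = "pleiotropy",
                       annotation = "blood_pressure_CAD_association"),
            file.path(out, "tpoab_pleiotropy_exclusions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
meta_avail <- c(meta_avail, tpoab_snps)
g1000_avail <- c(g1000_avail, tpoab_snps)

writeLines(meta_avail,
           file.path(out, "metabochip_outcome_snps_synthetic.txt"))
writeLines(g1000_avail,
           file.path(out, "g1000_outcome_snps_synthetic.txt"))
cat("fixtures written to", out, "\n")
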