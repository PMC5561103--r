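# Instrument selection: genome-wide significance filtering, LD pruning,
# pleiotropy exclusion, availability/proxy resolution, and instrument
# strength (per-variant F statistics).

#' Partition a table at a genome-wide significance threshold
#'
#' Retains variants with p strictly below the threshold (the conventional
#' genome-wide cut of 5e-8).
#'
#' @param table association table (canonical columns)
#' @param threshold p-value threshold in (0,1); default `5e-8`
#' @return list with `retained` and `subthreshold` data.frames
#' @export
filter_genome_wide <- function(table, threshold = 5e-8) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold <= 1)
  keep <- !is.na(table$pval) & table$pval < threshold
  list(retained = table[keep, , drop = FALSE],
       subthreshold = table[!keep, , drop = FALSE])
}

# enumerate upper-triangle pairs exceeding the r^2 threshold, sorted for a
# deterministic cascade: descending r^2, then lexicographic ids
.ld_offending_pairs <- function(ids, ld, r2_threshold) {
  common <- intersect(ids, rownames(ld))
  if (length(common) < 2) return(NULL)
  r2 <- ld[common, common, drop = FALSE]^2
  idx <- which(upper.tri(r2) & r2 > r2_threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  pairs <- data.frame(a = common[idx[, 1]], b = common[idx[, 2]],
                      r2 = r2[idx], stringsAsFactors = FALSE)
  swap <- pairs$a > pairs$b
  tmp <- pairs$a[swap]; pairs$a[swap] <- pairs$b[swap]; pairs$b[swap] <- tmp
  pairs[order(-pairs$r2, pairs$a, pairs$b), , drop = FALSE]
}

#' Prune instruments in linkage disequilibrium
#'
#' For every pair of variants with squared correlation above
#' `r2_threshold`, the member with the larger p-value is discarded.  Pairs
#' are processed in descending r^2 (ties broken lexicographically by
#' variant id) and exclusions cascade: a variant that has already been
#' excluded cannot exclude others.  Variants absent from the LD index are
#' treated as uncorrelated and noted in the `not_in_ld_index` attribute.
#'
#' @param table association table (canonical columns, `pval` required)
#' @param ld signed correlation matrix with rsID dimnames (squared
#'   internally), e.g. from [read_ld_matrix()] or [simulate_ld_matrix()]
#' @param r2_threshold squared-correlation cut; default 0.7
#' @return list with `retained` (data.frame) and `excluded` (data.frame
#'   with columns `SNP`, `reason = "ld"`, `partner`, `r2`)
#' @export
ld_prune <- function(table, ld, r2_threshold = 0.7) {
  pairs <- .ld_offending_pairs(table$SNP, ld, r2_threshold)
  excluded <- data.frame(SNP = character(), reason = character(),
                         partner = character(), r2 = numeric(),
                         stringsAsFactors = FALSE)
  alive <- stats::setNames(rep(TRUE, nrow(table)), table$SNP)
  pv <- stats::setNames(table$pval, table$SNP)
  if (!is.null(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- pairs$a[k]; b <- pairs$b[k]
      if (!alive[a] || !alive[b]) next
      # discard the larger p-value; tie broken by the later id
      drop_b <- pv[b] > pv[a] || (pv[b] == pv[a] && b > a)
      loser <- if (drop_b) b else a
      winner <- if (drop_b) a else b
      alive[loser] <- FALSE
      excluded <- rbind(excluded, data.frame(
        SNP = loser, reason = "ld", partner = winner, r2 = pairs$r2[k],
        stringsAsFactors = FALSE))
    }
  }
  list(retained = table[alive[table$SNP], , drop = FALSE],
       excluded = excluded,
       not_in_ld_index = setdiff(table$SNP, rownames(ld)))
}

#' Move listed pleiotropic variants into the excluded partition
#'
#' Variants named on the exclusion list are excluded with reason
#' `"pleiotropy"` and the list's annotation.  Listed variants absent from
#' the table are noted (`not_found`), not an error.  Both the excluding
#' analysis (retained) and the including analysis (the untouched input)
#' remain available to the caller, mirroring the paired
#' with/without-pleiotropy reporting.
#'
#' @param table association table
#' @param exclusion_list data.frame with columns `SNP` and optionally
#'   `reason`, `annotation` (see [read_exclusion_list()]), or a character
#'   vector of variant ids
#' @return list with `retained`, `excluded` (columns `SNP`, `reason`,
#'   `annotation`) and `not_found` (character)
#' @export
exclude_pleiotropic <- function(table, exclusion_list) {
  if (is.character(exclusion_list))
    exclusion_list <- data.frame(SNP = exclusion_list,
                                 stringsAsFactors = FALSE)
  if (is.null(exclusion_list) || nrow(exclusion_list) == 0)
    return(list(retained = table,
                excluded = data.frame(SNP = character(), reason = character(),
                                      annotation = character(),
                                      stringsAsFactors = FALSE),
                not_found = character()))
  if (!"annotation" %in% names(exclusion_list))
    exclusion_list$annotation <- NA_character_
  hit <- exclusion_list$SNP %in% table$SNP
  excluded <- data.frame(SNP = exclusion_list$SNP[hit],
                         reason = rep("pleiotropy", sum(hit)),
                         annotation = exclusion_list$annotation[hit],
                         stringsAsFactors = FALSE)
  list(retained = table[!table$SNP %in% excluded$SNP, , drop = FALSE],
       excluded = excluded,
       not_found = exclusion_list$SNP[!hit])
}

#' Per-variant F statistic from summary statistics
#'
#' In the two-sample summary-data setting the instrument strength of one
#' variant is approximated by its squared z-score, F = (beta/se)^2.
#'
#' @param beta_x SNP-exposure effect(s)
#' @param se_x positive standard error(s)
#' @return F statistic(s), vectorized
#' @export
variant_f_statistic <- function(beta_x, se_x) {
  if (any(is.na(se_x)) || any(se_x <= 0))
    stop("variant_f_statistic(): se_x must be positive")
  (beta_x / se_x)^2
}

#' Per-variant F statistic from explained variance
#'
#' Alternative approximation F = r2 (n - 2) / (1 - r2) from the variance in
#' the exposure explained by the variant and the exposure-sample size.
#'
#' @param r2 variance explained, in (0,1)
#' @param n exposure sample size
#' @return F statistic(s), vectorized
#' @export
variant_f_statistic_r2 <- function(r2, n) {
  stopifnot(all(r2 > 0 & r2 < 1), all(n > 2))
  r2 * (n - 2) / (1 - r2)
}

#' Resolve instrument availability in an outcome table
#'
#' Splits a set of candidate instruments into those present in the outcome
#' table, those recovered through a proxy, and those unavailable (absent
#' with no usable proxy).
#'
#' @param snps character vector of instrument rsIDs
#' @param outcome outcome association table (canonical columns)
#' @param proxies optional `mr_proxy_map`
#' @return list with `available` (ids found directly), `substituted`
#'   (data.frame `target`/`proxy` actually used) and `unavailable`
#' @export
resolve_availability <- function(snps, outcome, proxies = NULL) {
  present <- snps[snps %in% outcome$SNP]
  missing <- setdiff(snps, present)
  substituted <- data.frame(target = character(), proxy = character(),
                            stringsAsFactors = FALSE)
  unavailable <- character()
  for (tgt in missing) {
    prx <- if (!is.null(proxies)) proxies$proxy[match(tgt, proxies$target)]
           else NA_character_
    if (!is.na(prx) && prx %in% outcome$SNP) {
      substituted <- rbind(substituted, data.frame(
        target = tgt, proxy = prx, stringsAsFactors = FALSE))
    } else {
      unavailable <- c(unavailable, tgt)
    }
  }
  list(available = present, substituted = substituted,
       unavailable = unavailable)
}

#' Select instruments: significance filter, LD pruning, pleiotropy lists
#'
#' Applies, in order, the genome-wide significance filter, LD pruning at
#' `r2_threshold`, and the pleiotropy exclusion list, keeping a full record
#' of every exclusion.  The retained set before pleiotropy exclusion is
#' kept alongside so that paired analyses (with and without potentially
#' pleiotropic variants) can both be run.
#'
#' @param table exposure association table (canonical columns)
#' @param ld optional LD correlation matrix (see [ld_prune()])
#' @param exclusion_list optional pleiotropy exclusion list
#'   (see [exclude_pleiotropic()])
#' @param p_threshold genome-wide significance threshold; default 5e-8
#' @param r2_threshold LD pruning threshold; default 0.7
#' @return object of class `mr_instruments`: list with `retained`
#'   (data.frame, pleiotropy excluded), `retained_all` (data.frame,
#'   pleiotropic variants kept), `excluded` (data.frame `SNP`, `reason` in
#'   {subthreshold, ld, pleiotropy}, `detail`), per-variant `F` (named, over
#'   `retained`) and `mean_F`
#' @export
select_instruments <- function(table, ld = NULL, exclusion_list = NULL,
                               p_threshold = 5e-8, r2_threshold = 0.7) {
  excl <- data.frame(SNP = character(), reason = character(),
                     detail = character(), stringsAsFactors = FALSE)
  gw <- filter_genome_wide(table, p_threshold)
  if (nrow(gw$subthreshold) > 0)
    excl <- rbind(excl, data.frame(
      SNP = gw$subthreshold$SNP, reason = "subthreshold",
      detail = sprintf("p=%.3g", gw$subthreshold$pval),
      stringsAsFactors = FALSE))
  cur <- gw$retained
  if (!is.null(ld)) {
    pr <- ld_prune(cur, ld, r2_threshold)
    if (nrow(pr$excluded) > 0)
      excl <- rbind(excl, data.frame(
        SNP = pr$excluded$SNP, reason = "ld",
        detail = sprintf("r2=%.3g with %s", pr$excluded$r2,
                         pr$excluded$partner),
        stringsAsFactors = FALSE))
    cur <- pr$retained
  }
  retained_all <- cur
  if (!is.null(exclusion_list)) {
    pl <- exclude_pleiotropic(cur, exclusion_list)
    if (nrow(pl$excluded) > 0)
      excl <- rbind(excl, data.frame(
        SNP = pl$excluded$SNP, reason = "pleiotropy",
        detail = ifelse(is.na(pl$excluded$annotation), "listed",
                        pl$excluded$annotation),
        stringsAsFactors = FALSE))
    cur <- pl$retained
  }
  F_stat <- stats::setNames(variant_f_statistic(cur$beta, cur$se), cur$SNP)
  out <- list(retained = cur, retained_all = retained_all, excluded = excl,
              F = F_stat,
              mean_F = if (length(F_stat)) mean(F_stat) else NA_real_)
  class(out) <- "mr_instruments"
  out
}

#' @export
print.mr_instruments <- function(x, ...) {
  cat("Instrument set:", nrow(x$retained), "retained (",
      nrow(x$retained_all), "including listed pleiotropic ),",
      nrow(x$excluded), "excluded\n")
  if (nrow(x$excluded) > 0)
    print(table(x$excluded$reason))
  cat("mean F over retained set:", format(x$mean_F, digits = 4), "\n")
  invisible(x)
}

#' Write an instrument-set report as delimited text
#'
#' One row per input variant with its final status and detail, mirroring a
#' supplementary instrument-accounting table.
#'
#' @param instruments an `mr_instruments` object
#' @param path output path (tab-delimited)
#' @return `path`, invisibly
#' @export
write_instrument_report <- function(instruments, path) {
  ret <- data.frame(SNP = instruments$retained$SNP, status = "retained",
                    detail = sprintf("F=%.1f", instruments$F),
                    stringsAsFactors = FALSE)
  exc <- data.frame(SNP = instruments$excluded$SNP,
                    status = sprintf("excluded:%s",
                                     instruments$excluded$reason),
                    detail = instruments$excluded$detail,
                    stringsAsFactors = FALSE)
  utils::write.table(rbind(ret, exc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
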