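# End-to-end orchestration: for each configured analysis, select
# instruments, resolve availability and proxies, harmonize, estimate with
# every requested method on the paired instrument sets (with and without
# the listed pleiotropic variants), and emit results plus a provenance
# log.

#' Construct a run configuration
#'
#' @param analyses list of analysis descriptions, each a list with fields:
#'   `name`; `exposure` and `outcome` (file path or canonical data.frame);
#'   optional `ld` (path to matrix, with `ld_index`, or a matrix),
#'   `exclusion_list` (path or data.frame), `proxy_map` (path or
#'   `mr_proxy_map`), `column_map`, `palindrome_policy`, `eaf_window`,
#'   `p_threshold`, `r2_threshold`, `use_ld_in_estimation` (default TRUE
#'   when an LD matrix is given), `alpha`, `n_boot`
#' @param seed integer master seed; mandatory (each analysis derives its
#'   own sub-seed, so results are reproducible and order-independent)
#' @param output_dir directory for `results.tsv`, instrument reports and
#'   `log.txt`; NULL keeps everything in memory
#' @param alpha default two-sided level; default 0.05
#' @param n_boot default weighted-median bootstrap count; default 1000
#' @return list of class `mr_run_config`
#' @export
run_config <- function(analyses, seed, output_dir = NULL, alpha = 0.05,
                       n_boot = 1000) {
  stopifnot(is.list(analyses), length(analyses) > 0)
  stopifnot(is.numeric(seed), length(seed) == 1)
  nm <- vapply(analyses, function(a) a$name %||% "", character(1))
  if (any(nm == "")) stop("every analysis needs a name")
  if (anyDuplicated(nm)) stop("analysis names must be unique")
  out <- list(analyses = analyses, seed = as.integer(seed),
              output_dir = output_dir, alpha = alpha, n_boot = n_boot)
  class(out) <- "mr_run_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_table <- function(x, column_map = NULL, what = "table") {
  if (is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop(what, " file not found: ", x)
    return(read_association_table(x, column_map = column_map))
  }
  stop(what, " must be a data.frame or a file path")
}

.run_one <- function(an, cfg, sub_seed, log) {
  alpha <- an$alpha %||% cfg$alpha
  n_boot <- an$n_boot %||% cfg$n_boot
  exposure <- .load_table(an$exposure, an$column_map, "exposure")
  outcome <- .load_table(an$outcome, an$column_map, "outcome")
  ld <- an$ld
  if (is.character(ld)) ld <- read_ld_matrix(ld, an$ld_index)
  excl <- an$exclusion_list
  if (is.character(excl) && length(excl) == 1 && file.exists(excl))
    excl <- read_exclusion_list(excl)
  proxies <- an$proxy_map
  if (is.character(proxies)) proxies <- read_proxy_map(proxies)

  inst <- select_instruments(exposure, ld = ld, exclusion_list = excl,
                             p_threshold = an$p_threshold %||% 5e-8,
                             r2_threshold = an$r2_threshold %||% 0.7)
  for (i in seq_len(nrow(inst$excluded)))
    log(sprintf("[%s] excluded %s (%s: %s)", an$name,
                inst$excluded$SNP[i], inst$excluded$reason[i],
                inst$excluded$detail[i]))

  outcome <- apply_proxy_map(outcome, proxies)
  snp_sets <- list(without_pleiotropy = inst$retained,
                   all_snps = inst$retained_all)
  res <- list()
  for (set_name in names(snp_sets)) {
    tab <- snp_sets[[set_name]]
    avail <- resolve_availability(tab$SNP, outcome, proxies)
    for (u in avail$unavailable)
      log(sprintf("[%s/%s] %s unavailable in outcome, no proxy", an$name,
                  set_name, u))
    for (i in seq_len(nrow(avail$substituted)))
      log(sprintf("[%s/%s] %s used as a proxy for %s", an$name, set_name,
                  avail$substituted$proxy[i], avail$substituted$target[i]))
    usable <- tab[!tab$SNP %in% avail$unavailable, , drop = FALSE]
    # relabel proxied exposure rows to the proxy id carried by the outcome
    ix <- match(usable$SNP, avail$substituted$target)
    usable$SNP[!is.na(ix)] <- avail$substituted$proxy[ix[!is.na(ix)]]
    h <- harmonize(usable, outcome,
                   palindrome_policy = an$palindrome_policy %||% "drop",
                   eaf_window = an$eaf_window %||% 0.08)
    rep <- attr(h, "report")
    for (i in which(rep$action == "dropped"))
      log(sprintf("[%s/%s] %s dropped in harmonization (%s)", an$name,
                  set_name, rep$SNP[i], rep$reason[i]))
    use_ld <- !is.null(ld) && (an$use_ld_in_estimation %||% TRUE)
    r <- estimate_all(h, rho = if (use_ld) ld else NULL, alpha = alpha,
                      n_boot = n_boot, seed = sub_seed)
    r <- cbind(data.frame(analysis = an$name, snp_set = set_name,
                          stringsAsFactors = FALSE), r)
    res[[set_name]] <- r
    log(sprintf("[%s/%s] %d SNP(s) analysed, mean F %.1f", an$name, set_name,
                nrow(h), mean(variant_f_statistic(h$beta_x, h$se_x))))
  }
  list(results = do.call(rbind, res), instruments = inst)
}

#' Run a configured set of MR analyses end to end
#'
#' For every analysis in the configuration, instruments are selected,
#' availability and proxies resolved against the outcome table, exposure
#' and outcome harmonized, and every applicable estimator run on two
#' instrument sets: without the listed pleiotropic variants and with them
#' (the paired reporting convention).  A failing analysis is recorded and
#' the remaining analyses proceed.
#'
#' @param cfg an `mr_run_config`
#' @return list of class `mr_run_bundle`: `results` (one data.frame over
#'   all analyses), `instruments` (named list of `mr_instruments`), `log`
#'   (character), `failed` (named character vector of error messages);
#'   when `output_dir` is set, `results.tsv` and `log.txt` are written
#'   there
#' @export
mr_run <- function(cfg) {
  stopifnot(inherits(cfg, "mr_run_config"))
  log_lines <- character()
  log <- function(line) log_lines <<- c(log_lines, line)
  results <- list(); instruments <- list(); failed <- character()
  for (k in seq_along(cfg$analyses)) {
    an <- cfg$analyses[[k]]
    sub_seed <- (cfg$seed + 1000003L * k) %% .Machine$integer.max
    out <- tryCatch(.run_one(an, cfg, sub_seed, log),
                    error = function(e) e)
    if (inherits(out, "error")) {
      failed[an$name] <- conditionMessage(out)
      log(sprintf("[%s] FAILED: %s", an$name, conditionMessage(out)))
    } else {
      results[[an$name]] <- out$results
      instruments[[an$name]] <- out$instruments
    }
  }
  results <- if (length(results)) do.call(rbind, results)
             else data.frame()
  rownames(results) <- NULL
  bundle <- list(results = results, instruments = instruments,
                 log = log_lines, failed = failed)
  class(bundle) <- "mr_run_bundle"
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(results, file.path(cfg$output_dir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(log_lines, file.path(cfg$output_dir, "log.txt"))
    for (nm in names(instruments))
      write_instrument_report(instruments[[nm]],
        file.path(cfg$output_dir, paste0("instruments_", nm, ".tsv")))
  }
  bundle
}

#' @export
print.mr_run_bundle <- function(x, ...) {
  cat("MR run:", length(x$instruments), "analysis/analyses completed,",
      length(x$failed), "failed\n")
  if (nrow(x$results) > 0)
    print(x$results[, c("analysis", "snp_set", "method", "n_snps",
                        "estimate", "se", "pvalue")])
  invisible(x)
}
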