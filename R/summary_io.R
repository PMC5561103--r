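# Reading, validation and harmonization of GWAS summary-statistic tables.
#
# The canonical table has columns
#   SNP, effect_allele, other_allele, eaf, beta, se, pval, n
# where beta is the per-effect-allele association (per SD for continuous
# traits, log odds for binary traits), se its standard error, eaf the
# effect-allele frequency and n the sample size.  eaf and n may be missing.

.CANONICAL_COLS <- c("SNP", "effect_allele", "other_allele", "eaf",
                     "beta", "se", "pval", "n")
.MANDATORY_COLS <- c("SNP", "effect_allele", "other_allele",
                     "beta", "se", "pval")
.BASES <- c("A", "C", "G", "T")

.complement <- function(a) {
  unname(c(A = "T", T = "A", C = "G", G = "C")[a])
}

.is_palindromic <- function(ea, oa) {
  oa == .complement(ea)
}

#' Detect the delimiter of a delimited text file
#'
#' Looks at the header line: tab wins over comma, comma over whitespace.
#' @param path file path
#' @return single character, `"\t"`, `","` or `""` (any whitespace)
#' @keywords internal
.detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
}

#' Read a GWAS summary-statistics association table
#'
#' Reads a delimited text file of per-variant associations into the
#' canonical representation.  Non-canonical headers are supported through
#' `column_map`; the delimiter is auto-detected from the header line unless
#' pinned with `delimiter`.  Rows failing validation (non-numeric or
#' non-positive standard error, p-value outside (0,1], malformed alleles,
#' effect allele equal to other allele, allele frequency outside [0,1]) are
#' dropped and reported, with their file line numbers, in the `rejections`
#' attribute.
#'
#' @param path path to a delimited text file with a header row
#' @param column_map named character vector mapping canonical column names
#'   to the names used in the file, e.g.
#'   `c(SNP = "rsid", beta = "b", se = "se", ...)`.  Canonical names absent
#'   from the map are looked up verbatim.
#' @param delimiter `NULL` (auto-detect), `"\t"`, `","` or `""` (whitespace)
#' @return a `data.frame` with the canonical columns (class `mr_assoc`);
#'   attribute `rejections` is a data.frame with columns `line`, `SNP`,
#'   `reason` describing every dropped row
#' @export
read_association_table <- function(path, column_map = NULL, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (is.null(delimiter)) .detect_delimiter(path) else delimiter
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           na.strings = c("NA", "", "."),
                           colClasses = "character", check.names = FALSE)
  # resolve the column map: canonical name -> file name
  want <- .CANONICAL_COLS
  file_names <- vapply(want, function(cn) {
    if (!is.null(column_map) && cn %in% names(column_map)) column_map[[cn]]
    else cn
  }, character(1))
  missing_mand <- .MANDATORY_COLS[!file_names[.MANDATORY_COLS] %in% names(raw)]
  if (length(missing_mand) > 0) {
    stop("mandatory column(s) missing from ", path, ": ",
         paste(file_names[missing_mand], collapse = ", "),
         " (canonical: ", paste(missing_mand, collapse = ", "), ")")
  }
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
    SNP           = raw[[file_names["SNP"]]],
    effect_allele = toupper(raw[[file_names["effect_allele"]]]),
    other_allele  = toupper(raw[[file_names["other_allele"]]]))
  for (cn in c("eaf", "beta", "se", "pval", "n")) {
    fn <- file_names[cn]
    out[[cn]] <- if (fn %in% names(raw)) suppressWarnings(as.numeric(raw[[fn]]))
                 else NA_real_
  }
  validate_associations(out, line_offset = 1L)
}

#' Validate an association table row-by-row
#'
#' @param df data.frame with canonical columns
#' @param line_offset added to the row index to report file line numbers
#'   (1 for a file with a header row, 0 for in-memory tables)
#' @return the valid rows (class `mr_assoc`) with a `rejections` attribute
#' @export
validate_associations <- function(df, line_offset = 0L) {
  n <- nrow(df)
  reason <- character(n)
  flag <- function(bad, why) {
    bad <- which(bad & reason == "")
    reason[bad] <<- why
  }
  flag(is.na(df$SNP) | df$SNP == "", "missing variant id")
  flag(!(df$effect_allele %in% .BASES) | !(df$other_allele %in% .BASES),
       "allele not one of A/C/G/T")
  flag(df$effect_allele == df$other_allele, "effect allele equals other allele")
  flag(is.na(df$beta), "non-numeric or missing beta")
  flag(is.na(df$se) | df$se <= 0, "non-numeric, missing or non-positive se")
  flag(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "p-value outside (0, 1]")
  flag(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "eaf outside [0, 1]")
  bad <- reason != ""
  rejections <- data.frame(line = which(bad) + line_offset,
                           SNP = df$SNP[bad], reason = reason[bad],
                           stringsAsFactors = FALSE)
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  class(out) <- c("mr_assoc", "data.frame")
  out
}

#' Write an association table in the canonical tab-delimited format
#'
#' @param df association table (canonical columns)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_association_table <- function(df, path) {
  utils::write.table(df[, .CANONICAL_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LD correlation matrix with its variant index
#'
#' The matrix file is a square delimited numeric matrix (no header); the
#' index file lists one rsID per line, in matrix order.  Entries are signed
#' correlations r in [-1, 1] with a unit diagonal; `ld_prune()` squares them.
#'
#' @param path path to the matrix file
#' @param index_path path to the one-column rsID index file
#' @return numeric matrix with rsID dimnames
#' @export
read_ld_matrix <- function(path, index_path) {
  ids <- readLines(index_path)
  ids <- ids[nzchar(ids)]
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (nrow(m) != ncol(m)) stop("LD matrix is not square")
  if (nrow(m) != length(ids))
    stop("LD matrix dimension (", nrow(m), ") does not match index length (",
         length(ids), ")")
  if (any(abs(m) > 1 + 1e-8)) stop("LD matrix entries must lie in [-1, 1]")
  if (any(abs(diag(m) - 1) > 1e-8)) stop("LD matrix diagonal must be 1")
  dimnames(m) <- list(ids, ids)
  m
}

#' Read a proxy map (target rsID, proxy rsID)
#'
#' @param path two-column delimited text file, with or without a header
#'   (a header is assumed when the first field of line 1 is not an rs id)
#' @return data.frame with columns `target`, `proxy` (class `mr_proxy_map`)
#' @export
read_proxy_map <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "[\t, ]+")[[1]][1]
  header <- !grepl("^rs[0-9]", first)
  df <- utils::read.table(path, header = header, stringsAsFactors = FALSE)
  df <- df[, 1:2]
  names(df) <- c("target", "proxy")
  proxy_map(df$target, df$proxy)
}

#' Construct a proxy map
#'
#' @param target character vector of target rsIDs (the variants wanted)
#' @param proxy character vector of proxy rsIDs, same length
#' @return data.frame `target`/`proxy` with class `mr_proxy_map`
#' @export
proxy_map <- function(target = character(), proxy = character()) {
  df <- data.frame(target = as.character(target), proxy = as.character(proxy),
                   stringsAsFactors = FALSE)
  if (any(df$target == df$proxy))
    stop("a variant cannot proxy itself")
  if (anyDuplicated(df$proxy))
    stop("a proxy cannot stand in for two targets: ",
         paste(unique(df$proxy[duplicated(df$proxy)]), collapse = ", "))
  if (anyDuplicated(df$target))
    stop("duplicate target in proxy map")
  class(df) <- c("mr_proxy_map", "data.frame")
  df
}

#' Read an exclusion list (variant id, reason, annotation)
#'
#' One to three delimited columns; missing columns are filled with
#' placeholders.
#'
#' @param path delimited text file
#' @return data.frame with columns `SNP`, `reason`, `annotation`
#' @export
read_exclusion_list <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "[\t, ]+")[[1]][1]
  header <- !grepl("^rs[0-9]", first)
  df <- utils::read.table(path, header = header, sep = "",
                          stringsAsFactors = FALSE)
  out <- data.frame(SNP = as.character(df[[1]]), stringsAsFactors = FALSE)
  out$reason <- if (ncol(df) >= 2) as.character(df[[2]]) else "pleiotropy"
  out$annotation <- if (ncol(df) >= 3) as.character(df[[3]]) else NA_character_
  out
}

#' Substitute proxies for variants absent from a table
#'
#' For every map target absent from `table`: if its proxy is present, the
#' proxy's record is used in the target's stead and the substitution is
#' recorded in the `proxy_for` column; if the proxy is also absent, the
#' target is recorded as unavailable (not an error).  Targets already
#' present in the table are left untouched.
#'
#' @param table association table (canonical columns)
#' @param proxies an `mr_proxy_map` (or NULL for no-op)
#' @return `table` with a `proxy_for` column (NA where no substitution) and
#'   an `unavailable` attribute listing targets that could not be recovered
#' @export
apply_proxy_map <- function(table, proxies = NULL) {
  table$proxy_for <- if ("proxy_for" %in% names(table)) table$proxy_for
                     else NA_character_
  unavailable <- character()
  if (!is.null(proxies) && nrow(proxies) > 0) {
    for (i in seq_len(nrow(proxies))) {
      tgt <- proxies$target[i]; prx <- proxies$proxy[i]
      if (tgt %in% table$SNP) next
      if (prx %in% table$SNP) {
        table$proxy_for[table$SNP == prx] <- tgt
      } else {
        unavailable <- c(unavailable, tgt)
      }
    }
  }
  attr(table, "unavailable") <- unavailable
  table
}

#' Harmonize exposure and outcome association tables
#'
#' Intersects the two tables on variant id and re-orients every outcome
#' association onto the exposure's effect allele.  When the outcome effect
#' allele matches the exposure other allele (directly or after strand
#' complementing), the outcome beta sign is flipped and its eaf
#' complemented.  Palindromic variants (A/T or C/G) carry no strand
#' information in their allele labels and are handled by policy: dropped,
#' or oriented by comparing allele frequencies when both are far enough
#' from 0.5 (outside `0.5 +/- eaf_window`), else dropped.  Incompatible
#' allele pairs are dropped with reason "allele mismatch".
#'
#' @param exposure association table for the exposure (canonical columns)
#' @param outcome association table for the outcome
#' @param palindrome_policy `"drop"` (default) or `"infer-by-eaf"`
#' @param eaf_window half-width of the ambiguity window around eaf 0.5 used
#'   by `"infer-by-eaf"` (default 0.08)
#' @return data.frame of class `mr_harmonized` with columns `SNP`,
#'   `effect_allele`, `other_allele` (exposure orientation), `beta_x`,
#'   `se_x`, `pval_x`, `eaf_x`, `n_x`, `beta_y`, `se_y`, `pval_y`, `eaf_y`,
#'   `n_y`, `orientation` (`"unchanged"` or `"flipped"`); attribute
#'   `report` records one row per input intersection variant with the
#'   action taken and the reason for any drop
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop", "infer-by-eaf"),
                      eaf_window = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (nrow(exposure) == 0 || nrow(outcome) == 0)
    stop("harmonize() requires non-empty exposure and outcome tables")
  common <- intersect(exposure$SNP, outcome$SNP)
  ex <- exposure[match(common, exposure$SNP), , drop = FALSE]
  ou <- outcome[match(common, outcome$SNP), , drop = FALSE]

  n <- length(common)
  keep <- logical(n); flip <- logical(n); reason <- character(n)
  for (j in seq_len(n)) {
    ea1 <- ex$effect_allele[j]; oa1 <- ex$other_allele[j]
    ea2 <- ou$effect_allele[j]; oa2 <- ou$other_allele[j]
    pal <- .is_palindromic(ea1, oa1)
    if (pal) {
      # allele labels cannot resolve strand; same two letters either way
      if (!setequal(c(ea1, oa1), c(ea2, oa2))) {
        reason[j] <- "allele mismatch"; next
      }
      if (palindrome_policy == "drop") {
        reason[j] <- "palindromic (policy: drop)"; next
      }
      ex_eaf <- ex$eaf[j]; ou_eaf <- ou$eaf[j]
      if (is.na(ex_eaf) || is.na(ou_eaf)) {
        reason[j] <- "palindromic, eaf missing"; next
      }
      if (abs(ex_eaf - 0.5) <= eaf_window || abs(ou_eaf - 0.5) <= eaf_window) {
        reason[j] <- "palindromic, eaf too close to 0.5"; next
      }
      # nominal alignment by labels, then frequency concordance decides
      f <- ea2 == oa1
      ou_eaf_aligned <- if (f) 1 - ou_eaf else ou_eaf
      if ((ex_eaf - 0.5) * (ou_eaf_aligned - 0.5) < 0) f <- !f
      keep[j] <- TRUE; flip[j] <- f
    } else {
      if (ea2 == ea1 && oa2 == oa1) {
        keep[j] <- TRUE; flip[j] <- FALSE
      } else if (ea2 == oa1 && oa2 == ea1) {
        keep[j] <- TRUE; flip[j] <- TRUE
      } else if (.complement(ea2) == ea1 && .complement(oa2) == oa1) {
        keep[j] <- TRUE; flip[j] <- FALSE
      } else if (.complement(ea2) == oa1 && .complement(oa2) == ea1) {
        keep[j] <- TRUE; flip[j] <- TRUE
      } else {
        reason[j] <- "allele mismatch"
      }
    }
  }

  h <- data.frame(stringsAsFactors = FALSE,
    SNP = common,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    beta_x = ex$beta, se_x = ex$se, pval_x = ex$pval,
    eaf_x = ex$eaf, n_x = ex$n,
    beta_y = ifelse(flip, -ou$beta, ou$beta), se_y = ou$se,
    pval_y = ou$pval, eaf_y = ifelse(flip, 1 - ou$eaf, ou$eaf), n_y = ou$n,
    orientation = ifelse(flip, "flipped", "unchanged"))
  if ("proxy_for" %in% names(ou)) h$proxy_for <- ou$proxy_for
  report <- data.frame(stringsAsFactors = FALSE,
    SNP = common,
    action = ifelse(keep, ifelse(flip, "flipped", "unchanged"), "dropped"),
    reason = reason)
  h <- h[keep, , drop = FALSE]
  rownames(h) <- NULL
  attr(h, "report") <- report
  class(h) <- c("mr_harmonized", "data.frame")
  h
}
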