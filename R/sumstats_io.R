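# Reading, validation, harmonization and filtering of per-cohort GWAS
# summary statistics.
#
# A "cohort table" is a data.frame with one row per SNP and columns
#   snp_id, chrom, pos, effect_allele, other_allele, eaf, beta, se, p, n
# plus attributes `cohort_name` and `trait`. Rows are sorted by (chrom, pos)
# and snp_id is unique. The on-disk dialect is tab-separated text with the
# canonical header SNP CHR POS EA OA EAF BETA SE P N; `column_map` remaps
# other dialects (e.g. GWAMA-style headers) onto the canonical names.

SUMSTAT_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "p", "n")
CANONICAL_HEADER <- c(SNP = "snp_id", CHR = "chrom", POS = "pos", EA = "effect_allele",
                      OA = "other_allele", EAF = "eaf", BETA = "beta", SE = "se",
                      P = "p", N = "n")

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Construct a validated cohort summary-statistics table
#'
#' Validates row-level invariants (positive standard errors, frequencies and
#' p-values in range, single-character A/C/G/T alleles, distinct alleles,
#' Wald consistency of beta/se with p), drops violating rows into a rejection
#' log, de-duplicates SNP ids, and sorts by (chromosome, position).
#'
#' @param df data.frame with the canonical summary-statistic columns.
#' @param cohort_name,trait character scalars identifying the cohort and trait.
#' @param validate if `FALSE`, only sorting and attributes are applied.
#' @return A cohort table; dropped rows are recorded in `attr(, "rejections")`
#'   as a data.frame with columns `snp_id` and `reason`.
#' @export
cohort_table <- function(df, cohort_name = "cohort", trait = "trait",
                         validate = TRUE) {
  missing_cols <- setdiff(SUMSTAT_COLS, names(df))
  if (length(missing_cols))
    stopf("missing mandatory column(s): %s", paste(missing_cols, collapse = ", "))
  df <- df[SUMSTAT_COLS]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "p", "n"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))

  rej <- data.frame(snp_id = character(), reason = character(),
                    stringsAsFactors = FALSE)
  if (validate && nrow(df)) {
    reason <- rep(NA_character_, nrow(df))
    flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
    num <- c("pos", "eaf", "beta", "se", "p", "n")
    flag(Reduce(`|`, lapply(df[num], function(x) !is.finite(x))), "non_numeric_field")
    flag(!(df$effect_allele %in% names(DNA_COMP)) |
           !(df$other_allele %in% names(DNA_COMP)), "non_snp_allele")
    flag(df$effect_allele == df$other_allele, "identical_alleles")
    flag(!is.na(df$se) & df$se <= 0, "nonpositive_se")
    flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "eaf_out_of_range")
    flag(!is.na(df$p) & (df$p <= 0 | df$p > 1), "p_out_of_range")
    flag(!is.na(df$n) & (df$n < 1 | df$n != round(df$n)), "invalid_n")
    flag(!is.na(df$pos) & (df$pos < 1 | df$pos != round(df$pos)), "invalid_pos")
    ok <- is.na(reason)
    wald_p <- 2 * pnorm(-abs(df$beta / df$se))
    flag(ok & abs(wald_p - df$p) > 0.05, "p_z_inconsistent")
    flag(is.na(reason) & duplicated(df$snp_id), "duplicate_snp_id")
    bad <- !is.na(reason)
    rej <- data.frame(snp_id = df$snp_id[bad], reason = reason[bad],
                      stringsAsFactors = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  df$pos <- as.integer(df$pos)
  df$n <- as.integer(df$n)
  df <- df[order(df$chrom, df$pos, df$snp_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, cohort_name = cohort_name, trait = trait, rejections = rej,
            class = c("cohort_table", "data.frame"))
}

#' Read per-cohort GWAS summary statistics from delimited text
#'
#' @param path path to a tab-separated file with a header row.
#' @param column_map named character vector mapping canonical column names
#'   (`SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N`) to the file's header names;
#'   `NULL` assumes the canonical header.
#' @param cohort_name,trait labels attached to the returned table.
#' @param log_path optional path; dropped rows are appended there as JSON
#'   lines, one object per rejected row with a `reason` code.
#' @inherit cohort_table return
#' @export
read_sumstats <- function(path, column_map = NULL, cohort_name = "cohort",
                          trait = "trait", log_path = NULL) {
  if (!file.exists(path)) stopf("summary-statistics file not found: %s", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stopf("empty summary-statistics file: %s", path)
  file_names <- names(CANONICAL_HEADER)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(CANONICAL_HEADER))
    if (length(unknown))
      stopf("column_map refers to unknown canonical column(s): %s",
            paste(unknown, collapse = ", "))
    file_names[match(names(column_map), names(CANONICAL_HEADER))] <- column_map
  }
  absent <- setdiff(file_names, names(raw))
  if (length(absent))
    stopf("missing mandatory column(s) in %s: %s", path,
          paste(absent, collapse = ", "))
  df <- setNames(raw[file_names], unname(CANONICAL_HEADER))
  tab <- cohort_table(df, cohort_name = cohort_name, trait = trait)
  rej <- attr(tab, "rejections")
  if (!is.null(log_path) && nrow(rej)) {
    lines <- vapply(seq_len(nrow(rej)), function(i) {
      jsonlite::toJSON(list(cohort = cohort_name, trait = trait,
                            snp_id = rej$snp_id[i], reason = rej$reason[i]),
                       auto_unbox = TRUE)
    }, character(1))
    cat(lines, file = log_path, sep = "\n", append = TRUE)
  }
  tab
}

#' Write a cohort table as canonical tab-separated text
#'
#' Numeric fields are written with 17 significant digits so that
#' `read_sumstats(write_sumstats(x))` round-trips exactly.
#'
#' @param table cohort table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  out <- data.frame(SNP = table$snp_id, CHR = table$chrom, POS = table$pos,
                    EA = table$effect_allele, OA = table$other_allele,
                    EAF = sprintf("%.17g", table$eaf),
                    BETA = sprintf("%.17g", table$beta),
                    SE = sprintf("%.17g", table$se),
                    P = sprintf("%.17g", table$p),
                    N = table$n, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter SNPs on minor allele frequency
#'
#' Keeps records with `min(eaf, 1 - eaf)` strictly greater than `threshold`
#' (the boundary is excluded). Idempotent and order-preserving.
#'
#' @param table cohort table (any data.frame with an `eaf` column works).
#' @param threshold MAF cutoff in (0, 0.5); default 0.05.
#' @return The filtered table, attributes preserved.
#' @export
filter_maf <- function(table, threshold = 0.05) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold < 0.5)
  maf <- pmin(table$eaf, 1 - table$eaf)
  keep <- maf > threshold
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out) <- c(attributes(out),
                       attributes(table)[c("cohort_name", "trait")])
  out
}

# Classify one table's alleles against the reference orientation.
# Returns an action per row: keep / flip / drop_palindromic / drop_mismatch /
# absent (not in reference).
classify_alleles <- function(ea, oa, ref_ea, ref_oa, eaf, ref_eaf,
                             palindromic_maf = 0.4) {
  n <- length(ea)
  action <- rep("absent", n)
  shared <- !is.na(ref_ea)
  pal <- shared & (DNA_COMP[ea] == oa)            # A/T or C/G pair
  ref_pal <- shared & !is.na(ref_oa) & (DNA_COMP[ref_ea] == ref_oa)

  same <- shared & ea == ref_ea & oa == ref_oa
  swap <- shared & ea == ref_oa & oa == ref_ea
  csame <- shared & DNA_COMP[ea] == ref_ea & DNA_COMP[oa] == ref_oa
  cswap <- shared & DNA_COMP[ea] == ref_oa & DNA_COMP[oa] == ref_ea

  action[shared] <- "drop_mismatch"
  action[same | csame] <- "keep"
  action[swap | cswap] <- "flip"
  # Palindromic SNPs: strand is unresolvable from the letters. Common and
  # near-0.5 frequencies are ambiguous -> drop; otherwise orient by frequency.
  amb <- shared & (pal | ref_pal) & (same | swap | csame | cswap)
  hi_maf <- pmin(eaf, 1 - eaf) > palindromic_maf
  action[amb & hi_maf] <- "drop_palindromic"
  freq_flip <- amb & !hi_maf & !is.na(ref_eaf) &
    ((eaf < 0.5) != (ref_eaf < 0.5))
  action[amb & !hi_maf] <- "keep"
  action[freq_flip] <- "flip"
  action
}

#' Harmonize allele orientation across cohort tables
#'
#' Aligns every table's effect allele to a reference table: swapped alleles
#' flip the sign of beta and complement the effect-allele frequency;
#' strand-complement records are relabelled to the reference strand;
#' palindromic (A/T, C/G) SNPs with MAF above `palindromic_maf` are dropped as
#' strand-ambiguous, and below it are oriented by allele frequency;
#' irreconcilable allele pairs are dropped. SNPs absent from the reference
#' pass through unchanged. Applying the function twice equals applying it
#' once.
#'
#' @param tables a list of cohort tables.
#' @param reference a cohort table giving the target orientation.
#' @param palindromic_maf MAF cutoff above which palindromic SNPs are
#'   considered strand-ambiguous; default 0.4.
#' @return List of harmonized tables; each carries a per-SNP action log in
#'   `attr(, "harmonization")`.
#' @export
harmonize_alleles <- function(tables, reference, palindromic_maf = 0.4) {
  single <- is.data.frame(tables)
  if (single) tables <- list(tables)
  idx_ref <- setNames(seq_len(nrow(reference)), reference$snp_id)
  if (!any(unlist(lapply(tables, function(t) t$snp_id %in% reference$snp_id))))
    stopf("no SNP id shared between the tables and the reference")
  out <- lapply(tables, function(tab) {
    j <- idx_ref[tab$snp_id]
    ref_ea <- reference$effect_allele[j]
    ref_oa <- reference$other_allele[j]
    ref_eaf <- reference$eaf[j]
    action <- classify_alleles(tab$effect_allele, tab$other_allele,
                               ref_ea, ref_oa, tab$eaf, ref_eaf,
                               palindromic_maf)
    log <- data.frame(snp_id = tab$snp_id, action = action,
                      stringsAsFactors = FALSE)
    flip <- action == "flip"
    tab$beta[flip] <- -tab$beta[flip]
    tab$eaf[flip] <- 1 - tab$eaf[flip]
    aligned <- flip | action == "keep"
    tab$effect_allele[aligned] <- ref_ea[aligned]
    tab$other_allele[aligned] <- ref_oa[aligned]
    tab <- tab[!startsWith(action, "drop"), , drop = FALSE]
    rownames(tab) <- NULL
    attr(tab, "harmonization") <- log
    tab
  })
  if (single) out[[1]] else out
}

#' Per-trait sample-size report across cohorts
#'
#' The cohort-level n for a trait is the maximum per-record n in that cohort's
#' table (per-SNP missingness means individual records may carry smaller n);
#' the trait total is the sum of cohort n values.
#'
#' @param tables list of cohort tables (attributes `cohort_name` and `trait`
#'   identify the cells of the report).
#' @return data.frame with one row per trait: `trait`, one column per cohort,
#'   and `total`.
#' @export
sample_size_report <- function(tables) {
  info <- data.frame(
    trait = vapply(tables, function(t) attr(t, "trait"), character(1)),
    cohort = vapply(tables, function(t) attr(t, "cohort_name"), character(1)),
    n = vapply(tables, function(t) as.numeric(max(t$n)), numeric(1)),
    stringsAsFactors = FALSE)
  traits <- unique(info$trait)
  cohorts <- unique(info$cohort)
  wide <- data.frame(trait = traits, stringsAsFactors = FALSE)
  for (co in cohorts)
    wide[[co]] <- vapply(traits, function(tr) {
      v <- info$n[info$trait == tr & info$cohort == co]
      if (length(v)) sum(v) else NA_real_
    }, numeric(1))
  wide$total <- rowSums(as.matrix(wide[, cohorts, drop = FALSE]), na.rm = TRUE)
  rownames(wide) <- NULL
  wide
}
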