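# Genome-wide-significant SNP selection, locus definition around lead SNPs,
# and novelty flagging against a reference locus list.

#' Select genome-wide-significant meta-analysis records
#'
#' Strict comparison: records with `p_meta < alpha` are kept; a record exactly
#' at the threshold is not significant.
#'
#' @param meta data.frame from [meta_analyze()].
#' @param alpha significance threshold; default `5e-9`.
#' @return The significant subset (possibly empty).
#' @export
select_significant <- function(meta, alpha = 5e-9) {
  stopifnot(alpha > 0, alpha < 1)
  out <- meta[meta$p_meta < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define loci as windows around lead SNPs
#'
#' Greedy, p-ranked: the most significant remaining SNP becomes a lead; every
#' remaining significant SNP on the same chromosome within `window` base
#' pairs (boundary inclusive) joins its locus; repeat until all significant
#' SNPs are assigned. Ties on p break by (chromosome, position) so the result
#' is invariant to input row order.
#'
#' @param significant data.frame of significant records
#'   (see [select_significant()]).
#' @param window half-width of the locus in base pairs; default 250000
#'   (a locus spans lead position +/- 250 kb).
#' @return data.frame with one row per locus: `locus_id, chrom, start, end,
#'   lead_snp, lead_p, n_snps, member_snps` (members as a comma-separated
#'   string, lead first).
#' @export
define_loci <- function(significant, window = 250000) {
  stopifnot(window > 0)
  if (!nrow(significant)) {
    return(data.frame(locus_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      lead_snp = character(), lead_pos = integer(),
                      lead_p = numeric(),
                      n_snps = integer(), member_snps = character(),
                      stringsAsFactors = FALSE))
  }
  sig <- significant[order(significant$p_meta, significant$chrom,
                           significant$pos), , drop = FALSE]
  loci <- list()
  while (nrow(sig)) {
    lead <- sig[1, ]
    in_locus <- sig$chrom == lead$chrom & abs(sig$pos - lead$pos) <= window
    members <- sig[in_locus, ]
    loci[[length(loci) + 1L]] <- data.frame(
      chrom = lead$chrom,
      start = max(1, lead$pos - window),
      end = lead$pos + window,
      lead_snp = lead$snp_id,
      lead_pos = lead$pos,
      lead_p = lead$p_meta,
      n_snps = nrow(members),
      member_snps = paste(members$snp_id, collapse = ","),
      stringsAsFactors = FALSE)
    sig <- sig[!in_locus, , drop = FALSE]
  }
  out <- do.call(rbind, loci)
  out <- cbind(locus_id = sprintf("locus_%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Flag loci as known or novel against a reference position list
#'
#' A locus is `known` when its lead SNP lies within `window` base pairs
#' (boundary inclusive) of any reference position on the same chromosome,
#' matching sentinel-based comparison against a published locus list; with an
#' empty reference every locus is novel.
#'
#' @param loci data.frame from [define_loci()].
#' @param reference data.frame with columns `chrom` and `pos` (see
#'   [read_reference_loci()]).
#' @param window comparison half-width in base pairs; default 250000.
#' @return `loci` with an added logical column `novel`.
#' @export
novelty_check <- function(loci, reference, window = 250000) {
  known <- vapply(seq_len(nrow(loci)), function(i) {
    hit <- reference$chrom == loci$chrom[i] &
      abs(reference$pos - loci$lead_pos[i]) <= window
    any(hit)
  }, logical(1))
  loci$novel <- !known
  loci
}

#' Read a reference locus list for novelty checks
#'
#' Accepts either a 2-column `CHR POS` TSV (1-based points, with header) or a
#' 3-column headerless BED (0-based half-open intervals, converted to 1-based
#' points at the interval midpoint).
#'
#' @param path input path.
#' @param format `"tsv"` or `"bed"`; `"auto"` decides from the extension.
#' @return data.frame with columns `chrom` (character) and `pos` (integer).
#' @export
read_reference_loci <- function(path, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  if (format == "bed") {
    raw <- read.delim(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE)
    start0 <- as.numeric(raw[[2]])
    end0 <- as.numeric(raw[[3]])
    data.frame(chrom = as.character(raw[[1]]),
               pos = as.integer(floor((start0 + end0) / 2) + 1L),
               stringsAsFactors = FALSE)
  } else {
    raw <- read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    data.frame(chrom = as.character(raw[[1]]), pos = as.integer(raw[[2]]),
               stringsAsFactors = FALSE)
  }
}

#' Write a locus table as tab-separated text
#' @param loci data.frame from [define_loci()] (optionally after
#'   [novelty_check()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loci <- function(loci, path) {
  out <- data.frame(LOCUS_ID = loci$locus_id, CHR = loci$chrom,
                    START = loci$start, END = loci$end,
                    LEAD_SNP = loci$lead_snp,
                    LEAD_P = sprintf("%.17g", loci$lead_p),
                    N_SNPS = loci$n_snps,
                    NOVEL = if (is.null(loci$novel)) NA else loci$novel,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
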