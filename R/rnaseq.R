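#' Assign a read pair to a genome of origin
#'
#' Xenograft RNA-seq reads come from both the human graft and the mouse
#' host.  Each pair, aligned to both genomes, is placed in one of four
#' groups: `unaligned` (neither genome), `human_only` / `mouse_only`
#' (exactly one genome aligns, or both align and one wins the comparison),
#' or `common` (both align and the metrics tie).  When both genomes align,
#' the comparison is lexicographic over the mate-summed metrics: alignment
#' score (higher wins; differences within `tolerance` are ties), then number
#' of mismatched bases (fewer wins), then matched segment length (longer
#' wins).  A tie on all three yields `common`.
#'
#' @param score_h,nm_h,mlen_h Score, mismatches, matched length on the human
#'   genome (NA when unaligned).
#' @param score_m,nm_m,mlen_m Same for the mouse genome.
#' @param aligned_h,aligned_m Logical; defaults to "metrics present".
#' @param tolerance Score difference (score units) treated as a tie;
#'   default 0 (exact tie).
#' @return One of `"human_only"`, `"mouse_only"`, `"common"`, `"unaligned"`.
#' @export
assign_read <- function(score_h = NA, nm_h = NA, mlen_h = NA,
                        score_m = NA, nm_m = NA, mlen_m = NA,
                        aligned_h = !is.na(score_h),
                        aligned_m = !is.na(score_m),
                        tolerance = 0) {
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  if (!aligned_h && !aligned_m) return("unaligned")
  if (aligned_h && !aligned_m) return("human_only")
  if (!aligned_h && aligned_m) return("mouse_only")
  if (any(c(mlen_h, mlen_m) < 0, na.rm = TRUE))
    stop("matched length cannot be negative", call. = FALSE)
  if (abs(score_h - score_m) > tolerance)
    return(if (score_h > score_m) "human_only" else "mouse_only")
  if (nm_h != nm_m)
    return(if (nm_h < nm_m) "human_only" else "mouse_only")
  if (mlen_h != mlen_m)
    return(if (mlen_h > mlen_m) "human_only" else "mouse_only")
  "common"
}

#' Assign every read pair in a summary table
#'
#' @param pairs Data.frame in the read-summary layout produced by
#'   [simulate_read_pairs()] or [read_pair_summary()] (columns `score_h`,
#'   `nm_h`, `mlen_h`, `score_m`, `nm_m`, `mlen_m`, optional `aligned_h`,
#'   `aligned_m`).
#' @param tolerance Passed to [assign_read()].
#' @return Character vector of assignments, one per row.
#' @export
assign_reads <- function(pairs, tolerance = 0) {
  al_h <- if ("aligned_h" %in% names(pairs)) pairs$aligned_h else !is.na(pairs$score_h)
  al_m <- if ("aligned_m" %in% names(pairs)) pairs$aligned_m else !is.na(pairs$score_m)
  vapply(seq_len(nrow(pairs)), function(i) {
    assign_read(pairs$score_h[i], pairs$nm_h[i], pairs$mlen_h[i],
                pairs$score_m[i], pairs$nm_m[i], pairs$mlen_m[i],
                aligned_h = al_h[i], aligned_m = al_m[i],
                tolerance = tolerance)
  }, character(1))
}

#' Read the TSV read-pair summary format
#'
#' Columns: `read_id, score_h, nm_h, mlen_h, score_m, nm_m, mlen_m` and
#' optionally `true_origin`.  Empty or NA metric cells mean the pair did not
#' align to that genome.
#'
#' @param path TSV path.
#' @return Data.frame with an `aligned_h`/`aligned_m` pair of columns added.
#' @export
read_pair_summary <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("read_id", "score_h", "nm_h", "mlen_h",
                "score_m", "nm_m", "mlen_m")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("read-summary TSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  df$aligned_h <- !is.na(df$score_h)
  df$aligned_m <- !is.na(df$score_m)
  df
}

#' Reads retained for graft expression quantification
#'
#' To remove host (mouse) RNA contamination, only pairs assigned
#' `human_only` or `common` are carried into quantification.
#'
#' @param assignments Character vector from [assign_reads()].
#' @return Logical vector: TRUE for retained pairs.
#' @export
retained_for_quantification <- function(assignments) {
  assignments %in% c("human_only", "common")
}

#' Fragments per kilobase of transcript per million assigned reads
#'
#' `fpkm = counts * 1e9 / (gene_length_bp * total_assigned_reads)`.
#'
#' @param counts Fragment counts for the gene (vector OK).
#' @param gene_length_bp Transcript length in bp (> 0).
#' @param total_assigned_reads Library size after read assignment (> 0).
#' @return FPKM value(s).
#' @export
fpkm <- function(counts, gene_length_bp, total_assigned_reads) {
  stopifnot(all(gene_length_bp > 0), all(total_assigned_reads > 0))
  counts * 1e9 / (gene_length_bp * total_assigned_reads)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving (the i-th output corresponds to the i-th input).
#'
#' @param pvalues Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential-expression filter
#'
#' Applies the three-criterion up/down call to a per-gene statistics table:
#' a gene is `up` when log2 fold change > 1, mean FPKM > 1, and the
#' BH-adjusted p-value < 0.05; `down` when log2 fold change < -1 with the
#' same other conditions; otherwise `unchanged`.  All inequalities are
#' strict.  If the table has no `padj` column it is computed from `pvalue`
#' by [bh_adjust()].
#'
#' @param genes Data.frame with columns `log2fc`, `mean_fpkm`, and `padj`
#'   (or `pvalue`).
#' @param lfc_min Absolute log2-fold-change threshold (default 1).
#' @param fpkm_min Mean-FPKM threshold (default 1).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return The input with `padj` filled in and a `call` column
#'   (`"up"`/`"down"`/`"unchanged"`) added.
#' @export
de_filter <- function(genes, lfc_min = 1, fpkm_min = 1, alpha = 0.05) {
  required <- c("log2fc", "mean_fpkm")
  missing <- setdiff(required, names(genes))
  if (length(missing))
    stop(sprintf("gene table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (is.null(genes$padj)) {
    if (is.null(genes$pvalue))
      stop("gene table needs `padj` or `pvalue`", call. = FALSE)
    genes$padj <- bh_adjust(genes$pvalue)
  }
  pass <- genes$mean_fpkm > fpkm_min & genes$padj < alpha
  genes$call <- ifelse(pass & genes$log2fc > lfc_min, "up",
                ifelse(pass & genes$log2fc < -lfc_min, "down", "unchanged"))
  genes
}

#' Responder grouping
#'
#' Splits xenograft models into good responders (those achieving CR or MCR)
#' and poor responders (PR, SD or PD) from an activity table, for
#' differential-expression contrasts.
#'
#' @param models Character vector of model ids.
#' @param categories Matching response categories.
#' @return List with disjoint character vectors `good` and `poor`.
#' @export
responder_grouping <- function(models, categories) {
  stopifnot(length(models) == length(categories))
  categories <- vapply(categories, function(x)
    match.arg(x, RESPONSE_LEVELS), character(1))
  good <- models[categories %in% c("CR", "MCR")]
  poor <- models[!categories %in% c("CR", "MCR")]
  if (!length(good) || !length(poor))
    stop("both responder groups must be non-empty", call. = FALSE)
  list(good = good, poor = poor)
}
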