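#' Genomic inflation factor lambda
#'
#' `lambda = median(chi2) / median(Chi2_1)` where each p-value is converted
#' to its chi-square(1 df) quantile (`qchisq(p, 1, lower.tail = FALSE)`)
#' and the reference median `qchisq(0.5, 1)` (~0.4549) is computed at run
#' time from the inverse CDF. Lambda ~ 1 indicates a well-calibrated null.
#'
#' @param p_values vector of p-values in (0, 1]; NAs are dropped.
#' @return list of class `inflation_stat` with `lambda` and `n_pvalues`.
#' @export
genomic_inflation <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no p-values supplied", call. = FALSE)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  if (length(p) < 100L)
    warning("fewer than 100 p-values; lambda is unstable")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lam <- stats::median(chi) / stats::qchisq(0.5, df = 1)
  structure(list(lambda = lam, n_pvalues = length(p)), class = "inflation_stat")
}

#' QQ-plot data for a p-value vector
#'
#' Sorts observed p-values ascending and pairs them with uniform expected
#' quantiles `(rank - 0.5) / n`, both on the -log10 scale. Emits the
#' plotting table only; no rendering.
#'
#' @param p_values vector of p-values in (0, 1]; NAs are dropped.
#' @return data.frame with columns `expected` and `observed`
#'   (-log10 scale), rows ordered by ascending p-value (most significant
#'   first).
#' @export
qq_data <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no p-values supplied", call. = FALSE)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  p <- sort(p)
  n <- length(p)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n), observed = -log10(p))
}

#' Classify probes into significance tiers
#'
#' `significant` iff `p <= sig` (boundary included); `suggestive` iff
#' `sig < p < suggestive` (strict upper boundary); otherwise `none`.
#' Flagged rows (missing p) get tier `flagged`.
#'
#' @param results an `ewas_result` data.frame with `probe_id`, `p_value`.
#' @param sig significance threshold (typically Bonferroni).
#' @param suggestive suggestive threshold (default 1e-5).
#' @return data.frame with `probe_id`, `p_value`, `tier`, plus the
#'   thresholds as attributes.
#' @export
classify_hits <- function(results, sig, suggestive = 1e-5) {
  if (!is.numeric(sig) || sig <= 0 || sig >= 1 ||
      !is.numeric(suggestive) || suggestive <= 0 || suggestive >= 1)
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  if (sig >= suggestive)
    stop("'sig' must be smaller than 'suggestive'", call. = FALSE)
  p <- results$p_value
  tier <- ifelse(is.na(p), "flagged",
                 ifelse(p <= sig, "significant",
                        ifelse(p < suggestive, "suggestive", "none")))
  out <- data.frame(probe_id = results$probe_id, p_value = p, tier = tier,
                    stringsAsFactors = FALSE)
  attr(out, "sig") <- sig
  attr(out, "suggestive") <- suggestive
  out
}

#' Annotate results with the manifest and write result/Manhattan files
#'
#' Attaches the nearest-gene label and genomic coordinates from the
#' manifest, orders rows by (p-value, probe_id) with flagged rows last,
#' writes a tab-separated results file and a BED-like Manhattan data file
#' (`chrom`, `pos - 1`, `pos`, `neg_log10_p`, `tier`; 0-based half-open
#' intervals).
#'
#' @param results an `ewas_result` data.frame.
#' @param manifest the `probe_manifest` covering all result probes.
#' @param out_prefix path prefix; writes `<prefix>_results.tsv` and
#'   `<prefix>_manhattan.bed`.
#' @param sig,suggestive thresholds for the tier column.
#' @return (invisibly) list with the annotated table and the two paths.
#' @export
annotate_and_write <- function(results, manifest, out_prefix,
                               sig, suggestive = 1e-5) {
  idx <- match(results$probe_id, manifest$probe_id)
  if (anyNA(idx))
    stop(sprintf("probes missing from manifest: %s",
                 paste(results$probe_id[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  ann <- results
  ann$nearest_gene <- manifest$nearest_gene[idx]
  ann$chrom <- manifest$chrom[idx]
  ann$pos <- manifest$pos[idx]
  ann$tier <- classify_hits(results, sig, suggestive)$tier
  ord <- order(ann$p_value, ann$probe_id, na.last = TRUE)
  ann <- ann[ord, , drop = FALSE]
  res_path <- paste0(out_prefix, "_results.tsv")
  utils::write.table(ann, res_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  man <- ann[!is.na(ann$p_value), , drop = FALSE]
  manhattan <- data.frame(chrom = man$chrom, start = man$pos - 1L,
                          end = man$pos, neg_log10_p = -log10(man$p_value),
                          tier = man$tier, stringsAsFactors = FALSE)
  bed_path <- paste0(out_prefix, "_manhattan.bed")
  utils::write.table(manhattan, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(list(table = ann, results_path = res_path,
                 manhattan_path = bed_path))
}
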