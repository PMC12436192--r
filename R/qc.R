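#' Quality-control thresholds for sample exclusion
#'
#' @param min_call_rate samples with a call rate (fraction of non-missing
#'   genomic probes passing detection) strictly below this are excluded.
#' @param max_missing_signal_frac samples completely lacking signal in at
#'   least this fraction of probes are excluded.
#' @param control_outlier_sd number of robust SDs (median +/- k * 1.4826 * MAD)
#'   beyond which a sample's per-class control-probe mean flags it.
#' @param sex_check compare predicted against reported sex.
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, max_missing_signal_frac = 0.05,
                          control_outlier_sd = 4, sex_check = TRUE) {
  if (min_call_rate <= 0 || min_call_rate > 1 ||
      max_missing_signal_frac <= 0 || max_missing_signal_frac > 1)
    stop("QC fractions must lie in (0, 1]", call. = FALSE)
  if (control_outlier_sd <= 0)
    stop("'control_outlier_sd' must be positive", call. = FALSE)
  structure(list(min_call_rate = min_call_rate,
                 max_missing_signal_frac = max_missing_signal_frac,
                 control_outlier_sd = control_outlier_sd,
                 sex_check = isTRUE(sex_check)),
            class = "qc_thresholds")
}

#' Predict sample sex from sex-chromosome methylation
#'
#' Uses two documented signals: the fraction of chrY probes passing
#' detection (males retain Y signal, females do not; primary signal when Y
#' probes exist) and the fraction of chrX beta values in the intermediate
#' band (0.25, 0.75) (X inactivation leaves females intermediate, males near
#' 0 or 1; used when no Y probes are available). Cutoffs: male iff chrY
#' detection fraction >= 0.5; otherwise female iff chrX intermediate
#' fraction >= 0.3.
#'
#' @param dataset a `methylation_dataset`.
#' @param manifest the matching `probe_manifest`.
#' @return data.frame with `sample_id`, `predicted_sex` ("M"/"F", or NA when
#'   uncallable), `status` ("ok"/"uncallable"), `chrY_detection`,
#'   `chrX_intermediate`.
#' @export
predict_sex <- function(dataset, manifest) {
  genomic <- manifest[!manifest$is_control, , drop = FALSE]
  y_ids <- intersect(genomic$probe_id[genomic$chrom %in% "Y"], colnames(dataset$betas))
  x_ids <- intersect(genomic$probe_id[genomic$chrom %in% "X"], colnames(dataset$betas))
  n <- nrow(dataset$betas)
  y_det <- x_mid <- rep(NA_real_, n)
  if (length(y_ids))
    y_det <- rowMeans(dataset$detection_mask[, y_ids, drop = FALSE])
  if (length(x_ids)) {
    xb <- dataset$betas[, x_ids, drop = FALSE]
    x_mid <- rowMeans(xb > 0.25 & xb < 0.75, na.rm = TRUE)
  }
  if (!length(y_ids) && !length(x_ids)) {
    pred <- rep(NA_character_, n)
    status <- rep("uncallable", n)
  } else if (length(y_ids)) {
    pred <- ifelse(y_det >= 0.5, "M", "F")
    status <- rep("ok", n)
  } else {
    pred <- ifelse(x_mid >= 0.3, "F", "M")
    status <- rep("ok", n)
  }
  data.frame(sample_id = rownames(dataset$betas), predicted_sex = pred,
             status = status, chrY_detection = y_det,
             chrX_intermediate = x_mid, stringsAsFactors = FALSE)
}

#' Sample-level quality control
#'
#' Applies the four exclusion rules: call rate below `min_call_rate`
#' (fraction of genomic probes passing detection), missing signal in at
#' least `max_missing_signal_frac` of probes (beta absent), mismatch
#' between reported and predicted sex, and a per-class control-probe mean
#' beyond `control_outlier_sd` robust SDs (median +/- k * 1.4826 * MAD)
#' from the cohort median.
#'
#' @param dataset a `methylation_dataset` (typically baseline).
#' @param sheet the matching `sample_sheet`.
#' @param manifest the matching `probe_manifest`.
#' @param thresholds a [qc_thresholds()] object.
#' @return data.frame of class `qc_report`, one row per sample, with
#'   per-rule metrics, `excluded`, and a semicolon-separated
#'   `exclusion_reasons` string (empty when retained).
#' @export
sample_qc <- function(dataset, sheet, manifest, thresholds = qc_thresholds()) {
  if (nrow(dataset$betas) == 0L) stop("empty dataset", call. = FALSE)
  ids <- rownames(dataset$betas)
  sheet <- sheet[match(ids, sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id))
    stop("sample sheet does not cover all dataset samples", call. = FALSE)

  # call rate: fraction of non-missing genomic probes passing detection;
  # missing signal: fraction of probes with no measurable beta at all
  has_signal <- !is.na(dataset$betas)
  call_rate <- rowSums(dataset$detection_mask & has_signal) / rowSums(has_signal)
  missing_signal_frac <- rowMeans(!has_signal)

  sexp <- predict_sex(dataset, manifest)
  sex_mismatch <- rep(FALSE, length(ids))
  if (thresholds$sex_check && all(sexp$status == "ok"))
    sex_mismatch <- sexp$predicted_sex != sheet$reported_sex

  # control-probe outliers: robust z of per-sample class means, centered
  # within processing batch when known so plate-level shifts (ordinary
  # technical variation, removed later by the control PCs) do not read as
  # per-sample artifacts
  ctrl_man <- manifest[manifest$is_control, , drop = FALSE]
  classes <- unique(ctrl_man$control_class)
  ctrl_flag <- matrix(FALSE, length(ids), length(classes),
                      dimnames = list(ids, classes))
  batch <- if ("batch" %in% names(sheet) && !anyNA(sheet$batch)) sheet$batch
           else rep(1L, length(ids))
  for (cl in classes) {
    cols <- intersect(ctrl_man$probe_id[ctrl_man$control_class == cl],
                      colnames(dataset$control_betas))
    if (!length(cols)) next
    # class means on the logit scale, where control intensities are
    # additive and homoscedastic across samples
    cb <- dataset$control_betas[, cols, drop = FALSE]
    cm <- rowMeans(stats::qlogis(pmin(pmax(cb, 1e-6), 1 - 1e-6)), na.rm = TRUE)
    # leave-one-out batch median: a sample is compared against the other
    # arrays of its batch, so its own value cannot shrink the reference
    centered <- cm
    for (b in unique(batch)) {
      i <- which(batch == b)
      if (length(i) >= 3L) {
        # normalize by the LOO-median noise factor so batches of different
        # sizes contribute deviations on a common scale
        fac <- sqrt(1 + pi / (2 * (length(i) - 1)))
        for (j in i) centered[j] <- (cm[j] - stats::median(cm[setdiff(i, j)])) / fac
      } else {
        centered[i] <- cm[i] - stats::median(cm)
      }
    }
    mad_ <- stats::mad(centered)  # already scaled by 1.4826
    if (mad_ == 0) next
    ctrl_flag[, cl] <- abs(centered) > thresholds$control_outlier_sd * mad_
  }
  control_outlier <- rowSums(ctrl_flag) > 0

  reasons <- mapply(function(cr, ms, sm, co) {
    r <- c(if (cr < thresholds$min_call_rate) "call_rate",
           if (ms >= thresholds$max_missing_signal_frac) "missing_signal",
           if (sm) "sex_mismatch",
           if (co) "control_outlier")
    paste(r, collapse = ";")
  }, call_rate, missing_signal_frac, sex_mismatch, control_outlier)

  out <- data.frame(sample_id = ids, call_rate = call_rate,
                    missing_signal_frac = missing_signal_frac,
                    predicted_sex = sexp$predicted_sex,
                    sex_mismatch = sex_mismatch,
                    control_outlier = control_outlier,
                    excluded = nzchar(reasons),
                    exclusion_reasons = unname(reasons),
                    stringsAsFactors = FALSE)
  attr(out, "control_flags") <- ctrl_flag
  attr(out, "thresholds") <- thresholds
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Probe-level filtering
#'
#' Removes probes with a SNP within `snp_dist_max` bp at minor allele
#' frequency >= `snp_maf_min` (both conditions required), cross-reactive
#' probes, control probes, and (by default) sex-chromosome probes, whose
#' sex-linked bimodality makes unstratified association tests
#' anti-conservative under any sex imbalance. A probe triggering both the
#' SNP and cross-reactive rules is tallied under SNP (documented
#' precedence).
#'
#' @param manifest a `probe_manifest`.
#' @param snp_dist_max maximum SNP distance (bp) for removal.
#' @param snp_maf_min minimum minor allele frequency for removal.
#' @param drop_cross_reactive,drop_controls,drop_sex_chrom toggle the
#'   respective rules.
#' @return a list of class `probe_keep_list` with `kept_probe_ids`,
#'   `n_removed_snp`, `n_removed_cross`, `n_removed_control`,
#'   `n_removed_sex`, `n_evaluated`.
#' @export
filter_probes <- function(manifest, snp_dist_max = 5L, snp_maf_min = 0.01,
                          drop_cross_reactive = TRUE, drop_controls = TRUE,
                          drop_sex_chrom = TRUE) {
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  snp_hit <- !is.na(manifest$snp_dist_bp) & manifest$snp_dist_bp <= snp_dist_max &
    !is.na(manifest$snp_maf) & manifest$snp_maf >= snp_maf_min
  cross_hit <- drop_cross_reactive & manifest$cross_reactive
  ctrl_hit <- drop_controls & manifest$is_control
  sex_hit <- drop_sex_chrom & manifest$chrom %in% c("X", "Y")
  snp_hit <- snp_hit & !manifest$is_control
  removed <- snp_hit | cross_hit | ctrl_hit | sex_hit
  structure(list(
    kept_probe_ids = manifest$probe_id[!removed],
    n_removed_snp = sum(snp_hit),
    n_removed_cross = sum(cross_hit & !snp_hit),  # SNP-first precedence
    n_removed_control = sum(ctrl_hit),
    n_removed_sex = sum(sex_hit & !snp_hit & !cross_hit),
    n_evaluated = sum(!removed)),
    class = "probe_keep_list")
}

#' Bonferroni family-wise significance threshold
#'
#' @param n_evaluated number of evaluated probes.
#' @param alpha family-wise error rate.
#' @return `alpha / n_evaluated`.
#' @examples
#' bonferroni_threshold(780145)  # 6.409e-08
#' @export
bonferroni_threshold <- function(n_evaluated, alpha = 0.05) {
  if (!is.numeric(n_evaluated) || length(n_evaluated) != 1L || n_evaluated < 1)
    stop("'n_evaluated' must be a positive integer", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  alpha / n_evaluated
}

#' Label treatment response from HAM-A trajectories
#'
#' A patient is a responder iff the HAM-A score decreased by at least 50%
#' between the two timepoints: `(hama_from - hama_to) / hama_from >= 0.5`
#' (boundary included). Controls are excluded; patients missing either
#' score are labelled `"missing"`.
#'
#' @param sheet a `sample_sheet`.
#' @param from_tp,to_tp timepoints `"T0"`, `"T1"`, `"T2"` with
#'   `from_tp` earlier.
#' @return named character vector over patients: `"responder"`,
#'   `"non-responder"` or `"missing"`.
#' @export
label_response <- function(sheet, from_tp = "T0", to_tp = "T1") {
  tps <- c(T0 = 1L, T1 = 2L, T2 = 3L)
  if (!from_tp %in% names(tps) || !to_tp %in% names(tps) ||
      tps[[from_tp]] >= tps[[to_tp]])
    stop("'from_tp' must be an earlier timepoint than 'to_tp'", call. = FALSE)
  pat <- sheet[sheet$group == "patient", , drop = FALSE]
  from <- pat[[paste0("hama_", tolower(from_tp))]]
  to <- pat[[paste0("hama_", tolower(to_tp))]]
  zero_base <- !is.na(from) & from == 0
  if (any(zero_base))
    warning(sprintf("%d patient(s) with zero baseline HAM-A labelled missing",
                    sum(zero_base)))
  dec <- (from - to) / from
  lab <- ifelse(is.na(from) | is.na(to) | zero_base, "missing",
                ifelse(dec >= 0.5, "responder", "non-responder"))
  stats::setNames(lab, pat$sample_id)
}
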