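#' Build a validated pipeline run configuration
#'
#' Collects every tunable of the end-to-end synthetic EWAS run: cohort and
#' array dimensions, effect structure, QC thresholds, number of
#' control-probe PCs, significance thresholds and the designs to run. The
#' configuration is echoed verbatim into the run summary. A single global
#' seed expands to per-stage seeds by a fixed counter scheme
#' (`stage_seed = seed + stage_index`).
#'
#' @param seed global integer seed.
#' @param n_probes,n_control_probes,n_reference array dimensions.
#' @param n_patients,n_controls cohort sizes.
#' @param effects an [effect_spec()].
#' @param responder_frac target responder fraction at T1.
#' @param qc_violations planted QC violator counts (see [generate_cohort()]).
#' @param thresholds a [qc_thresholds()] object.
#' @param k_pcs number of control-probe principal components (default 10).
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param suggestive suggestive significance threshold.
#' @param designs subset of `case_control`, `response_binary`,
#'   `response_continuous`, `longitudinal_delta`, `smoking_robust`.
#' @param frac_snp_close,frac_cross_reactive manifest filter-flag fractions.
#' @param separation cell-reference separation (see [generate_reference()]).
#' @param dropout follow-up dropout fractions (see [generate_cohort()]).
#' @param write_matrices write adjusted M-value matrices to the run
#'   directory (large files; on by default).
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_probes = 5000L, n_control_probes = 120L,
                       n_reference = 100L, n_patients = 100L, n_controls = 100L,
                       effects = effect_spec(), responder_frac = 0.5,
                       qc_violations = list(low_call = 1L, missing_signal = 1L,
                                            sex_mismatch = 1L, control_outlier = 1L),
                       thresholds = qc_thresholds(), k_pcs = 10L, alpha = 0.05,
                       suggestive = 1e-5,
                       designs = c("case_control", "response_binary",
                                   "response_continuous", "longitudinal_delta",
                                   "smoking_robust"),
                       frac_snp_close = 0.02, frac_cross_reactive = 0.05,
                       separation = 1,
                       dropout = c(t1_clinical = 0.11, t2_clinical = 0.19,
                                   t1_meth = 0.21, t2_meth = 0.26),
                       write_matrices = TRUE) {
  known <- c("case_control", "response_binary", "response_continuous",
             "longitudinal_delta", "smoking_robust")
  bad <- setdiff(designs, known)
  if (length(bad))
    stop(sprintf("unknown designs: %s", paste(bad, collapse = ", ")), call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || suggestive <= 0 || suggestive >= 1)
    stop("alpha and suggestive must lie in (0, 1)", call. = FALSE)
  if (k_pcs < 1) stop("'k_pcs' must be positive", call. = FALSE)
  stopifnot(inherits(effects, "effect_spec"), inherits(thresholds, "qc_thresholds"))
  structure(list(seed = as.integer(seed), n_probes = as.integer(n_probes),
                 n_control_probes = as.integer(n_control_probes),
                 n_reference = as.integer(n_reference),
                 n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls), effects = effects,
                 responder_frac = responder_frac, qc_violations = qc_violations,
                 thresholds = thresholds, k_pcs = as.integer(k_pcs),
                 alpha = alpha, suggestive = suggestive, designs = designs,
                 frac_snp_close = frac_snp_close,
                 frac_cross_reactive = frac_cross_reactive,
                 separation = separation, dropout = dropout,
                 write_matrices = isTRUE(write_matrices)),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full synthetic EWAS pipeline
#'
#' Executes simulate -> QC -> probe filter -> preprocess -> associate ->
#' report and writes every artifact to `out_dir`: QC report, probe
#' keep-list, control-PC scores, cell fractions, adjusted matrices
#' (optional), per-design result and Manhattan-data files, QQ tables, and
#' a machine-readable `summary.json` that echoes the configuration,
#' reports per-design sample sizes, the realized Bonferroni threshold at
#' full precision, genomic-inflation lambdas, hit counts, and an MD5
#' content hash for every output file. Re-running with the same
#' configuration yields bit-identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if absent).
#' @return (invisibly) the summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  keep_file <- function(path) { files <<- c(files, path); path }

  # --- stage 1: simulate --------------------------------------------------
  sim <- .stage("simulate", {
    manifest <- generate_manifest(config$n_probes, config$n_control_probes,
                                  config$n_reference, config$frac_snp_close,
                                  config$frac_cross_reactive,
                                  seed = config$seed + 1L)
    reference <- generate_reference(config$n_reference, config$separation,
                                    seed = config$seed + 2L)
    cohort <- generate_cohort(manifest, reference, config$n_patients,
                              config$n_controls, config$effects,
                              config$responder_frac, config$qc_violations,
                              dropout = config$dropout, seed = config$seed + 3L)
    list(manifest = manifest, reference = reference, cohort = cohort)
  })
  manifest <- sim$manifest; reference <- sim$reference; cohort <- sim$cohort
  write_manifest(manifest, keep_file(file.path(out_dir, "manifest.tsv")))
  write_sample_sheet(cohort$sheet, keep_file(file.path(out_dir, "sample_sheet.csv")))

  # --- stage 2: sample QC (baseline; exclusion propagates to all analyses)
  qc <- .stage("qc", sample_qc(cohort$t0, cohort$sheet, manifest, config$thresholds))
  utils::write.table(qc, keep_file(file.path(out_dir, "qc_report.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pass <- qc$sample_id[!qc$excluded]
  sheet <- cohort$sheet[cohort$sheet$sample_id %in% pass, , drop = FALSE]
  sub_rows <- function(ds, ids) {
    keep <- rownames(ds$betas) %in% ids
    ds$betas <- ds$betas[keep, , drop = FALSE]
    ds$detection_mask <- ds$detection_mask[keep, , drop = FALSE]
    ds$control_betas <- ds$control_betas[keep, , drop = FALSE]
    ds
  }
  t0 <- sub_rows(cohort$t0, pass)
  t1 <- sub_rows(cohort$t1, pass)
  t2 <- sub_rows(cohort$t2, pass)

  # --- stage 3: probe filter ---------------------------------------------
  keep <- .stage("filter", filter_probes(manifest))
  writeLines(keep$kept_probe_ids, keep_file(file.path(out_dir, "keep_list.txt")))
  bonf <- bonferroni_threshold(keep$n_evaluated, config$alpha)
  # at small probe counts the Bonferroni threshold can exceed the suggestive
  # threshold; the suggestive tier is then vacuous
  sug_eff <- max(config$suggestive, bonf * (1 + 1e-9))

  # --- stage 4: preprocess (baseline) ------------------------------------
  ref_ids <- manifest$probe_id[manifest$is_cell_reference]
  pre <- .stage("preprocess", {
    m0 <- beta_to_m(t0$betas[, keep$kept_probe_ids, drop = FALSE])
    pcs0 <- control_pcs(t0$control_betas, config$k_pcs)
    cells0 <- estimate_cell_fractions(t0$betas[, ref_ids, drop = FALSE], reference)
    covars0 <- cbind(pcs0$scores, cells0$fractions)
    adj0 <- residualize(m0, covars0)
    list(m0 = m0, pcs0 = pcs0, cells0 = cells0, adj0 = adj0)
  })
  utils::write.table(
    data.frame(sample_id = rownames(t0$betas), pre$cells0$fractions,
               residual_norm = pre$cells0$residual_norm, check.names = FALSE),
    keep_file(file.path(out_dir, "cell_fractions_t0.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = rownames(t0$betas), pre$pcs0$scores, check.names = FALSE),
    keep_file(file.path(out_dir, "control_pcs_t0.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (config$write_matrices)
    write_beta_matrix(pre$adj0$residuals,
                      keep_file(file.path(out_dir, "adjusted_t0.tsv")))

  is_patient <- sheet$group == "patient"
  sex01 <- as.numeric(sheet$reported_sex == "M")
  summary_designs <- list()
  report_design <- function(name, res) {
    lam <- tryCatch(genomic_inflation(res$p_value)$lambda, error = function(e) NA_real_,
                    warning = function(w) suppressWarnings(genomic_inflation(res$p_value)$lambda))
    cls <- classify_hits(res, bonf, sug_eff)
    out <- annotate_and_write(res, manifest,
                              file.path(out_dir, name), bonf, sug_eff)
    keep_file(out$results_path); keep_file(out$manhattan_path)
    if (any(!is.na(res$p_value))) {
      qq <- qq_data(res$p_value[!is.na(res$p_value)])
      utils::write.table(qq, keep_file(file.path(out_dir, paste0(name, "_qq.tsv"))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summary_designs[[name]] <<- list(
      n_used = res$n_used[1L], lambda = lam,
      n_significant = sum(cls$tier == "significant"),
      n_suggestive = sum(cls$tier == "suggestive"),
      n_flagged = sum(cls$tier == "flagged"))
    res
  }

  assoc <- .stage("associate", {
    if ("case_control" %in% config$designs) {
      cc <- welch_case_control(pre$adj0, is_patient,
                               t0$betas[, keep$kept_probe_ids, drop = FALSE])
      cc <- report_design("case_control", cc)
      sig_ids <- cc$probe_id[!is.na(cc$p_value) & cc$p_value <= bonf]
      if (length(sig_ids)) {
        ph <- posthoc_depression_adjust(pre$adj0, is_patient, sheet$depression,
                                        sig_ids, bonf, sug_eff)
        utils::write.table(ph, keep_file(file.path(out_dir, "posthoc_depression.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    if ("smoking_robust" %in% config$designs) {
      sm_rows <- which(is_patient & !is.na(sheet$smoking))
      sm_cov <- cbind(sex = sex01[sm_rows], age = sheet$age[sm_rows],
                      pre$cells0$fractions[sm_rows, , drop = FALSE],
                      pre$pcs0$scores[sm_rows, , drop = FALSE])
      sm <- smoking_ewas_robust(t0$betas[sm_rows, keep$kept_probe_ids, drop = FALSE],
                                sheet$smoking[sm_rows], sm_cov)
      report_design("smoking_robust", sm)
    }
    for (tp in c("T1", "T2")) {
      tpl <- tolower(tp)
      labels <- label_response(sheet, "T0", tp)
      labelled <- names(labels)[labels != "missing"]
      rows <- match(labelled, sheet$sample_id)
      resp <- labels[labelled] == "responder"
      if ("response_binary" %in% config$designs && length(labelled) > config$k_pcs + 12L) {
        cov_b <- cbind(pre$pcs0$scores[rows, , drop = FALSE],
                       pre$cells0$fractions[rows, , drop = FALSE],
                       age = sheet$age[rows], sex = sex01[rows],
                       smoking = as.numeric(sheet$smoking[rows]),
                       depression = as.numeric(sheet$depression[rows]),
                       hama_t0 = sheet$hama_t0[rows])
        rb <- predict_response_logistic(pre$m0[rows, , drop = FALSE], resp, cov_b)
        report_design(paste0("response_binary_", tpl), rb)
      }
      if ("response_continuous" %in% config$designs && length(labelled) > config$k_pcs + 12L) {
        pct <- 100 * (sheet$hama_t0[rows] - sheet[[paste0("hama_", tpl)]][rows]) /
          sheet$hama_t0[rows]
        cov_c <- cbind(pre$pcs0$scores[rows, , drop = FALSE],
                       pre$cells0$fractions[rows, , drop = FALSE],
                       age = sheet$age[rows], sex = sex01[rows],
                       smoking = as.numeric(sheet$smoking[rows]),
                       depression = as.numeric(sheet$depression[rows]))
        rc <- response_continuous(pre$m0[rows, , drop = FALSE], pct, cov_c)
        report_design(paste0("response_continuous_", tpl), rc)
      }
      if ("longitudinal_delta" %in% config$designs) {
        tk <- if (tp == "T1") t1 else t2
        long_ids <- intersect(labelled, rownames(tk$betas))
        if (length(long_ids) >= 6L) {
          # technical adjustment is fit jointly over the arrays of both
          # timepoints (one pooled regression), so the within-patient
          # difference contrast is orthogonal to the per-probe intercept
          b0 <- t0$betas[long_ids, keep$kept_probe_ids, drop = FALSE]
          bk <- tk$betas[long_ids, keep$kept_probe_ids, drop = FALSE]
          nL <- length(long_ids)
          pool_b <- rbind(b0, bk)
          rownames(pool_b) <- c(paste0(long_ids, "_T0"), paste0(long_ids, "_", tp))
          pool_ctrl <- rbind(t0$control_betas[long_ids, , drop = FALSE],
                             tk$control_betas[long_ids, , drop = FALSE])
          rownames(pool_ctrl) <- rownames(pool_b)
          pool_ref <- rbind(t0$betas[long_ids, ref_ids, drop = FALSE],
                            tk$betas[long_ids, ref_ids, drop = FALSE])
          m_pool <- beta_to_m(pool_b)
          pcs_pool <- control_pcs(pool_ctrl, min(config$k_pcs, 2L * nL - 1L))
          cells_pool <- estimate_cell_fractions(pool_ref, reference)
          adj_pool <- residualize(m_pool, cbind(pcs_pool$scores, cells_pool$fractions))
          r0 <- adj_pool$residuals[seq_len(nL), , drop = FALSE]
          rk <- adj_pool$residuals[nL + seq_len(nL), , drop = FALSE]
          rownames(r0) <- rownames(rk) <- long_ids
          ld <- longitudinal_delta_test(r0, rk, labels[long_ids] == "responder",
                                        b0, bk)
          if (config$write_matrices)
            write_beta_matrix(adj_pool$residuals,
                              keep_file(file.path(out_dir, paste0("adjusted_", tpl, "_pooled.tsv"))))
          for (st in names(ld))
            if (!is.null(ld[[st]]))
              report_design(paste0("longitudinal_", tpl, "_", st), ld[[st]])
        }
      }
    }
    TRUE
  })

  # --- stage 6: summary ---------------------------------------------------
  summary <- .stage("report", {
    cfg_echo <- unclass(config)
    cfg_echo$effects <- lapply(unclass(config$effects), function(x)
      if (is.data.frame(x)) as.list(x) else x)
    cfg_echo$thresholds <- unclass(config$thresholds)
    cfg_echo$dropout <- as.list(config$dropout)
    s <- list(
      config = cfg_echo,
      n_samples_total = nrow(cohort$sheet),
      n_samples_excluded_qc = sum(qc$excluded),
      n_probes_evaluated = keep$n_evaluated,
      n_removed_snp = keep$n_removed_snp,
      n_removed_cross_reactive = keep$n_removed_cross,
      bonferroni_threshold = bonf,
      designs = summary_designs,
      files = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))))
    jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    s
  })
  invisible(summary)
}
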