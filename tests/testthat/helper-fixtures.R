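# Shared small fixtures, generated in code. Cached per test run so several
# test files can reuse the same cohort without regenerating it.

.fx <- new.env(parent = emptyenv())

small_manifest <- function() {
  if (is.null(.fx$man))
    .fx$man <- generate_manifest(800, 120, 100, frac_snp_close = 0.02,
                                 frac_cross_reactive = 0.05, seed = 11)
  .fx$man
}

small_reference <- function() {
  if (is.null(.fx$ref)) .fx$ref <- generate_reference(100, 1, seed = 12)
  .fx$ref
}

small_cohort <- function() {
  if (is.null(.fx$cohort))
    .fx$cohort <- generate_cohort(small_manifest(), small_reference(),
                                  n_patients = 60, n_controls = 60,
                                  qc_violations = list(low_call = 1,
                                                       missing_signal = 1,
                                                       sex_mismatch = 1,
                                                       control_outlier = 1),
                                  seed = 13)
  .fx$cohort
}

# baseline preprocessing of the QC-passed samples of small_cohort()
small_prep <- function() {
  if (is.null(.fx$prep)) {
    man <- small_manifest(); ref <- small_reference(); co <- small_cohort()
    qc <- sample_qc(co$t0, co$sheet, man)
    pass <- qc$sample_id[!qc$excluded]
    keep <- filter_probes(man)
    b0 <- co$t0$betas[pass, keep$kept_probe_ids, drop = FALSE]
    m0 <- beta_to_m(b0)
    pcs <- control_pcs(co$t0$control_betas[pass, , drop = FALSE], 10)
    ref_ids <- man$probe_id[man$is_cell_reference]
    cells <- estimate_cell_fractions(co$t0$betas[pass, ref_ids, drop = FALSE], ref)
    adj <- residualize(m0, cbind(pcs$scores, cells$fractions))
    sheet <- co$sheet[match(pass, co$sheet$sample_id), , drop = FALSE]
    .fx$prep <- list(qc = qc, pass = pass, keep = keep, b0 = b0, m0 = m0,
                     pcs = pcs, cells = cells, adj = adj, sheet = sheet)
  }
  .fx$prep
}
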