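# hand-built two-sample dataset for rule-level checks
tiny_dataset <- function(call_rates = c(1, 1), missing = c(0, 0), n_probes = 200) {
  n <- length(call_rates)
  betas <- matrix(runif(n * n_probes, 0.2, 0.8), n, n_probes,
                  dimnames = list(sprintf("S%02d", 1:n), sprintf("cg%03d", 1:n_probes)))
  mask <- matrix(TRUE, n, n_probes, dimnames = dimnames(betas))
  for (i in seq_len(n)) {
    n_miss <- round(missing[i] * n_probes)
    if (n_miss > 0) {
      j <- seq_len(n_miss)
      betas[i, j] <- NA
      mask[i, j] <- FALSE
    }
    n_fail <- round((1 - call_rates[i]) * (n_probes - n_miss))
    if (n_fail > 0) mask[i, n_miss + seq_len(n_fail)] <- FALSE
  }
  structure(list(betas = betas, detection_mask = mask, timepoint = "T0",
                 control_betas = matrix(0.5, n, 12,
                                        dimnames = list(rownames(betas),
                                                        sprintf("ctrl%02d", 1:12)))),
            class = "methylation_dataset")
}

tiny_sheet <- function(n) {
  data.frame(sample_id = sprintf("S%02d", 1:n), group = "control",
             age = 30, sex = "F", reported_sex = "F", smoking = NA,
             depression = FALSE, medication = FALSE, hama_t0 = NA,
             hama_t1 = NA, hama_t2 = NA, batch = 1,
             stringsAsFactors = FALSE)
}

tiny_manifest <- function(n_probes = 200) {
  data.frame(probe_id = c(sprintf("cg%03d", 1:n_probes), sprintf("ctrl%02d", 1:12)),
             chrom = c(rep("1", n_probes), rep(NA, 12)),
             pos = c(seq_len(n_probes), rep(NA, 12)),
             nearest_gene = NA, snp_dist_bp = NA, snp_maf = NA,
             cross_reactive = FALSE,
             is_control = c(rep(FALSE, n_probes), rep(TRUE, 12)),
             control_class = c(rep("none", n_probes),
                               rep(c("BS-I-C", "BS-II"), 6)),
             is_cell_reference = FALSE, stringsAsFactors = FALSE)
}

test_that("call-rate and missing-signal rules fire below/at their boundaries only", {
  set.seed(1)
  ds <- tiny_dataset(call_rates = c(0.94, 0.95, 1), missing = c(0, 0, 0.06))
  sheet <- tiny_sheet(3)
  qc <- sample_qc(ds, sheet, tiny_manifest(), qc_thresholds(sex_check = FALSE))
  expect_true(qc$excluded[1])
  expect_equal(qc$exclusion_reasons[1], "call_rate")
  expect_false(qc$excluded[2])          # boundary 0.95 retained
  expect_true(qc$excluded[3])
  expect_equal(qc$exclusion_reasons[3], "missing_signal")
  expect_equal(qc$missing_signal_frac[3], 0.06)
  empty <- structure(list(betas = matrix(numeric(0), 0, 5),
                          detection_mask = matrix(logical(0), 0, 5)),
                     class = "methylation_dataset")
  expect_error(sample_qc(empty, sheet, tiny_manifest()), "empty")
})

test_that("planted QC violators are recovered exactly, clean samples retained", {
  man <- small_manifest(); co <- small_cohort()
  qc <- sample_qc(co$t0, co$sheet, man)
  truth <- co$truth$qc_violations
  got <- qc[qc$excluded, ]
  expect_setequal(got$sample_id, truth$sample_id)   # recall and precision 1
  m <- merge(got[, c("sample_id", "exclusion_reasons")], truth)
  expect_equal(m$exclusion_reasons, m$reason)       # exactly the planted reason
})

test_that("sex is predicted from chrY detection and mismatches are flagged", {
  man <- small_manifest(); co <- small_cohort()
  pred <- predict_sex(co$t0, man)
  truth <- co$sheet$sex[match(pred$sample_id, co$sheet$sample_id)]
  expect_equal(pred$predicted_sex, truth)           # planted sex recovered
  swap <- co$truth$qc_violations$sample_id[co$truth$qc_violations$reason == "sex_mismatch"]
  i <- match(swap, pred$sample_id)
  expect_true(all(pred$predicted_sex[i] !=
                    co$sheet$reported_sex[match(swap, co$sheet$sample_id)]))
  # no sex-chromosome probes -> explicit uncallable status
  ds <- tiny_dataset(c(1, 1))
  pred2 <- predict_sex(ds, tiny_manifest())
  expect_true(all(is.na(pred2$predicted_sex)))
  expect_true(all(pred2$status == "uncallable"))
})

test_that("probe filtering applies SNP, cross-reactive and control rules", {
  man <- data.frame(
    probe_id = paste0("p", 1:6),
    chrom = c("1", "2", "3", "4", "5", NA), pos = c(1:5, NA),
    nearest_gene = NA,
    snp_dist_bp = c(5L, 6L, NA, 5L, 3L, NA),
    snp_maf = c(0.01, 0.50, NA, 0.005, 0.3, NA),
    cross_reactive = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    is_control = c(rep(FALSE, 5), TRUE),
    control_class = c(rep("none", 5), "BS-II"),
    is_cell_reference = FALSE, stringsAsFactors = FALSE)
  class(man) <- c("probe_manifest", "data.frame")
  keep <- filter_probes(man)
  # p1: SNP at 5 bp with MAF 0.01 -> removed; p2: distant SNP -> kept;
  # p3: cross-reactive -> removed; p4: close SNP but rare -> kept;
  # p5: both rules -> tallied under SNP; p6: control -> removed
  expect_setequal(keep$kept_probe_ids, c("p2", "p4"))
  expect_equal(keep$n_removed_snp, 2)      # p1 and p5 (SNP precedence)
  expect_equal(keep$n_removed_cross, 1)    # p3 only
  expect_equal(keep$n_removed_control, 1)
  expect_equal(keep$n_evaluated, 2)
  # idempotence: filtering an already-kept manifest removes nothing
  man2 <- man[man$probe_id %in% keep$kept_probe_ids, ]
  class(man2) <- c("probe_manifest", "data.frame")
  keep2 <- filter_probes(man2)
  expect_setequal(keep2$kept_probe_ids, keep$kept_probe_ids)
})

test_that("sex-chromosome probes are removed by default but can be retained", {
  man <- small_manifest()
  keep <- filter_probes(man)
  expect_false(any(man$chrom[match(keep$kept_probe_ids, man$probe_id)] %in% c("X", "Y")))
  keep2 <- filter_probes(man, drop_sex_chrom = FALSE)
  expect_gt(keep2$n_evaluated, keep$n_evaluated)
})

test_that("the Bonferroni threshold is exact division", {
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(20), 0.0025)
  # invariant: threshold * n recovers alpha to machine precision
  for (n in c(7L, 100L, 780145L))
    expect_equal(bonferroni_threshold(n) * n, 0.05, tolerance = 1e-15)
  expect_error(bonferroni_threshold(0), "positive")
  expect_error(bonferroni_threshold(10, alpha = 1), "alpha")
})

test_that("response labelling uses the >= 50% decrease rule with boundary included", {
  sheet <- data.frame(
    sample_id = paste0("P", 1:5),
    group = c(rep("patient", 4), "control"),
    hama_t0 = c(24, 24, 20, 0, NA), hama_t1 = c(12, 13, NA, 5, NA),
    hama_t2 = NA, stringsAsFactors = FALSE)
  expect_warning(lab <- label_response(sheet, "T0", "T1"), "zero baseline")
  expect_equal(unname(lab[1:4]),
               c("responder", "non-responder", "missing", "missing"))
  expect_false("P5" %in% names(lab))     # controls excluded
  # invariance under positive rescaling of all scores
  sheet2 <- sheet[1:2, ]
  sheet2$hama_t0 <- sheet2$hama_t0 * 3.7
  sheet2$hama_t1 <- sheet2$hama_t1 * 3.7
  expect_equal(unname(label_response(sheet2, "T0", "T1")),
               unname(lab[1:2]))
  expect_error(label_response(sheet, "T1", "T0"), "earlier")
})
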