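#' Generate a synthetic EPIC-like probe manifest
#'
#' Builds a probe annotation table mimicking a methylation array manifest:
#' genomic CpG probes with chromosome, 1-based position and a nearest-gene
#' label, plus non-genomic control probes (bisulfite-conversion, specificity
#' and staining classes) and a flagged set of cell-type reference CpGs used
#' for white-blood-cell deconvolution. Declared fractions of genomic probes
#' carry a SNP within 5 bp at minor allele frequency >= 0.01, or a
#' cross-reactive flag, so that probe filtering has known ground truth.
#'
#' @param n_probes number of genomic CpG probes.
#' @param n_control number of control probes (cycled over the six control
#'   classes).
#' @param n_reference number of genomic probes flagged as cell-type
#'   reference CpGs (must not exceed `n_probes`).
#' @param frac_snp_close fraction of genomic probes given a SNP at distance
#'   <= 5 bp with MAF >= 0.01 (i.e. removable by the SNP filter).
#' @param frac_cross_reactive fraction of genomic probes flagged
#'   cross-reactive.
#' @param frac_chrX,frac_chrY fractions of genomic probes placed on the X
#'   and Y chromosome (used by the sex predictor).
#' @param seed integer seed; output is deterministic given the seed.
#' @return a `data.frame` of class `probe_manifest` with columns
#'   `probe_id`, `chrom`, `pos`, `nearest_gene`, `snp_dist_bp`, `snp_maf`,
#'   `cross_reactive`, `is_control`, `control_class`, `is_cell_reference`.
#' @export
generate_manifest <- function(n_probes, n_control = 120L, n_reference = 100L,
                              frac_snp_close = 0.02, frac_cross_reactive = 0.05,
                              frac_chrX = 0.02, frac_chrY = 0.005, seed = 1L) {
  if (!is.numeric(n_probes) || n_probes < 1)
    stop("'n_probes' must be a positive integer", call. = FALSE)
  if (n_control < 0 || n_reference < 0)
    stop("probe counts must be non-negative", call. = FALSE)
  if (n_probes < n_reference)
    stop("'n_reference' cannot exceed 'n_probes'", call. = FALSE)
  .stopifnot_fraction(frac_snp_close, "frac_snp_close")
  .stopifnot_fraction(frac_cross_reactive, "frac_cross_reactive")
  set.seed(seed)

  n_probes <- as.integer(n_probes)
  ids <- sprintf("cg%08d", sample.int(99999999L, n_probes))
  n_x <- floor(frac_chrX * n_probes)
  n_y <- floor(frac_chrY * n_probes)
  chrom <- sample(as.character(1:22), n_probes, replace = TRUE,
                  prob = 23 - (1:22))  # larger chromosomes get more probes
  sex_idx <- sample.int(n_probes, n_x + n_y)
  chrom[sex_idx[seq_len(n_x)]] <- "X"
  if (n_y > 0) chrom[sex_idx[n_x + seq_len(n_y)]] <- "Y"
  pos <- sample.int(2.4e8, n_probes, replace = TRUE)
  gene_pool <- sprintf("GENE%05d", sample.int(90000L, max(10L, n_probes %/% 8L)))
  nearest_gene <- sample(gene_pool, n_probes, replace = TRUE)

  snp_dist_bp <- rep(NA_integer_, n_probes)
  snp_maf <- rep(NA_real_, n_probes)
  n_snp <- floor(frac_snp_close * n_probes)
  flaggable <- sample.int(n_probes, n_probes)  # random order without replacement
  snp_idx <- flaggable[seq_len(n_snp)]
  snp_dist_bp[snp_idx] <- sample(0:5, n_snp, replace = TRUE)
  snp_maf[snp_idx] <- stats::runif(n_snp, 0.01, 0.5)
  # some probes with a close SNP but MAF below 0.01, or a distant SNP:
  # these must survive the filter (both conditions are required)
  n_rare <- floor(0.01 * n_probes)
  if (n_rare > 0) {
    rare_idx <- flaggable[n_snp + seq_len(n_rare)]
    snp_dist_bp[rare_idx] <- sample(0:5, n_rare, replace = TRUE)
    snp_maf[rare_idx] <- stats::runif(n_rare, 0, 0.009)
  }
  n_far <- floor(0.05 * n_probes)
  if (n_far > 0) {
    far_idx <- flaggable[n_snp + n_rare + seq_len(min(n_far, n_probes - n_snp - n_rare))]
    snp_dist_bp[far_idx] <- sample(6:5000, length(far_idx), replace = TRUE)
    snp_maf[far_idx] <- stats::runif(length(far_idx), 0, 0.5)
  }

  cross_reactive <- rep(FALSE, n_probes)
  cross_reactive[sample.int(n_probes, floor(frac_cross_reactive * n_probes))] <- TRUE

  # reference CpGs: autosomal, preferring probes that survive filtering
  is_cell_reference <- rep(FALSE, n_probes)
  autosomal <- !(chrom %in% c("X", "Y"))
  clean <- autosomal & !cross_reactive &
    !(!is.na(snp_dist_bp) & snp_dist_bp <= 5 & !is.na(snp_maf) & snp_maf >= 0.01)
  pool <- if (sum(clean) >= n_reference) which(clean) else which(autosomal)
  if (length(pool) < n_reference)
    stop("not enough autosomal probes to host the cell-reference set", call. = FALSE)
  is_cell_reference[sample(pool, n_reference)] <- TRUE

  genomic <- data.frame(
    probe_id = ids, chrom = chrom, pos = pos, nearest_gene = nearest_gene,
    snp_dist_bp = snp_dist_bp, snp_maf = snp_maf,
    cross_reactive = cross_reactive, is_control = FALSE,
    control_class = "none", is_cell_reference = is_cell_reference,
    stringsAsFactors = FALSE)

  if (n_control > 0) {
    ctrl <- data.frame(
      probe_id = sprintf("ctrl%05d", seq_len(n_control)),
      chrom = NA_character_, pos = NA_integer_, nearest_gene = NA_character_,
      snp_dist_bp = NA_integer_, snp_maf = NA_real_,
      cross_reactive = FALSE, is_control = TRUE,
      control_class = rep_len(CONTROL_CLASSES, n_control),
      is_cell_reference = FALSE, stringsAsFactors = FALSE)
    genomic <- rbind(genomic, ctrl)
  }
  stopifnot(!anyDuplicated(genomic$probe_id))
  class(genomic) <- c("probe_manifest", "data.frame")
  genomic
}

#' Generate a synthetic cell-type methylation reference
#'
#' Produces a reference matrix of beta values at signature CpGs for the six
#' leukocyte types used in reference-based deconvolution (CD8 T cells,
#' CD4 T cells, natural killer cells, B cells, monocytes, granulocytes).
#' Columns are made mutually distinguishable by per-probe, per-cell-type
#' shifts on the logit scale whose magnitude is governed by `separation`.
#'
#' @param n_reference number of signature CpGs (>= 6).
#' @param separation positive scalar controlling how far apart the cell-type
#'   methylation profiles are on the logit scale (1 = default realism).
#' @param seed integer seed.
#' @return an object of class `cell_reference`: a list with `betas`
#'   (`n_reference` x 6 matrix in \[0,1\]), `cell_types`, and
#'   `condition_number` of the reference matrix.
#' @export
generate_reference <- function(n_reference = 100L, separation = 1, seed = 1L) {
  if (n_reference < 6) stop("'n_reference' must be at least 6", call. = FALSE)
  if (!is.numeric(separation) || separation <= 0)
    stop("'separation' must be positive", call. = FALSE)
  set.seed(seed)
  base <- stats::rnorm(n_reference, 0, 1.2)
  shift <- matrix(stats::rnorm(n_reference * 6L, 0, separation), ncol = 6L)
  betas <- .invlogit(base + shift)
  dimnames(betas) <- list(NULL, CELL_TYPES)
  structure(list(betas = betas, cell_types = CELL_TYPES,
                 condition_number = kappa(betas, exact = TRUE)),
            class = "cell_reference")
}

#' Specify spiked effects and noise structure for the cohort generator
#'
#' @param cc_spiked data.frame (`probe_id`, `delta_beta`): probes whose mean
#'   beta differs between patients and controls by `delta_beta`.
#' @param pred_spiked data.frame (`probe_id`, `slope`): probes whose baseline
#'   M-value shifts the log-odds of treatment response by `slope` per unit M
#'   (log2 scale).
#' @param long_spiked data.frame (`probe_id`, `drift`): probes whose beta
#'   drifts by `drift` per timepoint in responders only.
#' @param noise_sd per-probe logit-normal noise SD (natural-logit scale).
#' @param dirichlet_alpha positive 6-vector of Dirichlet concentrations for
#'   the leukocyte mixture (order CD8T, CD4T, NK, B, Mono, Gran); the default
#'   gives granulocyte-dominated whole-blood-like mixtures.
#' @param batch_sd SD of the per-batch additive shift on the logit scale,
#'   shared between control probes and a random subset of genomic probes.
#' @return a list of class `effect_spec`.
#' @export
effect_spec <- function(cc_spiked = NULL, pred_spiked = NULL, long_spiked = NULL,
                        noise_sd = 0.15,
                        dirichlet_alpha = c(2, 4, 1.25, 1, 2, 15),
                        batch_sd = 0.3) {
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("'noise_sd' must be positive", call. = FALSE)
  if (length(dirichlet_alpha) != 6L || any(dirichlet_alpha <= 0))
    stop("'dirichlet_alpha' must be a positive 6-vector", call. = FALSE)
  if (!is.numeric(batch_sd) || batch_sd < 0)
    stop("'batch_sd' must be non-negative", call. = FALSE)
  norm_spike <- function(x, value_col) {
    if (is.null(x)) return(NULL)
    x <- as.data.frame(x)
    names(x) <- c("probe_id", value_col)
    x
  }
  structure(list(cc_spiked = norm_spike(cc_spiked, "delta_beta"),
                 pred_spiked = norm_spike(pred_spiked, "slope"),
                 long_spiked = norm_spike(long_spiked, "drift"),
                 noise_sd = noise_sd, dirichlet_alpha = dirichlet_alpha,
                 batch_sd = batch_sd),
            class = "effect_spec")
}

# truncated-normal draw by vectorized rejection
.rtruncnorm_floor <- function(n, mean, sd, floor_at) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < floor_at)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < floor_at]
  }
  out
}

#' Generate a synthetic longitudinal anxiety-cohort methylation dataset
#'
#' Simulates a patient/control cohort measured on an EPIC-like array at
#' baseline (T0), post-treatment (T1) and follow-up (T2), with known ground
#' truth for every downstream analysis stage:
#' \itemize{
#'   \item beta values at cell-reference CpGs are Dirichlet-weighted mixtures
#'     of the reference cell-type profiles plus logit-normal noise;
#'   \item a per-batch shift on the logit scale is shared between control
#'     probes and a random 20% of genomic probes, so control-probe principal
#'     components can genuinely remove it;
#'   \item chrX probes are intermediate (~0.5) in females and near 0/1 in
#'     males; chrY probes are detected only in males;
#'   \item HAM-A anxiety scores start at a truncated normal (floor 19, the
#'     inclusion threshold) and improve by a two-component mixture so the
#'     realized responder fraction (>= 50% decrease) matches
#'     `responder_frac`;
#'   \item spiked effects follow [effect_spec()]: case-control mean-beta
#'     shifts, baseline-methylation log-odds slopes on response, and
#'     responder-only per-timepoint drift;
#'   \item a configurable set of samples is planted to violate QC rules
#'     (low call rate, missing signal, sex-label swap, control-probe
#'     outlier), recorded in the returned truth table.
#' }
#'
#' @param manifest a `probe_manifest` from [generate_manifest()].
#' @param reference a `cell_reference` from [generate_reference()]; its row
#'   count must equal the number of `is_cell_reference` probes.
#' @param n_patients,n_controls cohort sizes.
#' @param effects an [effect_spec()].
#' @param responder_frac target responder fraction at T1 (>= 50% HAM-A
#'   decrease); the T2 fraction defaults to `min(1, responder_frac + 0.15)`.
#' @param qc_violations list with integer counts `low_call`,
#'   `missing_signal`, `sex_mismatch`, `control_outlier` of planted QC
#'   violators (default none).
#' @param dropout named vector: fractions of patients lacking clinical
#'   follow-up (`t1_clinical`, `t2_clinical`) and, among those followed,
#'   lacking a methylation assay at that timepoint (`t1_meth`, `t2_meth`).
#'   Defaults mirror a longitudinal study with shrinking analysis panels.
#' @param n_batches number of processing batches; default one batch per
#'   chip of 8 arrays.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return a list of class `synthetic_cohort` with elements `sheet`
#'   (sample sheet), `t0`, `t1`, `t2` (methylation datasets; T1/T2 contain
#'   only assayed patients), and `truth` (responder labels, planted QC
#'   violators, mixture weights, batch structure).
#' @export
generate_cohort <- function(manifest, reference, n_patients, n_controls,
                            effects = effect_spec(), responder_frac = 0.5,
                            qc_violations = list(),
                            dropout = c(t1_clinical = 0.11, t2_clinical = 0.19,
                                        t1_meth = 0.21, t2_meth = 0.26),
                            n_batches = NULL, seed = 1L) {
  stopifnot(inherits(manifest, "probe_manifest"), inherits(reference, "cell_reference"))
  .stopifnot_fraction(responder_frac, "responder_frac")
  if (n_patients < 1) stop("'n_patients' must be positive", call. = FALSE)
  genomic <- manifest[!manifest$is_control, , drop = FALSE]
  ctrl_man <- manifest[manifest$is_control, , drop = FALSE]
  ref_ids <- genomic$probe_id[genomic$is_cell_reference]
  if (nrow(reference$betas) != length(ref_ids))
    stop("reference row count does not match the manifest's cell-reference probes",
         call. = FALSE)
  qv <- utils::modifyList(list(low_call = 0L, missing_signal = 0L,
                               sex_mismatch = 0L, control_outlier = 0L),
                          as.list(qc_violations))
  for (sp in c("cc_spiked", "pred_spiked", "long_spiked")) {
    s <- effects[[sp]]
    if (!is.null(s)) {
      miss <- setdiff(s$probe_id, genomic$probe_id)
      if (length(miss))
        stop(sprintf("%s probes not in manifest (or are control probes): %s",
                     sp, paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  set.seed(seed)

  n <- n_patients + n_controls
  # default batch granularity: one batch per chip of 8 arrays
  if (is.null(n_batches)) n_batches <- max(2L, ceiling(n / 8))
  G <- nrow(genomic)
  sample_id <- sprintf("S%04d", seq_len(n))
  group <- rep(c("patient", "control"), c(n_patients, n_controls))
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.44, 0.56))
  age <- round(pmin(pmax(stats::rnorm(n, 34, 11.5), 18), 70))
  smoking <- ifelse(group == "patient", stats::rbinom(n, 1, 0.26) == 1, NA)
  depression <- group == "patient" & stats::rbinom(n, 1, 0.32) == 1
  medication <- group == "patient" & stats::rbinom(n, 1, 0.2) == 1
  batch <- sample.int(n_batches, n, replace = TRUE)

  # --- HAM-A trajectories (patients only) ---------------------------------
  hama_t0 <- hama_t1 <- hama_t2 <- rep(NA_real_, n)
  pat <- which(group == "patient")
  base_score <- round(.rtruncnorm_floor(n_patients, 24.5, 5.3, 19))
  resp_frac_t2 <- min(1, responder_frac + 0.15)
  r1 <- stats::rbinom(n_patients, 1, responder_frac) == 1
  # correlate T2 response with T1 while matching the T2 marginal
  p_stay <- 0.9
  p_new <- if (responder_frac < 1)
    min(1, max(0, (resp_frac_t2 - p_stay * responder_frac) / (1 - responder_frac)))
  else resp_frac_t2
  r2 <- ifelse(r1, stats::rbinom(n_patients, 1, p_stay) == 1,
               stats::rbinom(n_patients, 1, p_new) == 1)
  improv1 <- ifelse(r1, stats::runif(n_patients, 0.52, 0.90),
                    stats::runif(n_patients, -0.15, 0.47))
  improv2 <- ifelse(r2, stats::runif(n_patients, 0.52, 0.95),
                    stats::runif(n_patients, -0.15, 0.47))
  hama_t0[pat] <- base_score
  hama_t1[pat] <- pmax(round(base_score * (1 - improv1)), 0)
  hama_t2[pat] <- pmax(round(base_score * (1 - improv2)), 0)
  # clinical dropout
  drop1 <- stats::runif(n_patients) < dropout[["t1_clinical"]]
  drop2 <- stats::runif(n_patients) < dropout[["t2_clinical"]]
  hama_t1[pat[drop1]] <- NA_real_
  hama_t2[pat[drop2]] <- NA_real_
  # realized responder labels from the emitted scores (>= 50% decrease)
  responder_t1 <- (hama_t0 - hama_t1) / hama_t0 >= 0.5
  responder_t2 <- (hama_t0 - hama_t2) / hama_t0 >= 0.5

  # --- planted QC violators ----------------------------------------------
  n_viol <- qv$low_call + qv$missing_signal + qv$sex_mismatch + qv$control_outlier
  if (n_viol > n) stop("more planted QC violators than samples", call. = FALSE)
  viol_idx <- if (n_viol > 0) sample.int(n, n_viol) else integer(0)
  take <- function(k) { out <- viol_idx[seq_len(k)]; viol_idx <<- viol_idx[-seq_len(k)]; out }
  idx_lowcall <- take(qv$low_call)
  idx_missig <- take(qv$missing_signal)
  idx_sexswap <- take(qv$sex_mismatch)
  idx_ctrlout <- take(qv$control_outlier)
  reported_sex <- sex
  reported_sex[idx_sexswap] <- ifelse(sex[idx_sexswap] == "M", "F", "M")

  sheet <- data.frame(
    sample_id = sample_id, group = group, age = age, sex = sex,
    reported_sex = reported_sex, smoking = smoking, depression = depression,
    medication = medication, hama_t0 = hama_t0, hama_t1 = hama_t1,
    hama_t2 = hama_t2, batch = batch, stringsAsFactors = FALSE)
  class(sheet) <- c("sample_sheet", "data.frame")

  # --- probe-level architecture ------------------------------------------
  is_ref <- genomic$is_cell_reference
  is_x <- genomic$chrom %in% "X"
  is_y <- genomic$chrom %in% "Y"
  plain <- !is_ref & !is_x & !is_y
  mu <- rep(NA_real_, G)
  comp <- sample.int(3L, G, replace = TRUE, prob = c(0.35, 0.30, 0.35))
  mu[comp == 1L] <- stats::rbeta(sum(comp == 1L), 1.5, 10)
  mu[comp == 2L] <- stats::rbeta(sum(comp == 2L), 5, 5)
  mu[comp == 3L] <- stats::rbeta(sum(comp == 3L), 10, 1.5)
  mu <- .clip01(mu, 0.02)
  mu_x_f <- .clip01(stats::rbeta(G, 30, 30), 0.02)    # females intermediate
  mu_x_m <- .clip01(ifelse(stats::runif(G) < 0.5,
                           stats::rbeta(G, 1.5, 20), stats::rbeta(G, 20, 1.5)), 0.02)
  mu_y <- .clip01(stats::rbeta(G, 5, 5), 0.02)

  # batch axis: per-batch shift, loadings on controls and 20% of genomic probes
  batch_shift <- stats::rnorm(n_batches, 0, effects$batch_sd)
  batch_load_g <- rep(0, G)
  batchable <- which(plain)
  bsub <- sample(batchable, floor(0.2 * length(batchable)))
  batch_load_g[bsub] <- stats::runif(length(bsub), 0.3, 1)
  n_ctrl <- nrow(ctrl_man)
  # probe-heterogeneous signed loadings: batch moves individual control
  # probes strongly but class means only weakly, as on real arrays, so the
  # control-PC adjustment sees the batch while the outlier QC rule is not
  # dominated by it
  batch_load_c <- stats::rnorm(n_ctrl, 0, 1)
  mu_ctrl <- .clip01(stats::rbeta(n_ctrl, 5, 5), 0.05)
  sample_shift <- batch_shift[batch]

  # cell mixture weights
  W <- .rdirichlet(n, effects$dirichlet_alpha)
  colnames(W) <- CELL_TYPES
  ref_mix <- .clip01(W %*% t(reference$betas))   # n x n_ref mixture means

  male <- sex == "M"
  eta_base <- matrix(.logit(mu), n, G, byrow = TRUE)
  eta_base[male, is_x] <- matrix(.logit(mu_x_m[is_x]), sum(male), sum(is_x), byrow = TRUE)
  eta_base[!male, is_x] <- matrix(.logit(mu_x_f[is_x]), sum(!male), sum(is_x), byrow = TRUE)
  eta_base[, is_y] <- matrix(.logit(mu_y[is_y]), n, sum(is_y), byrow = TRUE)
  eta_base[, is_ref] <- .logit(ref_mix)
  eta_batch <- outer(sample_shift, batch_load_g)

  # spiked-effect bookkeeping
  g_index <- stats::setNames(seq_len(G), genomic$probe_id)
  patient_rows <- group == "patient"
  if (!is.null(effects$cc_spiked)) {
    j <- g_index[effects$cc_spiked$probe_id]
    bad <- mu[j] + effects$cc_spiked$delta_beta
    if (any(bad <= 0 | bad >= 1))
      stop("cc_spiked delta_beta pushes mean beta outside (0, 1)", call. = FALSE)
  }
  if (!is.null(effects$long_spiked)) {
    j <- g_index[effects$long_spiked$probe_id]
    bad <- mu[j] + 2 * effects$long_spiked$drift
    if (any(bad <= 0 | bad >= 1))
      stop("long_spiked drift pushes mean beta outside (0, 1)", call. = FALSE)
  }

  r1_full <- rep(FALSE, n); r1_full[pat] <- r1
  r2_full <- rep(FALSE, n); r2_full[pat] <- r2
  sd_m2 <- effects$noise_sd / log(2)  # noise SD on the log2 (M-value) scale

  make_tp <- function(tp) {
    eta <- eta_base + eta_batch +
      matrix(stats::rnorm(n * G, 0, effects$noise_sd), n, G)
    betas <- .invlogit(eta)
    if (!is.null(effects$cc_spiked)) {
      j <- g_index[effects$cc_spiked$probe_id]
      betas[patient_rows, j] <- .clip01(
        sweep(betas[patient_rows, j, drop = FALSE], 2,
              effects$cc_spiked$delta_beta, `+`))
    }
    if (tp == "T0" && !is.null(effects$pred_spiked)) {
      # retrospective-Gaussian construction: m | responder ~ N(m0 + R*slope*s^2, s^2)
      # gives logistic slope exactly `slope` per unit M (log2 scale)
      for (k in seq_len(nrow(effects$pred_spiked))) {
        j <- g_index[effects$pred_spiked$probe_id[k]]
        slope <- effects$pred_spiked$slope[k]
        m0 <- log2(mu[j] / (1 - mu[j]))
        m_i <- m0 + r1_full[patient_rows] * slope * sd_m2^2 +
          stats::rnorm(sum(patient_rows), 0, sd_m2)
        betas[patient_rows, j] <- 2^m_i / (1 + 2^m_i)
      }
    }
    if (tp != "T0" && !is.null(effects$long_spiked)) {
      steps <- if (tp == "T1") 1 else 2
      resp <- if (tp == "T1") r1_full else r2_full
      j <- g_index[effects$long_spiked$probe_id]
      betas[resp, j] <- .clip01(
        sweep(betas[resp, j, drop = FALSE], 2,
              steps * effects$long_spiked$drift, `+`))
    }
    # two failure channels: absent signal (beta NA, always undetected) and
    # failed detection with a measurable beta (mask FALSE, beta present)
    mask <- matrix(stats::runif(n * G) > 0.002, n, G)
    na_sig <- matrix(stats::runif(n * G) < 0.001, n, G)
    # chrY undetected in females
    if (any(is_y)) {
      mask[!male, is_y] <- FALSE
      na_sig[!male, is_y] <- TRUE
    }
    if (tp == "T0") {
      for (s in idx_lowcall) {        # call rate 0.94 exactly: detection
        bad_j <- sample.int(G, round(0.06 * G))  # fails, signal present
        mask[s, ] <- TRUE
        mask[s, bad_j] <- FALSE
        na_sig[s, ] <- FALSE
        if (any(is_y) && sex[s] == "F") { mask[s, is_y] <- FALSE; na_sig[s, is_y] <- TRUE }
      }
      for (s in idx_missig) {         # 6% of probes lacking signal entirely
        na_sig[s, ] <- FALSE
        na_sig[s, sample.int(G, round(0.06 * G))] <- TRUE
        if (any(is_y) && sex[s] == "F") na_sig[s, is_y] <- TRUE
      }
    }
    mask[na_sig] <- FALSE             # no signal implies no detection
    betas[na_sig] <- NA_real_
    dimnames(betas) <- list(sample_id, genomic$probe_id)
    dimnames(mask) <- dimnames(betas)

    eta_c <- matrix(.logit(mu_ctrl), n, n_ctrl, byrow = TRUE) +
      outer(sample_shift, batch_load_c) +
      matrix(stats::rnorm(n * n_ctrl, 0, effects$noise_sd), n, n_ctrl)
    if (tp == "T0" && length(idx_ctrlout)) {
      out_class <- CONTROL_CLASSES[1 + (seq_along(idx_ctrlout) - 1) %% 6]
      for (k in seq_along(idx_ctrlout))
        eta_c[idx_ctrlout[k], ctrl_man$control_class == out_class[k]] <-
          eta_c[idx_ctrlout[k], ctrl_man$control_class == out_class[k]] + 6
    }
    control_betas <- .invlogit(eta_c)
    dimnames(control_betas) <- list(sample_id, ctrl_man$probe_id)
    structure(list(betas = betas, detection_mask = mask, timepoint = tp,
                   control_betas = control_betas),
              class = "methylation_dataset")
  }

  t0 <- make_tp("T0")
  t1 <- make_tp("T1")
  t2 <- make_tp("T2")

  # methylation dropout at follow-up: keep only assayed patients
  meth1 <- rep(FALSE, n)
  meth1[pat] <- !drop1 & stats::runif(n_patients) >= dropout[["t1_meth"]]
  meth2 <- rep(FALSE, n)
  meth2[pat] <- !drop2 & stats::runif(n_patients) >= dropout[["t2_meth"]]
  subset_ds <- function(ds, keep) {
    ds$betas <- ds$betas[keep, , drop = FALSE]
    ds$detection_mask <- ds$detection_mask[keep, , drop = FALSE]
    ds$control_betas <- ds$control_betas[keep, , drop = FALSE]
    ds
  }
  t1 <- subset_ds(t1, meth1)
  t2 <- subset_ds(t2, meth2)

  qc_truth <- data.frame(
    sample_id = sample_id[c(idx_lowcall, idx_missig, idx_sexswap, idx_ctrlout)],
    reason = rep(c("call_rate", "missing_signal", "sex_mismatch", "control_outlier"),
                 c(qv$low_call, qv$missing_signal, qv$sex_mismatch, qv$control_outlier)),
    stringsAsFactors = FALSE)

  structure(list(
    sheet = sheet, t0 = t0, t1 = t1, t2 = t2,
    truth = list(responder_t1 = stats::setNames(responder_t1, sample_id),
                 responder_t2 = stats::setNames(responder_t2, sample_id),
                 qc_violations = qc_truth,
                 cell_weights = W,
                 batch_shift = batch_shift,
                 batch_loading_genomic = stats::setNames(batch_load_g, genomic$probe_id),
                 probe_mean = stats::setNames(mu, genomic$probe_id))),
    class = "synthetic_cohort")
}
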