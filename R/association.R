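#' Case-control EWAS by Welch's unequal-variance t-test
#'
#' Per probe, compares adjusted methylation (residualized M-values) between
#' patients and controls with Welch's t-test, which tolerates unequal group
#' sizes and variances:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value. The effect column reports
#' the raw-beta group difference (patients minus controls), with
#' `effect_pct = 100 * delta_beta / control mean beta`.
#'
#' @param adjusted an `adjusted_matrix` (or plain residual matrix,
#'   samples x probes).
#' @param group logical vector (TRUE = patient) aligned with rows.
#' @param betas optional raw beta matrix (same shape) for the effect
#'   columns.
#' @return data.frame of class `ewas_result` with `probe_id`, `statistic`,
#'   `df`, `p_value`, `effect`, `effect_pct`, `n_used`, `flag`
#'   ("ok" or "degenerate" when both group variances are zero).
#' @export
welch_case_control <- function(adjusted, group, betas = NULL) {
  R <- if (inherits(adjusted, "adjusted_matrix")) adjusted$residuals else adjusted
  group <- as.logical(group)
  n1 <- sum(group); n2 <- sum(!group)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  x1 <- R[group, , drop = FALSE]; x2 <- R[!group, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- .colVars(x1); v2 <- .colVars(x2)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- (v1 + v2) == 0
  tstat[degenerate] <- NA_real_
  df[degenerate] <- NA_real_
  p[degenerate] <- NA_real_
  eff <- eff_pct <- rep(NA_real_, ncol(R))
  if (!is.null(betas)) {
    b1 <- colMeans(betas[group, , drop = FALSE], na.rm = TRUE)
    b2 <- colMeans(betas[!group, , drop = FALSE], na.rm = TRUE)
    eff <- b1 - b2
    eff_pct <- 100 * eff / b2
  }
  out <- data.frame(probe_id = colnames(R), statistic = tstat, df = df,
                    p_value = p, effect = eff, effect_pct = eff_pct,
                    n_used = n1 + n2,
                    flag = ifelse(degenerate, "degenerate", "ok"),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ewas_result", "data.frame")
  out
}

#' Post-hoc adjustment of case-control hits for comorbid depression
#'
#' For each probe in `probe_subset`, fits an ordinary linear model of the
#' adjusted methylation on group (patient vs control) and comorbid
#' depression as binary predictors, and classifies the group association
#' against the significant/suggestive thresholds ("remained_significant",
#' "suggestive", "dropped"). A depression indicator without variation is
#' dropped from the model; a depression indicator collinear with group is
#' an error.
#'
#' @param adjusted an `adjusted_matrix` or residual matrix.
#' @param group,depression logical vectors aligned with rows.
#' @param probe_subset probe ids to refit (typically the significant hits).
#' @param sig,suggestive classification thresholds.
#' @return data.frame with per-probe group coefficient, t, p and
#'   `classification`.
#' @export
posthoc_depression_adjust <- function(adjusted, group, depression, probe_subset,
                                      sig, suggestive = 1e-5) {
  R <- if (inherits(adjusted, "adjusted_matrix")) adjusted$residuals else adjusted
  if (!length(probe_subset)) stop("'probe_subset' is empty", call. = FALSE)
  missing_p <- setdiff(probe_subset, colnames(R))
  if (length(missing_p))
    stop(sprintf("unknown probes: %s", paste(missing_p, collapse = ", ")),
         call. = FALSE)
  g <- as.numeric(group); d <- as.numeric(depression)
  X <- if (stats::var(d) == 0) cbind(1, group = g)
       else cbind(1, group = g, depression = d)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("group and depression are collinear", call. = FALSE)
  Y <- R[, probe_subset, drop = FALSE]
  coefs <- qr.coef(qx, Y)
  rss <- colSums(qr.resid(qx, Y)^2)
  dfres <- nrow(X) - ncol(X)
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(rss / dfres * xtx_inv[2L, 2L])
  tstat <- coefs[2L, ] / se
  p <- 2 * stats::pt(-abs(tstat), dfres)
  cls <- ifelse(p <= sig, "remained_significant",
                ifelse(p < suggestive, "suggestive", "dropped"))
  data.frame(probe_id = probe_subset, coefficient = coefs[2L, ], se = se,
             statistic = tstat, df = dfres, p_value = p,
             classification = cls, stringsAsFactors = FALSE, row.names = NULL)
}

# shared guts of the per-probe logistic fit; separation is judged on the
# stability of the focal (second) coefficient, not on fitted probabilities
# hitting 0/1 through the covariates alone
.logistic_one <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  sep <- is.na(fit$coefficients[2L]) || abs(fit$coefficients[2L]) > 20
  flag <- if (!fit$converged) "nonconverged" else if (sep) "separation" else "ok"
  np <- length(fit$coefficients)
  se <- rep(NA_real_, np)
  rk <- fit$rank
  if (rk > 0) {
    piv <- fit$qr$pivot[seq_len(rk)]
    covp <- tryCatch(chol2inv(fit$qr$qr[seq_len(rk), seq_len(rk), drop = FALSE]),
                     error = function(e) NULL)
    if (!is.null(covp)) se[piv] <- sqrt(diag(covp))
  }
  list(coef = fit$coefficients, se = se, flag = flag)
}

#' Predict treatment response from baseline methylation (logistic EWAS)
#'
#' Per probe, fits a maximum-likelihood logistic regression of the binary
#' response label on the probe's baseline M-value plus covariates
#' (control-probe PCs, cell fractions, age, sex, smoking, depression and
#' baseline HAM-A score), combining technical adjustment and association
#' in one model. A positive coefficient means higher methylation predicts
#' increased response odds. Probes with perfect separation or
#' non-convergence are flagged and get no p-value.
#'
#' @param m M-value matrix (samples x probes), rows restricted to patients
#'   with a response label.
#' @param response logical/0-1 vector (TRUE = responder).
#' @param covariates numeric covariate matrix (samples x c).
#' @return data.frame of class `ewas_result` with `probe_id`,
#'   `coefficient`, `se`, `statistic` (Wald z), `p_value`, `n_used`,
#'   `flag`.
#' @export
predict_response_logistic <- function(m, response, covariates = NULL) {
  y <- as.numeric(response)
  n <- length(y)
  if (nrow(m) != n) stop("dimension mismatch", call. = FALSE)
  C <- if (is.null(covariates)) matrix(numeric(0), n, 0L) else as.matrix(covariates)
  if (ncol(C) && qr(cbind(1, C))$rank < ncol(C) + 1L)
    stop("covariate matrix is rank deficient", call. = FALSE)
  m <- .impute_probe_means(m)
  G <- ncol(m)
  coefv <- sev <- rep(NA_real_, G)
  flags <- character(G)
  for (j in seq_len(G)) {
    X <- cbind(1, meth = m[, j], C)
    f <- .logistic_one(X, y)
    coefv[j] <- f$coef[2L]
    sev[j] <- f$se[2L]
    flags[j] <- f$flag
  }
  flags[flags == "ok" & (is.na(sev) | sev > 100)] <- "separation"
  z <- coefv / sev
  p <- 2 * stats::pnorm(-abs(z))
  bad <- flags != "ok"
  p[bad] <- NA_real_
  out <- data.frame(probe_id = colnames(m), coefficient = coefv, se = sev,
                    statistic = z, p_value = p, n_used = n, flag = flags,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ewas_result", "data.frame")
  out
}

#' Continuous treatment-response EWAS (percent HAM-A change)
#'
#' Per probe, ordinary least squares of the percentage HAM-A improvement
#' on the probe's baseline M-value plus covariates (same covariates as the
#' logistic design minus the baseline HAM-A score). Implemented by the
#' Frisch-Waugh-Lovell decomposition (outcome and methylation residualized
#' on the covariates), which reproduces the joint-model slope and t
#' exactly.
#'
#' @param m M-value matrix (samples x probes).
#' @param pct_change numeric outcome `100 * (hama_from - hama_to) / hama_from`.
#' @param covariates numeric covariate matrix or NULL.
#' @return data.frame of class `ewas_result` with slope, se, t, df, p.
#' @export
response_continuous <- function(m, pct_change, covariates = NULL) {
  n <- length(pct_change)
  if (nrow(m) != n) stop("dimension mismatch", call. = FALSE)
  C <- if (is.null(covariates)) matrix(numeric(0), n, 0L) else as.matrix(covariates)
  pfit <- ncol(C) + 2L  # intercept + methylation + covariates
  if (n <= pfit) stop("fewer samples than model parameters", call. = FALSE)
  m <- .impute_probe_means(m)
  if (stats::var(pct_change) == 0) {
    out <- data.frame(probe_id = colnames(m), coefficient = 0, se = NA_real_,
                      statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                      n_used = n, flag = "zero_variance_outcome",
                      stringsAsFactors = FALSE, row.names = NULL)
    class(out) <- c("ewas_result", "data.frame")
    return(out)
  }
  qx <- qr(cbind(1, C))
  yr <- qr.resid(qx, pct_change)
  Mr <- qr.resid(qx, m)
  sxx <- colSums(Mr^2)
  slope <- colSums(Mr * yr) / sxx
  dfres <- n - pfit
  rss <- sum(yr^2) - slope^2 * sxx
  se <- sqrt(rss / dfres / sxx)
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), dfres)
  degenerate <- sxx < 1e-12
  p[degenerate] <- NA_real_
  out <- data.frame(probe_id = colnames(m), coefficient = slope, se = se,
                    statistic = tstat, df = dfres, p_value = p, n_used = n,
                    flag = ifelse(degenerate, "degenerate", "ok"),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ewas_result", "data.frame")
  out
}

#' Within-patient longitudinal methylation change, stratified by response
#'
#' Computes per-patient differences of adjusted methylation between two
#' timepoints and tests them against zero with a one-sample t-test
#' (`t = dbar / (s_d / sqrt(n))`, df = n - 1), separately in responders
#' and non-responders. The effect column reports the mean raw-beta
#' difference when beta matrices are supplied. Strata with fewer than 3
#' patients are skipped with a message.
#'
#' @param adjusted_t0,adjusted_tk `adjusted_matrix` objects (or residual
#'   matrices) over the same samples and probes.
#' @param responder_mask logical vector (TRUE = responder) aligned with rows.
#' @param betas_t0,betas_tk optional raw beta matrices for the effect column.
#' @return named list (`responder`, `non_responder`) of `ewas_result`
#'   data.frames (NULL for skipped strata).
#' @export
longitudinal_delta_test <- function(adjusted_t0, adjusted_tk, responder_mask,
                                    betas_t0 = NULL, betas_tk = NULL) {
  R0 <- if (inherits(adjusted_t0, "adjusted_matrix")) adjusted_t0$residuals else adjusted_t0
  Rk <- if (inherits(adjusted_tk, "adjusted_matrix")) adjusted_tk$residuals else adjusted_tk
  if (!identical(dim(R0), dim(Rk)) || !identical(colnames(R0), colnames(Rk)))
    stop("timepoint matrices must share samples and probe order", call. = FALSE)
  D <- Rk - R0
  dB <- if (!is.null(betas_t0)) betas_tk - betas_t0 else NULL
  one_stratum <- function(idx, label) {
    ns <- sum(idx)
    if (ns < 3L) {
      message(sprintf("stratum '%s' skipped: only %d patient(s)", label, ns))
      return(NULL)
    }
    d <- D[idx, , drop = FALSE]
    dbar <- colMeans(d)
    sdd <- sqrt(.colVars(d))
    tstat <- dbar / (sdd / sqrt(ns))
    p <- 2 * stats::pt(-abs(tstat), ns - 1L)
    degenerate <- sdd == 0
    tstat[degenerate] <- NA_real_
    p[degenerate] <- NA_real_
    eff <- if (!is.null(dB)) colMeans(dB[idx, , drop = FALSE], na.rm = TRUE)
           else rep(NA_real_, ncol(D))
    out <- data.frame(probe_id = colnames(D), statistic = tstat, df = ns - 1L,
                      p_value = p, effect = eff, n_used = ns,
                      flag = ifelse(degenerate, "degenerate", "ok"),
                      stringsAsFactors = FALSE, row.names = NULL)
    class(out) <- c("ewas_result", "data.frame")
    out
  }
  list(responder = one_stratum(as.logical(responder_mask), "responder"),
       non_responder = one_stratum(!as.logical(responder_mask), "non_responder"))
}

#' Smoking EWAS by robust (Huber) linear regression
#'
#' Per probe, M-estimation of the beta value on smoking status plus
#' covariates (sex, age, cell fractions, control-probe PCs) with Huber's
#' loss (k = 1.345, 95% Gaussian efficiency) via [MASS::rlm()]. Standard
#' errors use the conventional asymptotic M-estimation covariance with
#' Huber's finite-sample correction, as computed by [MASS::summary.rlm()];
#' the z statistic is referred to a t distribution with n - p df.
#'
#' @param betas beta matrix (samples x probes), rows restricted to samples
#'   with known smoking status.
#' @param smoking logical vector (TRUE = smoker).
#' @param covariates numeric covariate matrix or NULL.
#' @param k Huber tuning constant.
#' @return data.frame of class `ewas_result` with `coefficient`, `se`,
#'   `statistic` (z), `p_value`, `n_used`, `flag`.
#' @export
smoking_ewas_robust <- function(betas, smoking, covariates = NULL, k = 1.345,
                                maxit = 100L) {
  s <- as.numeric(smoking)
  if (anyNA(s)) stop("smoking status must be known for all samples", call. = FALSE)
  if (stats::var(s) == 0) stop("smoking vector has no contrast", call. = FALSE)
  n <- length(s)
  C <- if (is.null(covariates)) matrix(numeric(0), n, 0L) else as.matrix(covariates)
  X <- cbind(`(Intercept)` = 1, smoking = s, C)
  pfit <- ncol(X)
  G <- ncol(betas)
  coefv <- sev <- rep(NA_real_, G)
  flags <- character(G)
  for (j in seq_len(G)) {
    y <- betas[, j]
    ok <- !is.na(y)
    fit <- tryCatch(
      MASS::rlm(X[ok, , drop = FALSE], y[ok], psi = MASS::psi.huber, k = k,
                maxit = maxit),
      error = function(e) NULL)
    if (is.null(fit)) { flags[j] <- "fit_error"; next }
    flags[j] <- if (isTRUE(fit$converged)) "ok" else "nonconverged"
    sm <- tryCatch(summary(fit, method = "XtX")$coefficients,
                   error = function(e) NULL)
    if (is.null(sm)) { flags[j] <- "singular"; next }
    coefv[j] <- sm[2L, 1L]
    sev[j] <- sm[2L, 2L]
  }
  z <- coefv / sev
  p <- 2 * stats::pt(-abs(z), n - pfit)
  p[flags != "ok"] <- NA_real_
  out <- data.frame(probe_id = colnames(betas), coefficient = coefv, se = sev,
                    statistic = z, p_value = p, n_used = n, flag = flags,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ewas_result", "data.frame")
  out
}

#' Hypergeometric overlap test between two hit sets
#'
#' Counts the intersection of two probe sets and computes the upper-tail
#' hypergeometric probability of observing at least that overlap given the
#' set sizes and the evaluated-probe universe (computed stably in log
#' space by [stats::phyper()]).
#'
#' @param hits_a,hits_b character vectors of probe ids.
#' @param universe_n number of evaluated probes.
#' @return list with `overlap`, `p_value`, `expected` overlap.
#' @export
overlap_test <- function(hits_a, hits_b, universe_n) {
  hits_a <- unique(hits_a); hits_b <- unique(hits_b)
  if (length(hits_a) > universe_n || length(hits_b) > universe_n)
    stop("universe smaller than a hit set", call. = FALSE)
  count <- length(intersect(hits_a, hits_b))
  p <- stats::phyper(count - 1L, length(hits_a), universe_n - length(hits_a),
                     length(hits_b), lower.tail = FALSE)
  list(overlap = count, p_value = p,
       expected = length(hits_a) * length(hits_b) / universe_n)
}
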