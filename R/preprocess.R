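#' Transform beta values to M-values
#'
#' Computes the log2 logit transform
#' `M = log2(beta / (1 - beta))` after clipping beta into
#' `[offset, 1 - offset]` so the result is finite everywhere. Missing
#' entries stay missing.
#'
#' @param betas matrix of beta values in \[0, 1\] (samples x probes).
#' @param offset clipping offset in (0, 0.5).
#' @return M-value matrix with attribute `offset_used`.
#' @export
beta_to_m <- function(betas, offset = 0.001) {
  if (!is.numeric(offset) || offset <= 0 || offset >= 0.5)
    stop("'offset' must be in (0, 0.5)", call. = FALSE)
  rng <- range(betas, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values must lie in [0, 1]", call. = FALSE)
  b <- pmin(pmax(betas, offset), 1 - offset)
  m <- log2(b / (1 - b))
  attr(m, "offset_used") <- offset
  m
}

#' Back-transform M-values to beta values
#'
#' @param m M-value matrix (log2 logit scale).
#' @return beta matrix `2^m / (2^m + 1)`.
#' @export
m_to_beta <- function(m) 2^m / (2^m + 1)

# mean-impute missing entries per probe (column); used before PCA and
# residualization, where complete matrices are required
.impute_probe_means <- function(x) {
  nas <- which(is.na(x), arr.ind = TRUE)
  if (nrow(nas)) {
    mu <- colMeans(x, na.rm = TRUE)
    mu[is.nan(mu)] <- stats::median(x, na.rm = TRUE)
    x[nas] <- mu[nas[, 2L]]
  }
  x
}

#' Principal components of the control probes
#'
#' Column-centered (not variance-scaled) PCA of the control-probe matrix;
#' the scores of the first `k` components summarize technical variation
#' (batch, staining, bisulfite conversion) for use as adjustment
#' covariates. Sign convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param control_betas matrix (samples x control probes); missing entries
#'   are mean-imputed per probe.
#' @param k number of components (default 10).
#' @return list of class `control_pcs` with `scores` (samples x k,
#'   columns PC1..PCk), `explained_variance` (proportion per component)
#'   and `rotation`.
#' @export
control_pcs <- function(control_betas, k = 10L) {
  n <- nrow(control_betas)
  if (k > min(n - 1L, ncol(control_betas)))
    stop(sprintf("k = %d exceeds min(samples - 1, control probes) = %d",
                 k, min(n - 1L, ncol(control_betas))), call. = FALSE)
  x <- .impute_probe_means(control_betas)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation[, seq_len(k), drop = FALSE], 2L,
                function(v) sign(v[which.max(abs(v))]))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  rotation <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  colnames(scores) <- paste0("PC", seq_len(k))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, explained_variance = ev[seq_len(k)],
                 rotation = rotation),
            class = "control_pcs")
}

#' Estimate white-blood-cell composition by constrained projection
#'
#' Reference-based deconvolution at signature CpGs: for each sample,
#' solves the quadratic program
#' `min || y - R w ||^2  subject to  w >= 0, sum(w) <= 1`
#' exactly (via [quadprog::solve.QP()]), where `y` is the sample's beta
#' vector at the reference CpGs and `R` the 6-column cell-type reference.
#' The inequality sum constraint allows an unexplained remainder.
#'
#' @param betas_ref matrix (samples x reference probes) of beta values at
#'   the reference CpGs, columns in the reference's probe order.
#' @param reference a `cell_reference`.
#' @return list of class `cell_composition` with `fractions`
#'   (samples x 6, columns CD8T, CD4T, NK, B, Mono, Gran) and
#'   `residual_norm` per sample.
#' @export
estimate_cell_fractions <- function(betas_ref, reference) {
  R <- reference$betas
  if (ncol(R) != 6L) stop("reference must have exactly 6 cell types", call. = FALSE)
  if (ncol(betas_ref) != nrow(R))
    stop("betas_ref columns must match reference probes", call. = FALSE)
  kap <- kappa(R, exact = TRUE)
  if (kap > 1e8)
    stop(sprintf("reference matrix is rank-deficient (condition number %.3g)", kap),
         call. = FALSE)
  n <- nrow(betas_ref)
  frac <- matrix(NA_real_, n, 6L, dimnames = list(rownames(betas_ref), CELL_TYPES))
  rnorms <- rep(NA_real_, n)
  Amat <- cbind(rep(-1, 6L), diag(6L))   # -sum(w) >= -1 ; w >= 0
  bvec <- c(-1, rep(0, 6L))
  for (i in seq_len(n)) {
    y <- betas_ref[i, ]
    ok <- !is.na(y)
    Ri <- R[ok, , drop = FALSE]
    Dmat <- crossprod(Ri)
    sol <- quadprog::solve.QP(Dmat, crossprod(Ri, y[ok]), Amat, bvec, meq = 0L)
    w <- pmax(sol$solution, 0)
    frac[i, ] <- w
    rnorms[i] <- sqrt(sum((y[ok] - Ri %*% w)^2))
  }
  structure(list(fractions = frac, residual_norm = rnorms,
                 condition_number = kap),
            class = "cell_composition")
}

#' Residualize M-values on technical and cell-composition covariates
#'
#' First step of the two-step association analysis: per probe, ordinary
#' least squares of the M-values on an intercept plus the covariate
#' columns (control-probe PCs and estimated cell fractions); the residuals
#' form the adjusted methylation matrix used by downstream tests.
#'
#' @param m M-value matrix (samples x probes); missing entries are
#'   mean-imputed per probe before fitting.
#' @param covariates numeric matrix (samples x c), full column rank after
#'   adding an intercept.
#' @return list of class `adjusted_matrix` with `residuals` (same shape as
#'   `m`, per-probe mean ~ 0) and `covariates_used`.
#' @export
residualize <- function(m, covariates) {
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != nrow(m))
    stop("covariates and M-matrix disagree on sample count", call. = FALSE)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("V", seq_len(ncol(covariates)))
  X <- cbind(`(Intercept)` = 1, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop(sprintf("collinear covariates: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  res <- qr.resid(qx, .impute_probe_means(m))
  dimnames(res) <- dimnames(m)
  structure(list(residuals = res, covariates_used = colnames(covariates)),
            class = "adjusted_matrix")
}
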