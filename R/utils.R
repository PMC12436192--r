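# Internal numeric helpers shared across modules.

CELL_TYPES <- c("CD8T", "CD4T", "NK", "B", "Mono", "Gran")

CONTROL_CLASSES <- c("BS-I-C", "BS-II", "Specificity-I", "Specificity-II",
                     "Staining-Red", "Staining-Green")

# natural-logit helpers used by the generator (analysis uses log2 M-values)
.logit <- function(p) stats::qlogis(p)
.invlogit <- function(x) stats::plogis(x)

.clip01 <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

#' @noRd
.colVars <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(NA_real_, ncol(x)))
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

.stopifnot_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single fraction in [0, 1]", name), call. = FALSE)
  invisible(x)
}

# draw from a Dirichlet distribution (rows sum to 1)
.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}
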