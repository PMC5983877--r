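# LD estimation from a reference panel, shrinkage and imputation quality.

#' Pearson correlation matrix of panel dosage columns
#'
#' Missing genotypes are mean-imputed per variant before the correlation is
#' computed, so the result is always a valid correlation matrix over the full
#' panel. Zero-variance columns cannot be used for tagging and raise an error
#' unless `on_zero_var = "flag"`, in which case their indices are returned in
#' the `"excluded"` attribute and they are dropped from the matrix.
#'
#' @param panel a [ref_panel] object.
#' @param variant_indices integer column indices (default: all variants).
#' @param on_zero_var `"error"` or `"flag"`.
#' @return correlation matrix with unit diagonal; attribute `"excluded"` holds
#'   the indices of any dropped zero-variance variants.
#' @export
panel_correlation <- function(panel, variant_indices = NULL,
                              on_zero_var = c("error", "flag")) {
  on_zero_var <- match.arg(on_zero_var)
  G <- panel_dosage_imputed(panel, variant_indices)
  v <- apply(G, 2, stats::var)
  bad <- which(v <= 0 | !is.finite(v))
  if (length(bad)) {
    if (on_zero_var == "error")
      stop("zero-variance variant column(s): ", paste(bad, collapse = ", "))
    G <- G[, -bad, drop = FALSE]
  }
  C <- stats::cor(G)
  diag(C) <- 1
  attr(C, "excluded") <- bad
  C
}

# Dosage sub-matrix with per-variant mean imputation of missing entries.
panel_dosage_imputed <- function(panel, variant_indices = NULL) {
  G <- panel$dosage
  if (!is.null(variant_indices)) G <- G[, variant_indices, drop = FALSE]
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  G
}

#' Correlation of target variants with tag variants
#'
#' @param panel a [ref_panel].
#' @param target_indices,tag_indices integer column indices.
#' @return matrix (tags x targets) of Pearson correlations.
#' @export
panel_cross_correlation <- function(panel, tag_indices, target_indices) {
  Gt <- scale(panel_dosage_imputed(panel, tag_indices))
  Gu <- scale(panel_dosage_imputed(panel, target_indices))
  n <- nrow(Gt)
  crossprod(Gt, Gu) / (n - 1)
}

#' Choose the LD shrinkage intensity
#'
#' Two standard rules plus a user value: `fixed` gives lambda = 0.1; `sqrt_n`
#' scales with the reference panel size as 2/sqrt(n) (capped at 1); `value`
#' passes a user-supplied lambda through after range checking.
#'
#' @param mode one of `"fixed"`, `"sqrt_n"`, `"value"`.
#' @param n_panel reference panel size (individuals).
#' @param value user lambda in \[0, 1\] when `mode = "value"`.
#' @return lambda in \[0, 1\].
#' @export
choose_lambda <- function(mode = c("fixed", "sqrt_n", "value"),
                          n_panel = NULL, value = NULL) {
  mode <- match.arg(mode)
  switch(mode,
    fixed = 0.1,
    sqrt_n = {
      stopifnot(is.numeric(n_panel), n_panel >= 1)
      min(1, 2 / sqrt(n_panel))
    },
    value = {
      if (!is.numeric(value) || length(value) != 1 || value < 0 || value > 1)
        stop("lambda value must be a single number in [0, 1]")
      value
    }
  )
}

#' Shrink an LD system towards independence
#'
#' C_lambda = (1 - lambda) C + lambda I for the tag-tag matrix, and
#' c_lambda = (1 - lambda) c for target-tag correlations: the off-diagonal LD
#' is pulled towards zero so that the matrix is invertible and noisy
#' near-zero correlations are damped.
#'
#' @param C tag-tag correlation matrix.
#' @param c_vec target-tag correlation vector or matrix (tags x targets); may
#'   be `NULL`.
#' @param lambda shrinkage intensity in \[0, 1\].
#' @return list with `C_lambda` and `c_lambda`.
#' @export
shrink_ld <- function(C, c_vec = NULL, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  C <- as.matrix(C)
  Cl <- (1 - lambda) * C
  diag(Cl) <- (1 - lambda) * diag(C) + lambda
  list(C_lambda = Cl,
       c_lambda = if (is.null(c_vec)) NULL else (1 - lambda) * c_vec)
}

#' Predicted imputation quality
#'
#' The quadratic form c' C^-1 c of the shrunk system: the variance of the
#' target genotype explained by a linear combination of the tags, i.e. the
#' expected squared correlation between imputed and true statistic. Sampling
#' noise at small lambda can push the raw value slightly above 1; the returned
#' value is clamped to \[0, 1\] and the raw value kept in the `"raw"`
#' attribute.
#'
#' @param c_lambda shrunk target-tag correlation vector.
#' @param C_lambda shrunk tag-tag matrix (positive definite).
#' @return scalar quality in \[0, 1\] with attribute `"raw"`.
#' @export
impute_quality <- function(c_lambda, C_lambda) {
  raw <- as.numeric(crossprod(c_lambda, solve_spd(C_lambda, c_lambda)))
  out <- min(max(raw, 0), 1)
  attr(out, "raw") <- raw
  out
}

#' Effective number of variants in a correlation matrix
#'
#' The minimum number of leading eigenvalues whose cumulative sum reaches a
#' fraction `threshold` of the trace. Equals q for the identity and 1 for a
#' perfectly correlated block; used to discount correlated tags when adjusting
#' the imputation quality for panel size.
#'
#' @param C symmetric positive semi-definite correlation matrix.
#' @param threshold fraction of total variance to capture (default 0.995).
#' @return integer in \[1, q\].
#' @export
effective_num_variants <- function(C, threshold = 0.995) {
  ev <- eigen(as.matrix(C), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  tot <- sum(ev)
  if (tot <= 0) return(1L)
  as.integer(which(cumsum(ev) >= threshold * tot)[1])
}

#' Panel-size-adjusted imputation quality
#'
#' Adjusts the raw predicted quality for the ratio of the effective number of
#' tag variants to the reference panel size, analogous to an adjusted R^2:
#' 1 - (1 - r2) (n - 1) / (n - q_eff - 1). Negative values are set to zero
#' and the result is capped at 1. If the panel is too small
#' (n <= q_eff + 1) the quality is not estimable and 0 is returned with a
#' warning.
#'
#' @param r2_pred raw predicted quality.
#' @param n_panel reference panel size.
#' @param q_eff effective number of tag variants.
#' @return adjusted quality in \[0, 1\].
#' @export
adjust_quality <- function(r2_pred, n_panel, q_eff) {
  if (n_panel <= q_eff + 1) {
    warning("panel too small relative to effective number of tags; ",
            "quality not estimable, returning 0")
    return(0)
  }
  adj <- 1 - (1 - r2_pred) * (n_panel - 1) / (n_panel - q_eff - 1)
  min(max(adj, 0), 1)
}
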