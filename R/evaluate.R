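# Metrics comparing imputed to ground-truth summary statistics, and
# power / false-positive-rate curves.

#' RMSE and bias of imputed versus true Z-statistics
#'
#' With d_k = z_imp_k - z_true_k: RMSE = sqrt(mean(d^2)), bias = mean(d).
#'
#' @param z_imp,z_true equal-length numeric vectors.
#' @return named numeric vector `c(rmse, bias)`.
#' @export
rmse_bias <- function(z_imp, z_true) {
  stopifnot(length(z_imp) == length(z_true), length(z_imp) >= 1)
  d <- z_imp - z_true
  c(rmse = sqrt(mean(d^2)), bias = mean(d))
}

#' Through-origin regression slope and Pearson correlation
#'
#' Slope of the no-intercept regression of imputed on true statistics,
#' sum(xy)/sum(x^2), plus the Pearson correlation.
#'
#' @param z_imp,z_true equal-length numeric vectors.
#' @return named numeric vector `c(slope, r)`.
#' @export
slope_correlation <- function(z_imp, z_true) {
  stopifnot(length(z_imp) == length(z_true))
  c(slope = sum(z_true * z_imp) / sum(z_true^2),
    r = stats::cor(z_imp, z_true))
}

#' Power and false-positive-rate curve over a significance grid
#'
#' Power is the fraction of associated-variant P-values below each alpha,
#' FPR the same fraction among null variants; standard deviations assume the
#' hit counts are binomial: sd = sqrt(q (1 - q) / m).
#'
#' @param p_assoc P-values of truly associated variants (may be empty).
#' @param p_null P-values of null variants (may be empty).
#' @param alpha significance grid.
#' @return data.frame with `alpha`, `power`, `power_sd`, `fpr`, `fpr_sd`,
#'   `m_assoc`, `m_null`.
#' @export
power_fpr <- function(p_assoc, p_null, alpha = c(0.001, 0.01, 0.05)) {
  frac <- function(p, a) if (length(p)) mean(p < a) else NA_real_
  bsd <- function(q, m) if (is.na(q)) NA_real_ else sqrt(q * (1 - q) / m)
  pow <- vapply(alpha, frac, numeric(1), p = p_assoc)
  fpr <- vapply(alpha, frac, numeric(1), p = p_null)
  data.frame(alpha = alpha, power = pow,
             power_sd = vapply(pow, bsd, numeric(1), m = length(p_assoc)),
             fpr = fpr,
             fpr_sd = vapply(fpr, bsd, numeric(1), m = length(p_null)),
             m_assoc = length(p_assoc), m_null = length(p_null))
}

#' Stratify imputation results by MAF, quality and association status
#'
#' Assigns each evaluated variant to one MAF bin x quality bin (x association
#' status) cell and computes RMSE, bias, through-origin slope, Pearson
#' correlation and count per cell. Bin edges follow the convention that the
#' lower bound is excluded and the upper bound included. Association status
#' is derived from `ld_max` (largest squared correlation with any variant in
#' an associated-variant list): `associated` above `ld_assoc`, `null` below
#' `ld_null`, otherwise `intermediate`.
#'
#' @param results data.frame with columns `z_imp`, `z_true`, `maf`,
#'   `r2_pred_adj` and optionally `ld_max`.
#' @param maf_bins upper edges of the MAF bins (default `c(0.01, 0.05, 0.5)`).
#' @param quality_bins upper edges of the quality bins (default
#'   `c(0.3, 0.7, 1)`).
#' @param ld_assoc,ld_null thresholds on `ld_max` for the associated / null
#'   labels (defaults 0.3 and 0.05).
#' @return data.frame with one row per non-empty stratum.
#' @export
stratify_results <- function(results, maf_bins = c(0.01, 0.05, 0.5),
                             quality_bins = c(0.3, 0.7, 1),
                             ld_assoc = 0.3, ld_null = 0.05) {
  stopifnot(all(c("z_imp", "z_true", "maf", "r2_pred_adj") %in% names(results)))
  # (lo, hi] bins, lower bound excluded
  maf_bin <- cut(results$maf, breaks = c(0, maf_bins), right = TRUE,
                 labels = paste0("(", c(0, utils::head(maf_bins, -1)) * 100,
                                 ",", maf_bins * 100, "]%"))
  q_bin <- cut(results$r2_pred_adj, breaks = c(-Inf, quality_bins),
               right = TRUE,
               labels = paste0("(", c(0, utils::head(quality_bins, -1)),
                               ",", quality_bins, "]"))
  status <- if (is.null(results$ld_max)) factor(rep("all", nrow(results)))
    else factor(ifelse(results$ld_max > ld_assoc, "associated",
                ifelse(results$ld_max < ld_null, "null", "intermediate")))
  out <- list()
  for (lev in split(seq_len(nrow(results)),
                    interaction(status, maf_bin, q_bin, drop = TRUE))) {
    sub <- results[lev, , drop = FALSE]
    rb <- rmse_bias(sub$z_imp, sub$z_true)
    sc <- if (nrow(sub) >= 2 && stats::sd(sub$z_true) > 0 &&
              stats::sd(sub$z_imp) > 0)
      slope_correlation(sub$z_imp, sub$z_true) else c(slope = NA, r = NA)
    out[[length(out) + 1]] <- data.frame(
      status = as.character(status[lev[1]]),
      maf_bin = as.character(maf_bin[lev[1]]),
      quality_bin = as.character(q_bin[lev[1]]),
      rmse = rb[["rmse"]], bias = rb[["bias"]], slope = sc[["slope"]],
      r = sc[["r"]], n = nrow(sub), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
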