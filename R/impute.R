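# Z-statistic imputation: base estimator, variable-sample-size correction,
# windowed genome scan and leave-one-out masking.

#' Impute the Z-statistic of an untyped variant
#'
#' Conditional mean of a multivariate normal: z_imp = c_lambda' C_lambda^-1 z,
#' a linear combination of the tag Z-statistics weighted by shrunk
#' reference-panel LD.
#'
#' @param z_tags tag Z-statistics.
#' @param C_lambda shrunk tag-tag correlation matrix.
#' @param c_lambda shrunk target-tag correlation vector.
#' @return imputed Z-statistic (scalar).
#' @export
impute_z <- function(z_tags, C_lambda, c_lambda) {
  q <- length(z_tags)
  if (length(c_lambda) != q || nrow(as.matrix(C_lambda)) != q)
    stop("dimension mismatch between z_tags, C_lambda and c_lambda")
  as.numeric(crossprod(c_lambda, solve_spd(C_lambda, z_tags)))
}

#' Sample-size attenuation under maximally dependent missingness
#'
#' Assumes the two variants' samples overlap as much as their sizes allow
#' (N_kl = min(N_k, N_l)), the most conservative assumption:
#' delta = min(sqrt(N_k/N_l), sqrt(N_l/N_k)).
#'
#' @param N_k,N_l per-variant sample sizes (vectorized).
#' @return attenuation factor in (0, 1\].
#' @export
delta_dep <- function(N_k, N_l) {
  stopifnot(all(N_k >= 1), all(N_l >= 1))
  pmin(sqrt(N_k / N_l), sqrt(N_l / N_k))
}

#' Sample-size attenuation under independent missingness
#'
#' Assumes the two variants' samples are drawn independently from the full
#' N_max individuals, giving expected overlap N_k N_l / N_max:
#' delta = sqrt(N_k N_l) / N_max.
#'
#' @param N_k,N_l per-variant sample sizes (vectorized).
#' @param N_max maximum sample size.
#' @return attenuation factor in (0, 1\].
#' @export
delta_ind <- function(N_k, N_l, N_max) {
  stopifnot(all(N_k <= N_max), all(N_l <= N_max))
  sqrt(N_k * N_l) / N_max
}

#' Missingness model for variable per-variant sample size
#'
#' @param mode `"none"` (equal samples assumed), `"dependent"` (maximum
#'   overlap; recommended default), `"independent"` (random overlap) or
#'   `"known"` (pairwise overlap counts supplied).
#' @param N per-tag sample sizes.
#' @param overlap matrix of pairwise overlap counts N_kl (mode `"known"`);
#'   must satisfy overlap_kl <= min(N_k, N_l) and overlap_kk = N_k.
#' @return object of class `missingness_model`.
#' @export
missingness_model <- function(mode = c("dependent", "none", "independent", "known"),
                              N = NULL, overlap = NULL) {
  mode <- match.arg(mode)
  if (mode != "none") {
    stopifnot(is.numeric(N), all(N >= 1))
    if (mode == "known") {
      overlap <- as.matrix(overlap)
      if (any(abs(diag(overlap) - N) > 1e-8))
        stop("overlap diagonal must equal N")
      if (any(overlap > outer(N, N, pmin) + 1e-8))
        stop("overlap_kl may not exceed min(N_k, N_l)")
    }
  }
  structure(list(mode = mode, N = N, N_max = if (is.null(N)) NULL else max(N),
                 overlap = overlap),
            class = "missingness_model")
}

#' Adjust the shrunk tag-tag LD matrix for sample-size overlap
#'
#' Multiplies each off-diagonal entry of the shrunk matrix by the pairwise
#' attenuation factor delta_kl implied by the missingness model; the diagonal
#' stays 1. With mode `"none"` the matrix is returned unchanged, so the
#' variable-N estimator reduces exactly to the base estimator.
#'
#' @param C_lambda shrunk tag-tag correlation matrix.
#' @param model a [missingness_model()].
#' @return adjusted matrix D.
#' @export
build_D <- function(C_lambda, model) {
  if (model$mode == "none") return(C_lambda)
  N <- model$N
  q <- length(N)
  if (nrow(as.matrix(C_lambda)) != q)
    stop("missingness model N not aligned with tag matrix")
  delta <- switch(model$mode,
    dependent   = outer(N, N, delta_dep),
    independent = outer(N, N, delta_ind, N_max = model$N_max),
    known       = model$overlap / sqrt(outer(N, N)))
  D <- C_lambda * delta
  diag(D) <- 1
  D
}

#' Adjust the shrunk target-tag correlations for sample size
#'
#' d_k = c_k sqrt(N_k / N_max): the correlation between the complete-sample
#' target statistic and the partial-sample tag statistic.
#'
#' @param c_lambda shrunk target-tag correlation vector or (tags x targets)
#'   matrix.
#' @param model a [missingness_model()].
#' @return adjusted vector/matrix d.
#' @export
build_d <- function(c_lambda, model) {
  if (model$mode == "none") return(c_lambda)
  c_lambda * sqrt(model$N / model$N_max)
}

#' Impute a Z-statistic under variable sample size
#'
#' z_imp = d' D^-1 z, the conditional mean with the sample-size-adjusted LD
#' system. With all sample sizes equal (or mode `"none"`) this is identical to
#' [impute_z()].
#'
#' @param z_obs observed (partial-sample) tag Z-statistics.
#' @param d adjusted target-tag correlations from [build_d()].
#' @param D adjusted tag-tag matrix from [build_D()].
#' @return imputed Z-statistic (scalar).
#' @export
impute_z_varn <- function(z_obs, d, D) impute_z(z_obs, D, d)

#' Convert an imputed Z-statistic to a standardized effect size
#'
#' a = z / (sqrt(N_max) * quality) where quality = d' D^-1 d is the imputation
#' quality of the variable-N system. Below `quality_floor` the effect is not
#' estimable from noise-level quality and `NA` is returned (the Z-statistic
#' itself remains reportable).
#'
#' @param z_imp imputed Z-statistic.
#' @param N_max maximum tag sample size.
#' @param quality imputation quality d' D^-1 d.
#' @param quality_floor minimum quality for which an effect is reported.
#' @return standardized effect estimate, or `NA` below the floor.
#' @export
z_to_effect <- function(z_imp, N_max, quality, quality_floor = 1e-4) {
  stopifnot(N_max >= 1)
  out <- z_imp / (sqrt(N_max) * quality)
  out[quality <= quality_floor] <- NA_real_
  out
}

#' Rescale an observed Z-statistic to the full sample size
#'
#' z* = z sqrt(N_max / N_u), making a statistic observed on N_u individuals
#' comparable with imputed statistics referring to the full N_max sample.
#'
#' @param z_u observed Z-statistic.
#' @param N_u its sample size.
#' @param N_max full sample size.
#' @return rescaled Z-statistic.
#' @export
rescale_observed_z <- function(z_u, N_u, N_max) {
  stopifnot(all(N_u >= 1))
  z_u * sqrt(N_max / N_u)
}

# Resolve a lambda spec ("fixed" | "sqrt" | numeric) to a value.
resolve_lambda <- function(lambda, n_panel) {
  if (is.numeric(lambda)) return(choose_lambda("value", value = lambda))
  if (identical(lambda, "fixed")) return(choose_lambda("fixed"))
  if (lambda %in% c("sqrt", "sqrt_n"))
    return(choose_lambda("sqrt_n", n_panel = n_panel))
  stop("unknown lambda specification: ", lambda)
}

# Impute all targets of one window from one tag system. Internal work-horse
# shared by window_impute() and mask_and_impute().
impute_block <- function(z_tags, N_tags, C, c_mat, lambda, missingness,
                         overlap = NULL, n_panel, qeff_threshold = 0.995,
                         quality_floor = 1e-4) {
  sh <- shrink_ld(C, c_mat, lambda)
  model <- missingness_model(missingness, N = N_tags, overlap = overlap)
  D <- build_D(sh$C_lambda, model)
  d <- build_d(sh$c_lambda, model)
  N_max <- if (is.null(model$N_max)) max(N_tags) else model$N_max

  rhs <- cbind(z_tags, d)
  sol <- solve_spd(D, rhs)                   # one factorization per window
  z_imp <- as.numeric(crossprod(d, sol[, 1]))
  quality_raw <- colSums(d * sol[, -1, drop = FALSE])
  r2_pred <- pmin(pmax(quality_raw, 0), 1)

  q_eff <- effective_num_variants(sh$C_lambda, threshold = qeff_threshold)
  r2_adj <- vapply(r2_pred, adjust_quality, numeric(1),
                   n_panel = n_panel, q_eff = q_eff)
  a_imp <- z_to_effect(z_imp, N_max, r2_pred, quality_floor = quality_floor)
  data.frame(z_imp = z_imp, a_imp = a_imp, r2_pred = r2_pred,
             r2_pred_adj = r2_adj, N_max = N_max, p_imp = z_to_p(z_imp),
             n_tags = length(z_tags), q_eff = q_eff,
             stringsAsFactors = FALSE)
}

#' Windowed genome-wide summary statistics imputation
#'
#' Splits each chromosome into core windows of `core_bp`; every panel variant
#' inside a core window that passes the MAF filter and is not itself a tag is
#' imputed from the harmonized tag records lying within the core window plus
#' `flank_bp` on each side. The shrunk (and missingness-adjusted) LD system is
#' factorized once per window and reused for all its targets. The window grid
#' is anchored at the smallest tag position per chromosome rounded down to a
#' multiple of `core_bp`; positions are 1-based, window intervals half-open.
#'
#' @param records harmonized summary records (see [harmonize_sumstats()]).
#' @param panel a [ref_panel].
#' @param core_bp core window width (default 1 Mb).
#' @param flank_bp flanking width on each side for tags (default 250 kb).
#' @param lambda `"fixed"` (0.1), `"sqrt"` (2/sqrt(n)) or a numeric value.
#' @param missingness `"dependent"`, `"independent"`, `"none"` or `"known"`.
#' @param overlap pairwise overlap matrix (mode `"known"`), aligned to records.
#' @param maf_min minimum panel MAF for imputation targets (default 0.001).
#' @param min_quality adjusted-quality threshold for the `quality_ok` flag
#'   (default 0.3); all results are written, flagged pass/fail.
#' @param targets optional character vector restricting target variant ids.
#' @param qeff_threshold variance fraction for the effective number of tags.
#' @return data.frame with one row per target (`source = "imputed"`) and one
#'   per tag (`source = "tag"`, carrying its observed Z).
#' @export
window_impute <- function(records, panel, core_bp = 1e6, flank_bp = 2.5e5,
                          lambda = "fixed",
                          missingness = c("dependent", "independent", "none", "known"),
                          overlap = NULL, maf_min = 0.001, min_quality = 0.3,
                          targets = NULL, qeff_threshold = 0.995) {
  missingness <- match.arg(missingness)
  lam <- resolve_lambda(lambda, panel$n)
  info <- panel$info
  maf <- pmin(info$af, 1 - info$af)
  tag_key <- paste(records$chr, records$pos)
  out <- list()

  for (chrom in unique(records$chr)) {
    rec_c <- records[records$chr == chrom, , drop = FALSE]
    origin <- floor(min(rec_c$pos) / core_bp) * core_bp
    on_chr <- info$chr == chrom
    target_ok <- on_chr & maf >= maf_min &
      !(paste(info$chr, info$pos) %in% tag_key)
    if (!is.null(targets)) target_ok <- target_ok & info$id %in% targets
    if (!any(target_ok) && nrow(rec_c) == 0) next
    widx <- window_index(info$pos, origin, core_bp)
    for (w in sort(unique(widx[target_ok]))) {
      w_start <- origin + w * core_bp
      w_end <- w_start + core_bp
      tgt <- which(target_ok & widx == w)
      if (!length(tgt)) next
      tags <- rec_c[rec_c$pos >= w_start - flank_bp &
                    rec_c$pos < w_end + flank_bp, , drop = FALSE]
      tinfo <- info[tgt, , drop = FALSE]
      if (nrow(tags) == 0) {
        out[[length(out) + 1]] <- data.frame(
          variant_id = tinfo$id, chr = tinfo$chr, pos = tinfo$pos,
          effect_allele = tinfo$alt, other_allele = tinfo$ref,
          z_imp = NA_real_, a_imp = NA_real_, r2_pred = 0, r2_pred_adj = 0,
          N_max = NA_real_, p_imp = NA_real_, n_tags = 0L,
          q_eff = NA_integer_, source = "imputed", quality_ok = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      tag_idx <- match(paste(tags$chr, tags$pos), paste(info$chr, info$pos))
      C <- panel_correlation(panel, tag_idx, on_zero_var = "flag")
      drop <- attr(C, "excluded")
      if (length(drop)) {
        tags <- tags[-drop, , drop = FALSE]
        tag_idx <- tag_idx[-drop]
      }
      c_mat <- panel_cross_correlation(panel, tag_idx, tgt)
      ov <- if (missingness == "known" && !is.null(overlap))
        overlap[tags$variant_id, tags$variant_id, drop = FALSE] else NULL
      blk <- impute_block(tags$z, tags$n, C, c_mat, lam, missingness,
                          overlap = ov, n_panel = panel$n,
                          qeff_threshold = qeff_threshold)
      out[[length(out) + 1]] <- cbind(
        data.frame(variant_id = tinfo$id, chr = tinfo$chr, pos = tinfo$pos,
                   effect_allele = tinfo$alt, other_allele = tinfo$ref,
                   stringsAsFactors = FALSE),
        blk, source = "imputed",
        quality_ok = blk$r2_pred_adj >= min_quality)
    }
  }

  tag_rows <- data.frame(
    variant_id = records$variant_id, chr = records$chr, pos = records$pos,
    effect_allele = records$effect_allele, other_allele = records$other_allele,
    z_imp = records$z, a_imp = records$z / sqrt(records$n), r2_pred = 1,
    r2_pred_adj = 1, N_max = records$n, p_imp = z_to_p(records$z),
    n_tags = NA_integer_, q_eff = NA_integer_, source = "tag",
    quality_ok = TRUE, stringsAsFactors = FALSE)
  res <- rbind(do.call(rbind, out), tag_rows)
  res <- res[order(res$chr, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Leave-one-out imputation of a focal variant
#'
#' Masks the focal variant and imputes it from all harmonized records within
#' `tag_radius_bp` of its position (a 1.5 Mb tagging window by default),
#' mimicking imputation of an untyped variant whose truth is known.
#'
#' @param records harmonized summary records containing the focal variant.
#' @param panel a [ref_panel] covering the region.
#' @param focal_id variant id to mask and impute.
#' @param tag_radius_bp tagging radius around the focal position.
#' @inheritParams window_impute
#' @return one-row data.frame as in [window_impute()], plus `z_obs` (the
#'   masked variant's own observed Z-statistic).
#' @export
mask_and_impute <- function(records, panel, focal_id, tag_radius_bp = 7.5e5,
                            lambda = "fixed",
                            missingness = c("dependent", "independent", "none", "known"),
                            overlap = NULL, qeff_threshold = 0.995) {
  missingness <- match.arg(missingness)
  lam <- resolve_lambda(lambda, panel$n)
  foc <- records[records$variant_id == focal_id, , drop = FALSE]
  if (nrow(foc) != 1) stop("focal variant not present (once) in records: ", focal_id)
  tags <- records[records$variant_id != focal_id &
                  records$chr == foc$chr &
                  abs(records$pos - foc$pos) <= tag_radius_bp, , drop = FALSE]
  if (nrow(tags) == 0) stop("no tag variants within radius of ", focal_id)
  info <- panel$info
  tag_idx <- match(paste(tags$chr, tags$pos), paste(info$chr, info$pos))
  foc_idx <- match(paste(foc$chr, foc$pos), paste(info$chr, info$pos))
  if (anyNA(c(tag_idx, foc_idx))) stop("records not covered by panel")
  C <- panel_correlation(panel, tag_idx, on_zero_var = "flag")
  drop <- attr(C, "excluded")
  if (length(drop)) {
    tags <- tags[-drop, , drop = FALSE]
    tag_idx <- tag_idx[-drop]
  }
  c_vec <- panel_cross_correlation(panel, tag_idx, foc_idx)
  ov <- if (missingness == "known" && !is.null(overlap))
    overlap[tags$variant_id, tags$variant_id, drop = FALSE] else NULL
  blk <- impute_block(tags$z, tags$n, C, c_vec, lam, missingness,
                      overlap = ov, n_panel = panel$n,
                      qeff_threshold = qeff_threshold)
  cbind(data.frame(variant_id = foc$variant_id, chr = foc$chr, pos = foc$pos,
                   stringsAsFactors = FALSE),
        blk, z_obs = foc$z)
}
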