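# Synthetic-data generator: LD-block genotypes from a calibrated
# latent-Gaussian haplotype model, a single-causal-variant phenotype,
# empirical sample-size draws and theta-controlled missingness.

# Bivariate standard normal rectangle probability P(X < t1, Y < t2 | rho),
# via the identity Phi2(t1,t2,rho) = Phi(t1)Phi(t2) + int_0^rho phi2(t1,t2,r) dr
# (one-dimensional integral of the bivariate density along the correlation).
pbinorm <- function(t1, t2, rho) {
  base <- stats::pnorm(t1) * stats::pnorm(t2)
  if (abs(rho) < 1e-12) return(base)
  dens <- function(r)
    exp(-(t1^2 - 2 * r * t1 * t2 + t2^2) / (2 * (1 - r^2))) /
      (2 * pi * sqrt(1 - r^2))
  base + stats::integrate(dens, 0, rho, rel.tol = 1e-10)$value
}

# Latent correlation that yields a target dosage (phi) correlation after
# thresholding two latent layers at the MAF quantiles. Because thresholding
# attenuates correlation, the latent rho must exceed the target; solved by
# root finding on the phi coefficient of the thresholded binaries.
latent_rho <- function(target_r, maf1, maf2 = maf1) {
  if (abs(target_r) < 1e-10) return(0)
  t1 <- stats::qnorm(maf1); t2 <- stats::qnorm(maf2)
  denom <- sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
  phi_of <- function(rho) (pbinorm(t1, t2, rho) - maf1 * maf2) / denom
  hi <- 0.99999
  if (phi_of(sign(target_r) * hi) * sign(target_r) < abs(target_r))
    stop("target LD ", target_r, " not attainable for MAFs ",
         maf1, ", ", maf2)
  stats::uniroot(function(r) phi_of(r) - target_r,
                 interval = sort(c(0, sign(target_r) * hi)),
                 tol = 1e-8)$root
}

#' Simulate an LD-block reference panel
#'
#' Genotypes are generated from two independent latent-Gaussian haplotype
#' layers thresholded at the MAF quantile; within each block the latent
#' correlation is calibrated so that the realized dosage correlation matches
#' the requested LD level `r`. Blocks are mutually independent. Variants are
#' laid out on one chromosome at regular spacing.
#'
#' @param n number of individuals.
#' @param blocks data.frame with one row per LD block: `size` (number of
#'   variants), `maf` (minor allele frequency, shared within the block) and
#'   `r` (target pairwise dosage correlation within the block).
#' @param chr chromosome label (default "1").
#' @param pos_start position of the first variant (default 1e5).
#' @param spacing bp between adjacent variants (default 5000).
#' @param seed random seed.
#' @return a [ref_panel]; the minor allele is the alt allele.
#' @export
simulate_genotypes <- function(n, blocks, chr = "1", pos_start = 1e5,
                               spacing = 5000, seed = 1) {
  stopifnot(all(blocks$size >= 1), all(blocks$maf > 0 & blocks$maf < 0.5),
            all(blocks$r >= 0 & blocks$r < 1))
  set.seed(seed)
  cols <- list()
  for (b in seq_len(nrow(blocks))) {
    m <- blocks$size[b]; p <- blocks$maf[b]; r <- blocks$r[b]
    rho <- if (m > 1) latent_rho(r, p) else 0
    R <- matrix(rho, m, m); diag(R) <- 1
    U <- chol(R)
    t_p <- stats::qnorm(p)
    g <- matrix(0, n, m)
    for (layer in 1:2) {
      Z <- matrix(stats::rnorm(n * m), n, m) %*% U
      g <- g + (Z < t_p)
    }
    cols[[b]] <- g
  }
  dosage <- do.call(cbind, cols)
  m_tot <- ncol(dosage)
  info <- data.frame(
    id = sprintf("sv%04d", seq_len(m_tot)), chr = chr,
    pos = pos_start + (seq_len(m_tot) - 1L) * spacing,
    ref = "A", alt = "G",
    block = rep(seq_len(nrow(blocks)), blocks$size),
    stringsAsFactors = FALSE)
  ref_panel(dosage, info)
}

#' Split a panel into LD-estimation and GWAS halves
#'
#' Disjoint individual subsets (sizes differ by at most one): one half to
#' estimate the LD structure, the other to run the association study, so the
#' reference panel is external to the GWAS sample.
#'
#' @param panel a [ref_panel].
#' @param fraction fraction of individuals for the LD panel (default 0.5).
#' @param seed random seed.
#' @return list with `ld_panel` and `gwas_panel`.
#' @export
split_panel <- function(panel, fraction = 0.5, seed = 1) {
  set.seed(seed)
  n <- panel$n
  idx <- sample.int(n, floor(n * fraction))
  list(ld_panel = ref_panel(panel$dosage[idx, , drop = FALSE], panel$info),
       gwas_panel = ref_panel(panel$dosage[-idx, , drop = FALSE], panel$info))
}

#' Simulate a continuous phenotype with one causal variant
#'
#' y = sqrt(h2) g_std + e with Var(e) = 1 - h2, so the causal variant's true
#' standardized effect is sqrt(h2) and it explains a fraction h2 of the
#' phenotypic variance.
#'
#' @param gwas_panel a [ref_panel] providing the genotypes.
#' @param causal index or id of the causal variant (h2 = 0 needs none).
#' @param h2 variance explained by the causal variant (default 0.02).
#' @param seed random seed.
#' @return numeric phenotype vector of length `gwas_panel$n`.
#' @export
simulate_phenotype <- function(gwas_panel, causal = NULL, h2 = 0.02,
                               seed = 1) {
  stopifnot(h2 >= 0, h2 < 1)
  set.seed(seed)
  n <- gwas_panel$n
  e <- stats::rnorm(n, 0, sqrt(1 - h2))
  if (h2 == 0 || is.null(causal)) return(e)
  if (is.character(causal)) causal <- match(causal, gwas_panel$info$id)
  g <- panel_dosage_imputed(gwas_panel, causal)[, 1]
  sqrt(h2) * as.numeric(scale(g)) + e
}

#' Draw per-variant sample sizes from an empirical distribution
#'
#' `wide` draws log-uniformly over 13..110219 (a wide meta-analysis sample
#' size range), `narrow` uniformly over 50000..187167 (a narrow range); both
#' are rescaled multiplicatively so the distribution's upper bound maps to
#' `scale_to`. `list` resamples user-supplied values with replacement and
#' rescales by their maximum.
#'
#' @param source `"wide"`, `"narrow"` or `"list"`.
#' @param m number of variants.
#' @param scale_to target maximum sample size (default 12500).
#' @param values sample sizes to resample when `source = "list"`.
#' @param seed random seed.
#' @return integer vector of length `m`, each >= 1.
#' @export
draw_sample_sizes <- function(source = c("wide", "narrow", "list"), m,
                              scale_to = 12500, values = NULL, seed = 1) {
  source <- match.arg(source)
  set.seed(seed)
  raw <- switch(source,
    wide = exp(stats::runif(m, log(13), log(110219))),
    narrow = stats::runif(m, 50000, 187167),
    list = {
      stopifnot(length(values) >= 1)
      sample(values, m, replace = TRUE)
    })
  upper <- switch(source, wide = 110219, narrow = 187167, list = max(values))
  pmax(1L, as.integer(round(raw * scale_to / upper)))
}

#' Assign per-variant observation masks with correlated missingness
#'
#' Each variant k gets an observed-individual set of exact size N_k. With
#' `theta = 1` the sets are nested prefixes of one shared individual ordering
#' (maximum possible pairwise overlap, min(N_k, N_l)); with `theta = 0` each
#' set is an independent uniform draw (hypergeometric overlap, mean
#' N_k N_l / n). Intermediate theta mixes the two: a Binomial(N_k, theta)
#' number of slots is taken from the shared nested prefix and the remainder
#' drawn uniformly from the other individuals, which hits both endpoints
#' exactly and is monotone in theta.
#'
#' @param N per-variant sample sizes (each <= n).
#' @param n number of individuals.
#' @param theta missingness correlation in \[0, 1\].
#' @param seed random seed.
#' @return logical matrix n x length(N); TRUE = observed.
#' @export
assign_missingness <- function(N, n, theta, seed = 1) {
  stopifnot(all(N <= n), theta >= 0, theta <= 1)
  set.seed(seed)
  ord <- sample.int(n)                       # shared nesting order
  mask <- matrix(FALSE, n, length(N))
  for (k in seq_along(N)) {
    b <- stats::rbinom(1, N[k], theta)
    nested <- ord[seq_len(b)]
    rest <- if (N[k] > b)
      sample(setdiff(seq_len(n), nested), N[k] - b) else integer(0)
    mask[c(nested, rest), k] <- TRUE
  }
  mask
}

#' Run a per-variant GWAS on (possibly masked) genotypes
#'
#' For each variant, genotype and phenotype are restricted to that variant's
#' observed individuals and standardized on that subset; the standardized
#' effect is a = g'y/N_k and the Z-statistic z = a sqrt(N_k). Variants with a
#' constant genotype in their observed subset are dropped with a warning.
#'
#' @param gwas_panel a [ref_panel].
#' @param phenotype numeric vector of length `gwas_panel$n`.
#' @param mask optional logical observation matrix from
#'   [assign_missingness()]; `NULL` means complete data.
#' @return data.frame of summary records (`variant_id`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `z`, `n`, `af`), aligned to the panel
#'   alt allele.
#' @export
run_gwas <- function(gwas_panel, phenotype, mask = NULL) {
  info <- gwas_panel$info
  G <- gwas_panel$dosage
  m <- ncol(G)
  z <- n_k <- rep(NA_real_, m)
  for (k in seq_len(m)) {
    obs <- if (is.null(mask)) !is.na(G[, k]) else mask[, k] & !is.na(G[, k])
    g <- G[obs, k]; y <- phenotype[obs]
    if (length(g) < 3 || stats::sd(g) == 0) next
    a <- stats::cor(g, y)
    n_k[k] <- length(g)
    z[k] <- a * sqrt(n_k[k])
  }
  bad <- is.na(z)
  if (any(bad))
    warning(sum(bad), " variant(s) dropped (constant genotype in observed subset)")
  data.frame(variant_id = info$id[!bad], chr = info$chr[!bad],
             pos = info$pos[!bad], effect_allele = info$alt[!bad],
             other_allele = info$ref[!bad], z = z[!bad], n = n_k[!bad],
             af = info$af[!bad], stringsAsFactors = FALSE)
}

#' Missingness-correction simulation experiment
#'
#' Reproduces the structure of the variable-sample-size validation: for each
#' simulated region the causal (non-tag) variant's standardized effect is
#' imputed from tag summary statistics under three estimators — the
#' conventional one that ignores missingness, and the dependent- and
#' independent-overlap corrections — and the squared error against the known
#' true effect sqrt(h2) is recorded. Genotypes and phenotype are shared
#' across the theta x distribution grid within a replicate; only sample
#' sizes and missingness masks are redrawn.
#'
#' @param dists sample-size distributions to use (subset of
#'   `c("wide", "narrow")`).
#' @param thetas missingness correlation values.
#' @param n_regions number of independently simulated regions (default 10).
#' @param n_replicates replicates per region (default 50).
#' @param n_gwas GWAS sample size (default 2500); the simulated panel has
#'   2 * n_gwas individuals, half of which estimate LD.
#' @param blocks LD-block layout for each region (default: three blocks of 8
#'   variants, r = 0.8, MAF drawn in 0.1..0.4).
#' @param h2 causal explained variance (default 0.02).
#' @param lambda shrinkage intensity (default 0.1).
#' @param seed base seed; all stages derive named sub-seeds from it.
#' @return data.frame with columns `dist`, `theta`, `region`, `estimator`
#'   (`conventional`, `dep`, `ind`) and `mse` (mean squared error over
#'   replicates).
#' @export
missingness_mse_experiment <- function(dists = c("wide", "narrow"),
                                       thetas = c(0, 0.5, 1),
                                       n_regions = 10, n_replicates = 50,
                                       n_gwas = 2500, blocks = NULL,
                                       h2 = 0.02, lambda = 0.1, seed = 1) {
  err <- array(0, dim = c(length(dists), length(thetas), n_regions, 3),
               dimnames = list(dists, paste(thetas), NULL,
                               c("conventional", "dep", "ind")))
  alpha_true <- sqrt(h2)
  for (rg in seq_len(n_regions)) {
    blk <- blocks %||% {
      set.seed(sub_seed(seed, paste0("blocks", rg)))
      data.frame(size = c(8, 8, 8),
                 maf = stats::runif(3, 0.1, 0.4),
                 r = c(0.8, 0.8, 0.8))
    }
    for (rep_i in seq_len(n_replicates)) {
      s0 <- sub_seed(seed, paste0("region", rg, "rep", rep_i))
      panel <- simulate_genotypes(2 * n_gwas, blk, seed = s0)
      halves <- split_panel(panel, 0.5, seed = s0 + 1L)
      m <- ncol(panel$dosage)
      causal <- ceiling(blk$size[1] / 2)     # inside the first block
      y <- simulate_phenotype(halves$gwas_panel, causal, h2, seed = s0 + 2L)
      tag_idx <- setdiff(seq_len(m), causal)
      Cs <- panel_correlation(halves$ld_panel, tag_idx)
      cs <- as.numeric(panel_cross_correlation(halves$ld_panel, tag_idx, causal))
      sh <- shrink_ld(Cs, cs, lambda)
      for (di in seq_along(dists)) {
        N <- draw_sample_sizes(dists[di], length(tag_idx), scale_to = n_gwas,
                               seed = s0 + 3L + di)
        for (ti in seq_along(thetas)) {
          mask_full <- matrix(FALSE, n_gwas, m)
          mask_full[, tag_idx] <- assign_missingness(
            N, n_gwas, thetas[ti], seed = s0 + 10L * di + ti)
          recs <- suppressWarnings(run_gwas(halves$gwas_panel, y, mask_full))
          keep <- match(recs$variant_id, panel$info$id[tag_idx])
          ok <- !is.na(keep)
          zk <- recs$z[ok]; Nk <- recs$n[ok]; sel <- keep[ok]
          Cl <- sh$C_lambda[sel, sel, drop = FALSE]
          cl <- sh$c_lambda[sel]
          a_conv <- as.numeric(crossprod(cl, solve_spd(Cl, zk / sqrt(Nk))))
          for (est in c("dep", "ind")) {
            model <- missingness_model(
              if (est == "dep") "dependent" else "independent", N = Nk)
            D <- build_D(Cl, model)
            d <- build_d(cl, model)
            sol <- solve_spd(D, cbind(zk, d))
            z_hat <- sum(d * sol[, 1])
            qual <- sum(d * sol[, 2])
            a_hat <- z_hat / (sqrt(model$N_max) * qual)
            err[di, ti, rg, est] <- err[di, ti, rg, est] +
              (a_hat - alpha_true)^2
          }
          err[di, ti, rg, "conventional"] <-
            err[di, ti, rg, "conventional"] + (a_conv - alpha_true)^2
        }
      }
    }
  }
  out <- expand.grid(dist = dists, theta = thetas, region = seq_len(n_regions),
                     estimator = c("conventional", "dep", "ind"),
                     stringsAsFactors = FALSE)
  out$mse <- mapply(function(d, t, r, e)
    err[d, paste(t), r, e] / n_replicates,
    out$dist, out$theta, out$region, out$estimator)
  out
}
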