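# Z-statistic imputation and the variable-sample-size correction.

test_that("impute_z: self-tagging, full shrinkage, and a generic-solver oracle", {
  C <- matrix(c(1, .5, .2, .5, 1, .3, .2, .3, 1), 3, 3)
  z <- c(2, -1, 3)
  # target is tag 2 at lambda = 0: picks out its own z
  expect_equal(impute_z(z, C, C[, 2]), z[2])
  # lambda = 1: c shrinks to zero, imputation is zero
  s <- shrink_ld(C, c(.4, .6, .1), 1)
  expect_equal(impute_z(z, s$C_lambda, s$c_lambda), 0)
  # frozen oracle: qr.solve on the same 3-tag system
  expect_equal(impute_z(z, C, c(.4, .6, .1)), -0.5661764706, tolerance = 1e-9)
  expect_equal(impute_z(z, C, c(.4, .6, .1)),
               drop(crossprod(c(.4, .6, .1), qr.solve(C, z))))
  expect_error(impute_z(z, C, c(.4, .6)), "dimension mismatch")
})

test_that("sample-size attenuation factors match their closed forms", {
  expect_equal(delta_dep(100, 100), 1.0)
  expect_equal(delta_dep(50, 200), 0.5)
  expect_equal(delta_dep(200, 50), 0.5)              # symmetric
  expect_equal(delta_dep(1, 1e6), 1e-3)
  expect_equal(delta_ind(200, 200, 200), 1.0)
  expect_equal(delta_ind(50, 200, 200), 0.5)
  expect_equal(delta_ind(100, 100, 200), 0.5)
})

test_that("dependent attenuation dominates independent over a grid", {
  Ns <- round(seq(1, 5000, length.out = 100))
  grid <- expand.grid(Nk = Ns, Nl = Ns)
  Nmax <- 5000
  dd <- delta_dep(grid$Nk, grid$Nl)
  di <- delta_ind(grid$Nk, grid$Nl, Nmax)
  expect_true(all(dd >= di - 1e-12))
  eq <- abs(dd - di) < 1e-12
  expect_equal(eq, pmax(grid$Nk, grid$Nl) == Nmax)
})

test_that("D and d constructions follow the overlap model", {
  Cl <- matrix(c(1, 0.8, 0.8, 1), 2)
  m_dep <- missingness_model("dependent", N = c(50, 200))
  D <- build_D(Cl, m_dep)
  expect_equal(D[1, 2], 0.4)
  expect_equal(diag(D), c(1, 1))
  m_eq <- missingness_model("dependent", N = c(200, 200))
  expect_equal(build_D(Cl, m_eq), Cl)
  m_known <- missingness_model("known", N = c(50, 200),
                               overlap = matrix(c(50, 0, 0, 200), 2))
  expect_equal(build_D(Cl, m_known)[1, 2], 0)        # disjoint samples
  expect_error(missingness_model("known", N = c(50, 200),
                                 overlap = matrix(c(50, 60, 60, 200), 2)),
               "min")
  expect_equal(build_d(c(0.8, 0), m_dep), c(0.8, 0) * sqrt(c(50, 200) / 200))
  expect_equal(build_d(c(0.8, 0.3), m_eq), c(0.8, 0.3))
})

test_that("variable-N imputation reduces exactly to the base estimator", {
  set.seed(7)
  p <- toy_panel(n = 400)
  C <- panel_correlation(p, 1:4)
  cv <- as.numeric(panel_cross_correlation(p, 1:4, 5))
  s <- shrink_ld(C, cv, 0.1)
  z <- rnorm(4)
  model <- missingness_model("none", N = rep(1000, 4))
  expect_identical(impute_z_varn(z, build_d(s$c_lambda, model),
                                 build_D(s$C_lambda, model)),
                   impute_z(z, s$C_lambda, s$c_lambda))
  # single tag with quartered sample size halves the imputed z
  expect_equal(impute_z_varn(5, 0.8 * sqrt(100 / 400), matrix(1)), 2.0)
  # random 5-tag system equals a generic linear solve
  C5 <- panel_correlation(p, c(1:3, 6:7))
  c5 <- as.numeric(panel_cross_correlation(p, c(1:3, 6:7), 8))
  s5 <- shrink_ld(C5, c5, 0.1)
  m5 <- missingness_model("dependent", N = c(100, 900, 400, 1000, 250))
  D <- build_D(s5$C_lambda, m5); d <- build_d(s5$c_lambda, m5)
  z5 <- rnorm(5)
  expect_equal(impute_z_varn(z5, d, D), drop(crossprod(d, qr.solve(D, z5))),
               tolerance = 1e-10)
})

test_that("effect conversion and observed-z rescaling follow their algebra", {
  expect_equal(z_to_effect(2, 400, 1), 0.1)
  expect_equal(z_to_effect(0, 400, 0.5), 0)
  expect_true(is.na(z_to_effect(2, 400, 1e-5)))      # below quality floor
  # round trip a -> z -> a with fixed quality
  a <- 0.07; q <- 0.6; Nmax <- 900
  z <- a * sqrt(Nmax) * q
  expect_equal(z_to_effect(z, Nmax, q), a)
  expect_equal(rescale_observed_z(3, 100, 400), 6)
  expect_equal(rescale_observed_z(1.5, 400, 400), 1.5)
  expect_equal(rescale_observed_z(0, 10, 400), 0)
})

test_that("imputation is equivariant under a tag's allele sign flip", {
  set.seed(17)
  C <- matrix(c(1, .5, .2, .5, 1, .3, .2, .3, 1), 3, 3)
  cv <- c(.4, .6, .1); z <- rnorm(3)
  base <- impute_z(z, C, cv)
  k <- 2
  Cf <- C; Cf[k, ] <- -Cf[k, ]; Cf[, k] <- -Cf[, k]
  cf <- cv; cf[k] <- -cf[k]
  zf <- z; zf[k] <- -zf[k]
  expect_equal(impute_z(zf, Cf, cf), base, tolerance = 1e-12)
})

test_that("variable-N quality is bounded and shrinks as a sample size drops", {
  set.seed(27)
  p <- toy_panel(n = 500)
  C <- panel_correlation(p, 1:4)
  cv <- as.numeric(panel_cross_correlation(p, 1:4, 5))
  s <- shrink_ld(C, cv, 0.1)
  qual <- function(N) {
    m <- missingness_model("dependent", N = N)
    D <- build_D(s$C_lambda, m); d <- build_d(s$c_lambda, m)
    drop(crossprod(d, solve(D, d)))
  }
  Nvals <- c(1000, 600, 300, 100, 20)
  qs <- vapply(Nvals, function(nk) qual(c(nk, 1000, 1000, 1000)), numeric(1))
  expect_true(all(qs >= 0 & qs <= 1 + 1e-8))
  expect_true(all(diff(qs) <= 1e-8))                 # non-increasing
})

test_that("windowed imputation emits tags as tags and respects locality", {
  p <- simulate_genotypes(600, data.frame(size = c(6, 6), maf = c(0.3, 0.25),
                                          r = c(0.8, 0.8)),
                          pos_start = 1e5, spacing = 3e5, seed = 13)
  # blocks straddle several 1 Mb windows; tag half the variants
  recs <- toy_records(p)[c(1, 2, 4, 7, 8, 10), ]
  res <- window_impute(recs, p, lambda = 0.1, missingness = "none")
  expect_setequal(res$variant_id, p$info$id)
  expect_setequal(res$variant_id[res$source == "tag"], recs$variant_id)
  imp <- res[res$source == "imputed", ]
  expect_true(all(is.finite(imp$z_imp)))
  expect_true(all(imp$r2_pred >= 0 & imp$r2_pred <= 1))
  expect_equal(imp$p_imp, 2 * pnorm(-abs(imp$z_imp)))

  # locality: windows with disjoint tag sets give independent results
  far <- simulate_genotypes(600, data.frame(size = c(4, 4), maf = 0.3, r = 0.8),
                            pos_start = 1e5, spacing = 1e4, seed = 14)
  far$info$pos[5:8] <- far$info$pos[5:8] + 5e6       # second window, far away
  far <- ref_panel(far$dosage, far$info)
  recs2 <- toy_records(far)[c(1, 2, 5, 6), ]
  both <- window_impute(recs2, far, lambda = 0.1, missingness = "none")
  solo <- window_impute(recs2[1:2, ], far, lambda = 0.1, missingness = "none")
  shared <- intersect(both$variant_id[both$source == "imputed" &
                                      both$pos < 2e6],
                      solo$variant_id[solo$source == "imputed"])
  expect_equal(both$z_imp[match(shared, both$variant_id)],
               solo$z_imp[match(shared, solo$variant_id)])
})

test_that("windows without tags yield zero-quality targets, not errors", {
  p <- simulate_genotypes(300, data.frame(size = 4, maf = 0.3, r = 0.5),
                          pos_start = 1e5, spacing = 1e4, seed = 15)
  p$info$pos[4] <- 8e6                               # lone target far away
  p <- ref_panel(p$dosage, p$info)
  recs <- toy_records(p)[1:3, ]
  res <- window_impute(recs, p, lambda = 0.1, missingness = "none")
  lone <- res[res$variant_id == p$info$id[4], ]
  expect_equal(lone$r2_pred, 0)
  expect_true(is.na(lone$z_imp))
})

test_that("masking recovers a perfect-LD proxy and flags unlinked targets", {
  set.seed(19)
  p <- toy_panel(n = 1500)
  # duplicate column: perfect proxy for sv0001
  dup <- ref_panel(cbind(p$dosage, p$dosage[, 1]),
                   rbind(p$info[, 1:5],
                         data.frame(id = "proxy", chr = "1", pos = 2.05e5,
                                    ref = "A", alt = "G")))
  y <- simulate_phenotype(dup, 1, 0.02, seed = 3)
  recs <- run_gwas(dup, y)
  res <- mask_and_impute(recs, dup, "sv0001", lambda = 1e-4,
                         missingness = "none")
  z_obs <- recs$z[recs$variant_id == "sv0001"]
  expect_equal(res$z_imp, z_obs, tolerance = 0.01)
  expect_gt(res$r2_pred, 0.99)

  # a target with no LD to any tag: quality near zero
  set.seed(23)
  solo <- ref_panel(cbind(p$dosage, rbinom(p$n, 2, 0.3)),
                    rbind(p$info[, 1:5],
                          data.frame(id = "unlinked", chr = "1", pos = 2.1e5,
                                     ref = "A", alt = "G")))
  recs2 <- run_gwas(solo, simulate_phenotype(solo, 1, 0.02, seed = 4))
  res2 <- mask_and_impute(recs2, solo, "unlinked", lambda = 0.1,
                          missingness = "none")
  expect_lt(res2$r2_pred, 0.05)
  expect_lt(abs(res2$z_imp), abs(res2$z_obs) + 2)
})
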