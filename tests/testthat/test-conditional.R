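# Approximate conditional analysis and the candidate-locus scan.

test_that("conditional z: empty set, closed form, and degenerate LD", {
  r <- conditional_z(3.2, numeric(0), numeric(0), NULL)
  expect_equal(r$z_cond, 3.2)
  expect_equal(r$p_cond, 2 * pnorm(-3.2))
  # single conditioner closed form: (6 - 0.6*5)/sqrt(1 - 0.36) = 3.75
  r2 <- conditional_z(6, 5, 0.6, matrix(1), lambda = 0)
  expect_equal(r2$z_cond, 3.75)
  # perfect LD with the conditioner: non-estimable, never inflated
  r3 <- conditional_z(6, 5, 1, matrix(1), lambda = 0)
  expect_false(r3$estimable)
  expect_true(is.na(r3$z_cond))
})

test_that("conditional z is invariant to conditioner order and null additions", {
  set.seed(33)
  C <- matrix(c(1, .4, .4, 1), 2)
  c_uS <- c(.5, .3); z_S <- c(4, 2)
  a <- conditional_z(5, z_S, c_uS, C, lambda = 0.05)
  b <- conditional_z(5, rev(z_S), rev(c_uS), C[2:1, 2:1], lambda = 0.05)
  expect_equal(abs(a$z_cond), abs(b$z_cond), tolerance = 1e-12)

  # adding a conditioner with zero LD to target and set leaves z unchanged
  C3 <- rbind(cbind(C, c(0, 0)), c(0, 0, 1))
  a3 <- conditional_z(5, c(z_S, 1.7), c(c_uS, 0), C3, lambda = 0)
  a0 <- conditional_z(5, z_S, c_uS, C, lambda = 0)
  expect_equal(a3$z_cond, a0$z_cond, tolerance = 1e-10)
})

# Two distant LD blocks: a "reported" causal tag in block 1 and a novel
# untyped causal variant in block 2, in different 1 Mb windows.
scan_fixture <- function(seed) {
  blocks <- data.frame(size = c(6, 6), maf = c(0.3, 0.25), r = c(0.9, 0.9))
  p <- simulate_genotypes(9000, blocks, pos_start = 5e5, spacing = 2e4,
                          seed = seed)
  info <- p$info
  info$pos[info$block == 2] <- info$pos[info$block == 2] + 1.5e6
  p <- ref_panel(p$dosage, info)
  halves <- split_panel(p, 0.4, seed = seed + 1)
  gw <- halves$gwas_panel
  reported_id <- gw$info$id[1]                       # typed causal, block 1
  novel_id <- gw$info$id[9]                          # untyped causal, block 2
  g1 <- scale(gw$dosage[, 1]); g2 <- scale(gw$dosage[, 9])
  set.seed(seed + 2)
  h2 <- 0.012
  y <- sqrt(h2) * (as.numeric(g1) + as.numeric(g2)) +
    rnorm(gw$n, 0, sqrt(1 - 2 * h2))
  tags <- setdiff(seq_len(ncol(gw$dosage)), 9)       # novel variant untyped
  recs <- run_gwas(ref_panel(gw$dosage[, tags], gw$info[tags, ]), y)
  list(panel = halves$ld_panel, records = recs, reported_id = reported_id,
       novel_id = novel_id)
}

test_that("locus scan keeps the novel signal and conditions away the reported one", {
  fx <- scan_fixture(101)
  imp <- window_impute(fx$records, fx$panel, lambda = 0.1,
                       missingness = "none", maf_min = 0.01)
  reported <- fx$records[fx$records$variant_id == fx$reported_id,
                         c("variant_id", "chr", "pos", "z")]
  scan <- locus_scan(imp, reported, fx$panel, p_threshold = 1e-8,
                     lambda = 0.1)
  expect_equal(nrow(scan$loci), 1)
  expect_equal(scan$loci$top_variant, fx$novel_id)
  # block-1 members were conditioned away (or none passed); none significant
  blk1 <- scan$members[scan$members$pos < 1.5e6 & scan$members$estimable, ]
  if (nrow(blk1)) expect_true(all(blk1$p_cond > 1e-8))
})

test_that("scan with no reported variant in range falls back to marginal P", {
  fx <- scan_fixture(202)
  imp <- window_impute(fx$records, fx$panel, lambda = 0.1,
                       missingness = "none", maf_min = 0.01)
  far_reported <- data.frame(variant_id = "rs_not_in_panel", chr = "2",
                             pos = 1e6, z = 10)
  expect_warning(
    scan <- locus_scan(imp, far_reported, fx$panel, p_threshold = 1e-8),
    "absent from panel")
  novel_rows <- scan$members[scan$members$variant_id == fx$novel_id, ]
  expect_equal(novel_rows$z_cond, novel_rows$z_imp)
})

test_that("a set-1 member in perfect LD with a reported variant cannot seed a locus", {
  p <- toy_panel(n = 2000, seed = 55)
  dup <- ref_panel(cbind(p$dosage, p$dosage[, 1]),
                   rbind(p$info[, 1:5],
                         data.frame(id = "shadow", chr = "1", pos = 2.05e5,
                                    ref = "A", alt = "G")))
  imp <- data.frame(variant_id = "shadow", chr = "1", pos = 2.05e5,
                    z_imp = 8, p_imp = 2 * pnorm(-8), r2_pred = 1,
                    r2_pred_adj = 1, source = "imputed",
                    stringsAsFactors = FALSE)
  reported <- data.frame(variant_id = "sv0001", chr = "1", pos = 1e5, z = 8)
  scan <- locus_scan(imp, reported, dup, p_threshold = 1e-8, lambda = 0)
  expect_equal(nrow(scan$loci), 0)
  expect_false(scan$members$estimable[1])
})

test_that("pairwise conditional returns the worst-case neighbour", {
  p <- toy_panel(n = 2000, seed = 66)
  lead <- data.frame(variant_id = "sv0002", chr = "1", pos = p$info$pos[2],
                     z_imp = 7, stringsAsFactors = FALSE)
  # no neighbours: marginal P
  none <- pairwise_conditional(lead, lead[0, ], p)
  expect_equal(none$p_max, 2 * pnorm(-7))
  # a strong-LD proxy of the same signal explains it away
  nb <- data.frame(variant_id = c("sv0001", "sv0006"), chr = "1",
                   pos = p$info$pos[c(1, 6)], z = c(7.2, 0.3))
  res <- pairwise_conditional(lead, nb, p, lambda = 0.05)
  expect_equal(res$worst_neighbor, "sv0001")
  expect_gt(res$p_max, 1e-4)
  # a zero-LD neighbour barely moves the P-value
  solo <- pairwise_conditional(lead, nb[2, ], p, lambda = 0.05)
  expect_equal(solo$p_max, 2 * pnorm(-7), tolerance = 0.3)
})

test_that("adjacent-window loci describing one signal are merged", {
  p <- toy_panel(n = 2000, seed = 77)
  dup <- ref_panel(cbind(p$dosage, p$dosage[, 1]),
                   rbind(p$info[, 1:5],
                         data.frame(id = "twin", chr = "1", pos = 1.2e6,
                                    ref = "A", alt = "G")))
  loci <- data.frame(
    chr = "1", window = c(0L, 1L), start = c(0, 1e6), end = c(1e6, 2e6),
    bp1 = c(1e5, 1.2e6), bp2 = c(1e5, 1.2e6),
    top_variant = c("sv0001", "twin"), top_pos = c(1e5, 1.2e6),
    top_z_cond = c(9, 8.5), top_p_cond = z_p <- 2 * pnorm(-c(9, 8.5)),
    n_members = 1L, n_conditioners = 0L, stringsAsFactors = FALSE)
  merged <- merge_adjacent_loci(loci, dup, imputed = NULL,
                                p_threshold = 1e-8, lambda = 0)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$top_variant, "sv0001")         # stronger top retained
})
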