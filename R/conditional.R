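# Approximate conditional analysis of summary statistics and the
# candidate-locus scan against previously reported variants.

#' Condition a Z-statistic on a set of variants
#'
#' Standardized residual of the multivariate normal: the target Z-statistic
#' minus its LD-predicted component from the conditioning set, divided by the
#' residual standard deviation:
#' z_cond = (z_u - c' C^-1 z_S) / sqrt(1 - c' C^-1 c), with shrunk c and C.
#' When the residual variance falls below `var_floor` (near-perfect LD with
#' the conditioners) the result is non-estimable rather than inflated.
#'
#' @param z_u target Z-statistic.
#' @param z_S Z-statistics of the conditioning variants (may be empty).
#' @param c_uS target-conditioner correlation vector.
#' @param C_SS conditioner-conditioner correlation matrix.
#' @param lambda shrinkage intensity.
#' @param var_floor minimum residual variance (default 1e-3).
#' @return list with `z_cond`, `p_cond`, `estimable`, `ld_max` (maximum
#'   squared correlation with a conditioner).
#' @export
conditional_z <- function(z_u, z_S, c_uS, C_SS, lambda = 0.1,
                          var_floor = 1e-3) {
  if (length(z_S) == 0)
    return(list(z_cond = z_u, p_cond = z_to_p(z_u), estimable = TRUE,
                ld_max = 0))
  sh <- shrink_ld(C_SS, c_uS, lambda)
  sol <- solve_spd(sh$C_lambda, cbind(as.numeric(z_S), as.numeric(sh$c_lambda)))
  fitted <- sum(sh$c_lambda * sol[, 1])
  resid_var <- 1 - sum(sh$c_lambda * sol[, 2])
  ld_max <- max(c_uS^2)
  if (resid_var < var_floor)
    return(list(z_cond = NA_real_, p_cond = NA_real_, estimable = FALSE,
                ld_max = ld_max))
  z_cond <- (z_u - fitted) / sqrt(resid_var)
  list(z_cond = z_cond, p_cond = z_to_p(z_cond), estimable = TRUE,
       ld_max = ld_max)
}

# Correlations needed for conditioning one target on a set, from the panel.
cond_ld <- function(panel, target_id, cond_ids) {
  ti <- match(target_id, panel$info$id)
  si <- match(cond_ids, panel$info$id)
  list(c_uS = as.numeric(panel_cross_correlation(panel, si, ti)),
       C_SS = panel_correlation(panel, si))
}

#' Scan imputed results for candidate loci independent of reported variants
#'
#' Within each core window, the first set holds all imputed variants passing
#' the quality gate (adjusted quality >= `min_quality`) with imputed P-value
#' <= `p_threshold`, spanning positions bp1..bp2; the second set holds all
#' reported variants within bp1 - `flank_bp` to bp2 + `flank_bp`. Each
#' first-set member is conditioned on the entire second set; a window is
#' declared a candidate locus if at least one member retains a conditional
#' P-value <= `p_threshold`. The member with the smallest conditional P-value
#' (ties: smaller position, then lexicographic id) is the top variant.
#' Adjacent-window loci are then merged via [merge_adjacent_loci()].
#'
#' @param imputed data.frame from [window_impute()] (rows with
#'   `source == "imputed"` are scanned).
#' @param reported data.frame of reported variants: `variant_id`, `chr`,
#'   `pos`, `z`. Reported variants absent from the panel are dropped with a
#'   warning.
#' @param panel a [ref_panel] covering imputed and reported variants.
#' @param p_threshold significance threshold (default 1e-8).
#' @param flank_bp reported-variant search flank (default 1 Mb).
#' @param min_quality adjusted-quality gate for the first set (default 0.3).
#' @param lambda shrinkage intensity for the conditional systems.
#' @param core_bp core window width used to group results (default 1 Mb).
#' @param merge merge adjacent-window loci (default TRUE).
#' @return list with `loci` (one row per candidate locus: window bounds, top
#'   variant, its conditional Z/P, number of members and conditioners) and
#'   `members` (per-variant conditional results in candidate windows).
#' @export
locus_scan <- function(imputed, reported, panel, p_threshold = 1e-8,
                       flank_bp = 1e6, min_quality = 0.3, lambda = 0.1,
                       core_bp = 1e6, merge = TRUE) {
  imp <- imputed[imputed$source == "imputed" & !is.na(imputed$p_imp), ,
                 drop = FALSE]
  in_panel <- reported$variant_id %in% panel$info$id
  if (any(!in_panel)) {
    warning(sum(!in_panel), " reported variant(s) absent from panel; dropped")
    reported <- reported[in_panel, , drop = FALSE]
  }
  set1_all <- imp[imp$r2_pred_adj >= min_quality & imp$p_imp <= p_threshold, ,
                  drop = FALSE]
  if (nrow(set1_all) == 0)
    return(list(loci = empty_loci(), members = empty_members()))

  loci <- list(); members <- list()
  for (chrom in unique(set1_all$chr)) {
    s1c <- set1_all[set1_all$chr == chrom, , drop = FALSE]
    origin <- floor(min(imp$pos[imp$chr == chrom]) / core_bp) * core_bp
    widx <- window_index(s1c$pos, origin, core_bp)
    for (w in sort(unique(widx))) {
      s1 <- s1c[widx == w, , drop = FALSE]
      bp1 <- min(s1$pos); bp2 <- max(s1$pos)
      rep_w <- reported[reported$chr == chrom &
                        reported$pos >= bp1 - flank_bp &
                        reported$pos <= bp2 + flank_bp, , drop = FALSE]
      cond <- condition_set(s1, rep_w, panel, lambda)
      cond$window <- w
      members[[length(members) + 1]] <- cond
      hit <- cond$estimable & !is.na(cond$p_cond) & cond$p_cond <= p_threshold
      if (!any(hit)) next
      top <- pick_top(cond[hit, , drop = FALSE])
      loci[[length(loci) + 1]] <- data.frame(
        chr = chrom, window = w, start = origin + w * core_bp,
        end = origin + (w + 1) * core_bp, bp1 = bp1, bp2 = bp2,
        top_variant = top$variant_id, top_pos = top$pos,
        top_z_cond = top$z_cond, top_p_cond = top$p_cond,
        n_members = sum(hit), n_conditioners = nrow(rep_w),
        stringsAsFactors = FALSE)
    }
  }
  loci <- if (length(loci)) do.call(rbind, loci) else empty_loci()
  members <- if (length(members)) do.call(rbind, members) else empty_members()
  if (merge && nrow(loci) > 1)
    loci <- merge_adjacent_loci(loci, panel, imputed = imp,
                                p_threshold = p_threshold, lambda = lambda)
  rownames(loci) <- NULL
  list(loci = loci, members = members)
}

empty_loci <- function() data.frame(
  chr = character(), window = integer(), start = numeric(), end = numeric(),
  bp1 = integer(), bp2 = integer(), top_variant = character(),
  top_pos = integer(), top_z_cond = numeric(), top_p_cond = numeric(),
  n_members = integer(), n_conditioners = integer(), stringsAsFactors = FALSE)

empty_members <- function() data.frame(
  variant_id = character(), chr = character(), pos = integer(),
  z_imp = numeric(), p_imp = numeric(), z_cond = numeric(),
  p_cond = numeric(), estimable = logical(), ld_max = numeric(),
  window = integer(), stringsAsFactors = FALSE)

# Condition each row of set1 on all reported variants in rep_w.
condition_set <- function(s1, rep_w, panel, lambda) {
  out <- lapply(seq_len(nrow(s1)), function(i) {
    row <- s1[i, ]
    if (nrow(rep_w) == 0) {
      cz <- conditional_z(row$z_imp, numeric(0), numeric(0), NULL, lambda)
    } else {
      ld <- cond_ld(panel, row$variant_id, rep_w$variant_id)
      cz <- conditional_z(row$z_imp, rep_w$z, ld$c_uS, ld$C_SS, lambda)
    }
    data.frame(variant_id = row$variant_id, chr = row$chr, pos = row$pos,
               z_imp = row$z_imp, p_imp = row$p_imp, z_cond = cz$z_cond,
               p_cond = cz$p_cond, estimable = cz$estimable,
               ld_max = cz$ld_max, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

pick_top <- function(df) {
  ord <- order(df$p_cond, df$pos, df$variant_id)
  df[ord[1], , drop = FALSE]
}

#' Worst-case single-conditioner P-value for a lead variant
#'
#' Conditions the lead variant on each neighbouring variant in turn and
#' returns the maximum (least significant) conditional P-value; a large value
#' means some single neighbour explains the lead signal.
#'
#' @param lead one-row data.frame with `variant_id`, `chr`, `pos`, `z_imp`.
#' @param neighbors data.frame of variants with `variant_id`, `chr`, `pos`,
#'   `z`; only those within `radius_bp` of the lead are used.
#' @param panel a [ref_panel].
#' @param radius_bp neighbourhood radius (default 1 Mb).
#' @param lambda shrinkage intensity.
#' @return list with `p_max`, `worst_neighbor`, and the per-neighbour table.
#' @export
pairwise_conditional <- function(lead, neighbors, panel, radius_bp = 1e6,
                                 lambda = 0.1) {
  nb <- neighbors[neighbors$chr == lead$chr &
                  abs(neighbors$pos - lead$pos) <= radius_bp &
                  neighbors$variant_id != lead$variant_id &
                  neighbors$variant_id %in% panel$info$id, , drop = FALSE]
  if (nrow(nb) == 0)
    return(list(p_max = z_to_p(lead$z_imp), worst_neighbor = NA_character_,
                table = empty_members()[0, 1:7]))
  res <- lapply(seq_len(nrow(nb)), function(i) {
    ld <- cond_ld(panel, lead$variant_id, nb$variant_id[i])
    cz <- conditional_z(lead$z_imp, nb$z[i], ld$c_uS, ld$C_SS, lambda)
    data.frame(neighbor = nb$variant_id[i], z_cond = cz$z_cond,
               p_cond = cz$p_cond, estimable = cz$estimable,
               ld = ld$c_uS^2, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  est <- tab[tab$estimable, , drop = FALSE]
  if (nrow(est) == 0)
    return(list(p_max = NA_real_, worst_neighbor = NA_character_, table = tab))
  i <- which.max(est$p_cond)
  list(p_max = est$p_cond[i], worst_neighbor = est$neighbor[i], table = tab)
}

#' Merge candidate loci in adjacent windows
#'
#' For each pair of loci in neighbouring windows on the same chromosome, the
#' weaker top variant (larger conditional P) is conditioned on the stronger
#' one; if its conditional P-value rises above `p_threshold` the two loci
#' describe the same signal and are merged, retaining the stronger top.
#'
#' @param loci locus table as returned by [locus_scan()].
#' @param panel a [ref_panel].
#' @param imputed imputed results (for the top variants' Z-statistics).
#' @param p_threshold significance threshold.
#' @param lambda shrinkage intensity.
#' @return merged locus table.
#' @export
merge_adjacent_loci <- function(loci, panel, imputed, p_threshold = 1e-8,
                                lambda = 0.1) {
  if (nrow(loci) < 2) return(loci)
  loci <- loci[order(loci$chr, loci$window), , drop = FALSE]
  drop <- rep(FALSE, nrow(loci))
  for (i in seq_len(nrow(loci) - 1)) {
    j <- i + 1
    if (drop[i] || loci$chr[i] != loci$chr[j] ||
        loci$window[j] - loci$window[i] != 1) next
    weak <- if (loci$top_p_cond[i] > loci$top_p_cond[j]) i else j
    strong <- if (weak == i) j else i
    ld <- cond_ld(panel, loci$top_variant[weak], loci$top_variant[strong])
    cz <- conditional_z(loci$top_z_cond[weak], loci$top_z_cond[strong],
                        ld$c_uS, ld$C_SS, lambda)
    if (!cz$estimable || is.na(cz$p_cond) || cz$p_cond > p_threshold)
      drop[weak] <- TRUE
  }
  loci[!drop, , drop = FALSE]
}
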