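# Reading GWAS summary statistics and harmonizing them against a panel.

#' Read GWAS association summary statistics
#'
#' Reads a delimited text file with a header and maps its columns onto the
#' roles the pipeline needs. Either a Z-statistic column or a pair of
#' effect/standard-error columns must be mapped; in the latter case
#' z = beta/se. Rows with non-numeric z (or beta/se) or sample size are
#' dropped with a message. Records are returned sorted by (chromosome,
#' position).
#'
#' @param path delimited text file with a header row.
#' @param column_map named character vector mapping roles to column names.
#'   Mandatory roles: `id`, `chr`, `pos`, `effect_allele`, `other_allele`,
#'   `n`, and either `z` or both `beta` and `se`. Optional: `af`.
#' @param sep field separator (default: auto-detected by fread).
#' @return data.frame with columns `variant_id`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `z`, `n` and optionally `af`.
#' @export
read_sumstats <- function(path, column_map = c(
                            id = "variant_id", chr = "chr", pos = "pos",
                            effect_allele = "effect_allele",
                            other_allele = "other_allele",
                            z = "z", n = "n"),
                          sep = "auto") {
  if (!file.exists(path)) stop("cannot read summary statistics file: ", path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = list(character = unname(
                            column_map[c("chr")])))
  has_z <- "z" %in% names(column_map)
  has_bs <- all(c("beta", "se") %in% names(column_map))
  need <- c("id", "chr", "pos", "effect_allele", "other_allele", "n")
  for (role in need)
    if (!role %in% names(column_map))
      stop("column_map is missing the mandatory role: ", role)
  if (!has_z && !has_bs)
    stop("column_map must provide role 'z' or roles 'beta' and 'se'")
  for (role in names(column_map))
    if (!column_map[[role]] %in% names(dt))
      stop("column '", column_map[[role]], "' (role ", role,
           ") not found in ", path)

  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(
    variant_id = as.character(dt[[column_map[["id"]]]]),
    chr = as.character(dt[[column_map[["chr"]]]]),
    pos = as.integer(num(dt[[column_map[["pos"]]]])),
    effect_allele = toupper(as.character(dt[[column_map[["effect_allele"]]]])),
    other_allele = toupper(as.character(dt[[column_map[["other_allele"]]]])),
    stringsAsFactors = FALSE)
  if (has_z) {
    out$z <- num(dt[[column_map[["z"]]]])
  } else {
    beta <- num(dt[[column_map[["beta"]]]])
    se <- num(dt[[column_map[["se"]]]])
    se[!is.na(se) & se <= 0] <- NA
    out$z <- beta / se
  }
  out$n <- num(dt[[column_map[["n"]]]])
  if ("af" %in% names(column_map)) out$af <- num(dt[[column_map[["af"]]]])

  ok <- is.finite(out$z) & is.finite(out$n) & out$n >= 1 & !is.na(out$pos)
  if (any(!ok))
    message(sum(!ok), " row(s) dropped (non-numeric z or N, or invalid position)")
  out <- out[ok, , drop = FALSE]
  out <- out[order(out$chr, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write imputation output as a tab-separated table
#'
#' @param results data.frame of imputation results.
#' @param path output path.
#' @param header_lines optional character vector of `#`-prefixed provenance
#'   lines written before the table.
#' @export
write_sumstats <- function(results, path, header_lines = NULL) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  close(con)
  data.table::fwrite(results, tmp, sep = "\t", append = !is.null(header_lines),
                     col.names = TRUE, quote = FALSE, na = "NA")
  file.rename(tmp, path)
  invisible(path)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize summary statistics with a reference panel
#'
#' Matches records to panel variants on (chromosome, position) and aligns the
#' effect allele to the panel alt allele: if the summary effect allele equals
#' the panel alt the Z-statistic is kept, if it equals the panel ref the sign
#' is flipped (and any allele frequency complemented). Records whose alleles
#' do not match the panel pair are excluded, as are strand-ambiguous
#' palindromic variants (A/T, C/G) when `drop_palindromic` is set; strand
#' flips are never inferred for them. Duplicated (chr, pos, alleles) rows keep
#' the first occurrence. Exclusions are data, not errors: each input record is
#' either aligned or appears exactly once in the exclusion log.
#'
#' @param records data.frame from [read_sumstats()].
#' @param panel a [ref_panel].
#' @param drop_palindromic drop A/T and C/G variants (default TRUE).
#' @return list with `records` (aligned, effect allele = panel alt) and
#'   `exclusions` (data.frame of `variant_id`, `reason`).
#' @export
harmonize_sumstats <- function(records, panel, drop_palindromic = TRUE) {
  info <- panel$info
  excl <- list()
  note <- function(ids, reason) {
    if (length(ids)) excl[[length(excl) + 1]] <<-
        data.frame(variant_id = ids, reason = reason, stringsAsFactors = FALSE)
  }

  key <- paste(records$chr, records$pos, pmin(records$effect_allele, records$other_allele),
               pmax(records$effect_allele, records$other_allele))
  dup <- duplicated(key)
  note(records$variant_id[dup], "duplicate")
  records <- records[!dup, , drop = FALSE]

  pkey <- paste(info$chr, info$pos)
  m <- match(paste(records$chr, records$pos), pkey)
  note(records$variant_id[is.na(m)], "not_in_panel")
  keep <- !is.na(m)
  records <- records[keep, , drop = FALSE]
  m <- m[keep]

  pal <- is_palindromic(records$effect_allele, records$other_allele)
  if (drop_palindromic) {
    note(records$variant_id[pal], "palindromic")
    records <- records[!pal, , drop = FALSE]
    m <- m[!pal]
  }

  ref <- info$ref[m]; alt <- info$alt[m]
  same <- records$effect_allele == alt & records$other_allele == ref
  flip <- records$effect_allele == ref & records$other_allele == alt
  note(records$variant_id[!(same | flip)], "allele_mismatch")
  keep <- same | flip
  records <- records[keep, , drop = FALSE]
  flip <- flip[keep]

  records$z[flip] <- -records$z[flip]
  if (!is.null(records$af)) records$af[flip] <- 1 - records$af[flip]
  ea <- records$effect_allele
  records$effect_allele[flip] <- records$other_allele[flip]
  records$other_allele[flip] <- ea[flip]
  rownames(records) <- NULL

  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(variant_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  list(records = records, exclusions = exclusions)
}
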