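# Reference panel container and readers (VCF or plain dosage matrix).

#' Construct a reference panel
#'
#' A reference panel is a dosage matrix (individuals x variants, entries in
#' \[0, 2\], `NA` allowed) together with per-variant metadata. All LD estimates
#' in the package are computed from such a panel.
#'
#' @param dosage numeric matrix, n individuals x m variants.
#' @param info data.frame with columns `id`, `chr`, `pos`, `ref`, `alt` and
#'   optionally `af` (alt-allele frequency; computed from the dosages when
#'   absent).
#' @return object of class `ref_panel` with elements `dosage`, `info`, `n`.
#' @export
ref_panel <- function(dosage, info) {
  dosage <- as.matrix(dosage)
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  if (ncol(dosage) != nrow(info))
    stop("dosage column count (", ncol(dosage),
         ") does not match metadata rows (", nrow(info), ")")
  need <- c("id", "chr", "pos", "ref", "alt")
  miss <- setdiff(need, names(info))
  if (length(miss)) stop("panel metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  info$pos <- as.integer(info$pos)
  if (is.null(info$af)) info$af <- unname(colMeans(dosage, na.rm = TRUE) / 2)
  colnames(dosage) <- info$id
  structure(list(dosage = dosage, info = info, n = nrow(dosage)),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat("ref_panel:", x$n, "individuals x", ncol(x$dosage), "variants\n")
  if (ncol(x$dosage))
    cat("  chr", paste(unique(x$info$chr), collapse = ","),
        " pos", min(x$info$pos), "-", max(x$info$pos), "\n")
  invisible(x)
}

#' Subset a panel to a genomic region or variant set
#'
#' @param panel a [ref_panel].
#' @param chr chromosome (optional).
#' @param start,end 1-based inclusive start, half-open end of the bp interval.
#' @param ids variant ids to keep (applied after the region filter).
#' @return a [ref_panel]; `n` is preserved even when no variant matches.
#' @export
panel_region <- function(panel, chr = NULL, start = NULL, end = NULL,
                         ids = NULL) {
  keep <- rep(TRUE, ncol(panel$dosage))
  if (!is.null(chr)) keep <- keep & panel$info$chr == chr
  if (!is.null(start)) keep <- keep & panel$info$pos >= start
  if (!is.null(end)) keep <- keep & panel$info$pos < end
  if (!is.null(ids)) keep <- keep & panel$info$id %in% ids
  out <- ref_panel(panel$dosage[, keep, drop = FALSE],
                   panel$info[keep, , drop = FALSE])
  out$n <- panel$n
  out
}

#' Read a reference panel
#'
#' Two on-disk layouts are supported: VCF 4.x (genotypes from the `GT` or `DS`
#' FORMAT field, via vcfR) and a plain-text layout consisting of a dosage
#' matrix (one individual per row, one variant per column, tab-separated,
#' header = variant ids, `NA` for missing) with a sidecar metadata table
#' `<path>.info` (columns `id`, `chr`, `pos`, `ref`, `alt`).
#'
#' @param path file path; files ending in `.vcf` / `.vcf.gz` are parsed as VCF.
#' @param chr,start,end optional region restriction (half-open bp interval).
#' @param multiallelic `"skip"` (default) drops multi-allelic VCF sites.
#' @return a [ref_panel].
#' @export
read_panel <- function(path, chr = NULL, start = NULL, end = NULL,
                       multiallelic = c("skip")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("cannot read panel file: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    panel <- read_panel_vcf(path)
  } else {
    panel <- read_panel_matrix(path)
  }
  panel_region(panel, chr = chr, start = start, end = end)
}

read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- !grepl(",", fix$ALT, fixed = TRUE)
  gt_field <- if ("DS" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) "DS" else "GT"
  if (gt_field == "DS") {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    dosage <- t(ds)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")  # variants x samples
    cnt <- matrix(NA_real_, nrow(gt), ncol(gt))
    ok <- !is.na(gt) & !grepl(".", gt, fixed = TRUE)
    # count alt alleles; any missing allele ('.') makes the genotype missing
    cnt[ok] <- vapply(strsplit(gt[ok], "[/|]"),
                      function(a) sum(a == "1"), numeric(1))
    dosage <- t(cnt)
  }
  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(id) | id == "."]
  info <- data.frame(id = id, chr = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  ref_panel(dosage[, keep, drop = FALSE], info[keep, , drop = FALSE])
}

read_panel_matrix <- function(path) {
  info_path <- paste0(path, ".info")
  if (!file.exists(info_path))
    stop("plain-matrix panel requires a sidecar metadata file: ", info_path)
  dosage <- as.matrix(data.table::fread(path, sep = "\t", header = TRUE))
  info <- as.data.frame(data.table::fread(info_path, sep = "\t", header = TRUE))
  ref_panel(dosage, info)
}

#' Write a panel in the plain-matrix layout
#'
#' @param panel a [ref_panel].
#' @param path output path; the metadata table is written to `<path>.info`.
#' @export
write_panel <- function(panel, path) {
  data.table::fwrite(as.data.frame(panel$dosage), path, sep = "\t", na = "NA",
                     quote = FALSE)
  data.table::fwrite(panel$info, paste0(path, ".info"), sep = "\t",
                     quote = FALSE)
  invisible(path)
}
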