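# Fixture builders shared across tests; everything is generated in code.

# A small deterministic panel: two LD blocks on chr 1.
toy_panel <- function(n = 800, seed = 11) {
  simulate_genotypes(n, data.frame(size = c(5, 5), maf = c(0.3, 0.2),
                                   r = c(0.8, 0.7)),
                     chr = "1", pos_start = 1e5, spacing = 1e4, seed = seed)
}

# Summary records perfectly aligned to a panel (effect allele = panel alt).
toy_records <- function(panel, z = NULL, n = 1000) {
  m <- ncol(panel$dosage)
  data.frame(variant_id = panel$info$id, chr = panel$info$chr,
             pos = panel$info$pos, effect_allele = panel$info$alt,
             other_allele = panel$info$ref,
             z = z %||% seq(-2, 2, length.out = m),
             n = rep(n, m), stringsAsFactors = FALSE)
}

write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  path
}

# Minimal VCF with GT genotypes, written as text.
write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1\t1|1",
    "1\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t./.\t0/0",
    "1\t400\trs4\tT\tC,G\t.\tPASS\t.\tGT\t0/1\t0/0")
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
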