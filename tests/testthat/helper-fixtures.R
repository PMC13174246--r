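# Small in-code fixtures shared across test files.

toy_genomat <- function(codes, chrom = "1", pos = NULL) {
  codes <- as.matrix(codes)
  if (is.null(pos)) pos <- seq_len(ncol(codes)) * 10L
  genotype_matrix(codes, data.frame(chrom = chrom, pos = pos))
}

random_genomat <- function(n, p, miss_rate = 0, chrom = "1") {
  codes <- matrix(sample(1:3, n * p, replace = TRUE), n, p)
  if (miss_rate > 0)
    codes[sample(length(codes), round(miss_rate * length(codes)))] <- 0L
  toy_genomat(codes, chrom = chrom)
}

random_position_set <- function(n, chroms = c("1", "2")) {
  position_set(sample(chroms, n, replace = TRUE),
               sample.int(1000L, n, replace = TRUE))
}

# minimal VCF written to a temp file; returns the path
write_test_vcf <- function(records, samples = c("s1", "s2"),
                           path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_rec <- function(chrom, pos, ref, alt, gts, id = ".") {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# tiny fast training configuration for orchestration tests
tiny_cfg <- function(window = 24L, ...) {
  network_config(window = window, max_epochs = 2L, batch = 16L,
                 knn_k = 2L, seed = 7L, ...)
}

pos_keys_test <- function(ps) paste(ps$chrom, ps$pos, sep = ":")
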