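#' Read genotypes from a VCF file
#'
#' Parses the GT field of a VCF (phased or unphased; phase is discarded)
#' into an integer-coded [genotype_matrix()]. Only biallelic SNP records
#' are used; multi-allelic or non-SNP records are skipped with a warning.
#' GT "0/0" maps to code 1, "0/1"/"1/0" (either separator) to 2, "1/1" to
#' 3, and any genotype containing a missing allele to 0.
#'
#' @param path VCF file path (plain text or gzipped).
#' @param chrom_filter optional single chromosome label; only its records
#'   are returned.
#' @return a `genomat` in file marker order (validated sorted by position).
#' @export
read_vcf <- function(path, chrom_filter = NULL) {
  if (!file.exists(path)) stop("cannot read VCF file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no records in VCF: ", path)
  if (!is.null(chrom_filter)) {
    sel <- fix$CHROM == as.character(chrom_filter)
    if (!any(sel)) stop("no records on chromosome ", chrom_filter)
    v <- v[sel, ]
    fix <- fix[sel, , drop = FALSE]
  }
  bases <- c("A", "C", "G", "T")
  bial <- fix$REF %in% bases & fix$ALT %in% bases
  if (!all(bial)) {
    warning(sum(!bial), " non-biallelic-SNP record(s) skipped")
    if (!any(bial)) stop("no biallelic SNP records in VCF: ", path)
    v <- v[bial, ]
    fix <- fix[bial, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  codes <- gt_to_codes(gt) # markers x samples
  markers <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                        id = fix$ID, ref = fix$REF, alt = fix$ALT,
                        stringsAsFactors = FALSE)
  bad_id <- is.na(markers$id) | markers$id == "."
  markers$id[bad_id] <- paste0(markers$chrom[bad_id], "_", markers$pos[bad_id])
  dup <- duplicated(paste(markers$chrom, markers$pos, sep = ":"))
  if (any(dup)) {
    warning(sum(dup), " duplicate (chrom,pos) record(s) dropped (first kept)")
    markers <- markers[!dup, , drop = FALSE]
    codes <- codes[!dup, , drop = FALSE]
  }
  check_sorted_markers(markers) # errors on unsorted positions
  genotype_matrix(t(codes), markers, sample_ids = colnames(gt))
}

gt_to_codes <- function(gt) {
  g <- gsub("|", "/", as.character(gt), fixed = TRUE)
  code <- integer(length(g))
  code[g %in% "0/0"] <- 1L
  code[g %in% c("0/1", "1/0")] <- 2L
  code[g %in% "1/1"] <- 3L
  # anything containing a missing allele (".", "./.", NA) stays 0
  matrix(code, nrow = nrow(gt), ncol = ncol(gt))
}

#' Read genotypes from a CSV/TXT table (marker-rows dialect)
#'
#' Reads a delimited table with markers as rows. Metadata columns (at
#' least chromosome and position) come first; the column header
#' immediately preceding the genotype block must be `ref`, `alt` or
#' `QCcode` (case-insensitive) — all columns after the last such sentinel
#' are sample columns holding integer codes 0/1/2/3. Comma and tab
#' delimiters are auto-detected.
#'
#' @param path file path.
#' @return a `genomat`.
#' @export
read_csv_genotypes <- function(path) {
  if (!file.exists(path)) stop("cannot read genotype table: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  low <- tolower(names(dt))
  sent <- which(low %in% c("ref", "alt", "qccode"))
  if (!length(sent))
    stop("no sentinel column header (ref, alt or QCcode) found")
  first_sample <- max(sent) + 1L
  if (first_sample > ncol(dt)) stop("no sample columns after the sentinel")
  ccol <- which(low %in% c("chrom", "chr", "#chrom", "chromosome"))[1]
  pcol <- which(low %in% c("pos", "position"))[1]
  if (is.na(ccol) || is.na(pcol))
    stop("chromosome and position columns are required")
  samp <- names(dt)[first_sample:ncol(dt)]
  raw <- as.matrix(dt[, samp, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  if (any(is.na(num)) || any(!num %in% 0:3))
    stop("genotype cells must be integer codes in {0,1,2,3}")
  markers <- data.frame(chrom = dt[[ccol]], pos = as.integer(dt[[pcol]]),
                        stringsAsFactors = FALSE)
  idc <- which(low %in% c("id", "rs", "marker", "snp"))[1]
  if (!is.na(idc)) markers$id <- dt[[idc]]
  rfc <- which(low == "ref")[1]; alc <- which(low == "alt")[1]
  if (!is.na(rfc)) markers$ref <- ifelse(dt[[rfc]] == "", NA, dt[[rfc]])
  if (!is.na(alc)) markers$alt <- ifelse(dt[[alc]] == "", NA, dt[[alc]])
  genotype_matrix(t(num), markers, sample_ids = samp)
}

#' Write a fully imputed genotype matrix as an integer-coded table
#'
#' Writes markers as rows with chrom/pos/id/ref/alt metadata followed by
#' one integer column per sample. The matrix must be complete (no code 0):
#' imputation output carries no missing genotypes. Re-reading the file with
#' [read_csv_genotypes()] reproduces the input.
#'
#' @param g a complete [genotype_matrix()].
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return invisibly, `path`.
#' @export
write_integer_genotypes <- function(g, path, sep = ",") {
  stopifnot(inherits(g, "genomat"))
  if (any(g$codes == 0L))
    stop("genotype matrix still contains missing codes (0); ",
         "only fully imputed matrices can be written")
  out <- cbind(g$markers, as.data.frame(t(g$codes)))
  names(out) <- c(names(g$markers), g$sample_ids)
  data.table::fwrite(out, path, sep = sep, quote = FALSE, na = "")
  invisible(path)
}

#' Read a marker position file
#'
#' Accepts a two-column chrom/pos text file (with or without header), any
#' delimited table containing chromosome and position columns, or a
#' genotype file (VCF or the CSV dialect): any file carrying chromosome
#' and position information can serve as a position file.
#'
#' @param path file path.
#' @return a [position_set()].
#' @export
read_positions <- function(path) {
  if (!file.exists(path)) stop("cannot read position file: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF") || grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    return(position_set(as.character(v@fix[, "CHROM"]),
                        as.integer(v@fix[, "POS"])))
  }
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  low <- tolower(names(dt))
  ccol <- which(low %in% c("chrom", "chr", "#chrom", "chromosome"))[1]
  pcol <- which(low %in% c("pos", "position"))[1]
  if (is.na(ccol) || is.na(pcol)) {
    if (ncol(dt) < 2L) stop("position file needs chromosome and position columns")
    dt <- data.table::fread(path, header = FALSE, data.table = FALSE)
    ccol <- 1L; pcol <- 2L
  }
  position_set(as.character(dt[[ccol]]), as.integer(dt[[pcol]]))
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with GT-only records (unphased), used for writing
#' simulated reference panels. Missing codes are written as `./.`.
#'
#' @param g a [genotype_matrix()] with ref/alt alleles set.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genomat"))
  m <- g$markers
  ref <- ifelse(is.na(m$ref), "A", m$ref)
  alt <- ifelse(is.na(m$alt), "G", m$alt)
  gt_str <- c("./.", "0/0", "0/1", "1/1")[g$codes + 1L] # samples x markers
  gt <- matrix(gt_str, nrow(g$codes), ncol(g$codes))
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$sample_ids), collapse = "\t"))
  body <- paste(m$chrom, m$pos, m$id, ref, alt, ".", "PASS", ".", "GT",
                sep = "\t")
  body <- paste(body, apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}
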