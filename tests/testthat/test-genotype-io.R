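test_that("one-hot encoding round-trips all codes and flags missing", {
  g <- toy_genomat(matrix(c(0L, 1L, 2L, 3L, 3L, 0L), 2, 3))
  oh <- encode_onehot(g)
  expect_equal(dim(oh), c(2L, 3L, 3L))
  # 0 -> [0,0,0], 1 -> [1,0,0], 2 -> [0,1,0], 3 -> [0,0,1]
  expect_equal(oh[1, 1, ], c(0, 0, 0))
  expect_equal(oh[2, 1, ], c(1, 0, 0))
  expect_equal(oh[1, 2, ], c(0, 1, 0))
  expect_equal(oh[2, 2, ], c(0, 0, 1))
  expect_equal(decode_onehot(oh), g$codes, ignore_attr = TRUE)
  # channel sums are 0 only at missing entries
  sums <- apply(oh, c(1, 2), sum)
  expect_equal(sums == 0, g$codes == 0L, ignore_attr = TRUE)
  expect_error(encode_onehot(matrix(4L, 1, 1)), "out of range")
})

test_that("genotype_matrix validates codes and marker order", {
  expect_error(toy_genomat(matrix(5L, 1, 1)), "codes")
  expect_error(genotype_matrix(matrix(1L, 1, 2),
                               data.frame(chrom = "1", pos = c(20L, 10L))),
               "increasing")
  expect_error(genotype_matrix(matrix(1L, 1, 1),
                               data.frame(chrom = "1", pos = 5L,
                                          ref = "A", alt = "A")),
               "differ")
})

test_that("VCF genotypes map to codes with phase discarded", {
  path <- write_test_vcf(c(
    vcf_rec("1", 100, "A", "G", c("0/0", "0|1")),
    vcf_rec("1", 200, "C", "T", c("1|0", "1/1")),
    vcf_rec("1", 300, "G", "A", c("./.", ".")),
    vcf_rec("1", 400, "T", "TA", c("0/0", "0/0")), # indel: skipped
    vcf_rec("1", 500, "G", "A,C", c("0/0", "0/0")) # multi-allelic: skipped
  ))
  expect_warning(g <- read_vcf(path), "skipped")
  expect_equal(n_markers(g), 3L)
  expect_equal(g$codes[, 1], c(s1 = 1L, s2 = 2L)) # hom-ref / het (phased)
  expect_equal(g$codes[, 2], c(s1 = 2L, s2 = 3L)) # het either order / hom-alt
  expect_equal(g$codes[, 3], c(s1 = 0L, s2 = 0L)) # missing
  expect_equal(g$markers$ref, c("A", "C", "G"))
})

test_that("VCF reading enforces order, uniqueness and chromosome filter", {
  path <- write_test_vcf(c(
    vcf_rec("1", 100, "A", "G", c("0/0", "0/0")),
    vcf_rec("1", 100, "A", "G", c("1/1", "1/1")), # duplicate key
    vcf_rec("2", 50, "C", "T", c("0/1", "0/0"))
  ))
  expect_warning(g <- read_vcf(path), "duplicate")
  expect_equal(n_markers(g), 2L)
  expect_equal(g$codes[1, ], c(`1_100` = 1L, `2_50` = 2L))
  g2 <- suppressWarnings(read_vcf(path, chrom_filter = "2"))
  expect_equal(n_markers(g2), 1L)
  bad <- write_test_vcf(c(
    vcf_rec("1", 200, "A", "G", c("0/0", "0/0")),
    vcf_rec("1", 100, "C", "T", c("0/0", "0/0"))
  ))
  expect_error(read_vcf(bad), "increasing")
  expect_error(read_vcf(tempfile()), "cannot read")
})

test_that("CSV dialect parses via the ref/alt/QCcode sentinel", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("chrom,pos,extra,ref,alt,S1,S2,S3",
               "chr1,1234,x,A,G,1,3,2",
               "chr1,2000,y,C,T,2,2,0"), path)
  g <- read_csv_genotypes(path)
  expect_equal(g$sample_ids, c("S1", "S2", "S3"))
  expect_equal(unname(g$codes[, 1]), c(1L, 3L, 2L))
  expect_equal(g$markers$chrom[1], "chr1")
  expect_equal(g$markers$pos[1], 1234L)
  expect_equal(g$markers$ref, c("A", "C"))

  # QCcode sentinel, tab-delimited, two samples detected
  path2 <- tempfile(fileext = ".txt")
  writeLines(c("chrom\tpos\tQCcode\tS1\tS2",
               "1\t10\tok\t1\t2",
               "1\t20\tok\t3\t3"), path2)
  g2 <- read_csv_genotypes(path2)
  expect_equal(n_samples(g2), 2L)

  writeLines(c("chrom,pos,S1", "1,10,1"), path)
  expect_error(read_csv_genotypes(path), "sentinel")
  writeLines(c("chrom,pos,ref,alt", "1,10,A,G"), path)
  expect_error(read_csv_genotypes(path), "sample")
  writeLines(c("chrom,pos,ref,alt,S1", "1,10,A,G,7"), path)
  expect_error(read_csv_genotypes(path), "codes")
})

test_that("integer genotype tables round-trip and refuse missing codes", {
  set.seed(1)
  g <- random_genomat(3, 5)
  g$markers$ref <- c("A", "C", "G", "T", "A")
  g$markers$alt <- c("G", "T", "A", "C", "T")
  g <- genotype_matrix(g$codes, g$markers, g$sample_ids)
  path <- tempfile(fileext = ".csv")
  write_integer_genotypes(g, path)
  g2 <- read_csv_genotypes(path)
  expect_equal(g2$codes, g$codes, ignore_attr = TRUE)
  expect_equal(g2$markers, g$markers)
  one <- toy_genomat(matrix(2L, 1, 1))
  write_integer_genotypes(one, path)
  expect_length(readLines(path), 2L) # header + 1 data row
  gm <- toy_genomat(matrix(c(1L, 0L), 1, 2))
  expect_error(write_integer_genotypes(gm, path), "missing")
})

test_that("minimal VCF writing round-trips through read_vcf", {
  set.seed(2)
  g <- random_genomat(4, 6)
  g$markers$ref <- rep("A", 6); g$markers$alt <- rep("G", 6)
  g <- genotype_matrix(g$codes, g$markers, g$sample_ids)
  path <- tempfile(fileext = ".vcf")
  write_vcf(g, path)
  g2 <- read_vcf(path)
  expect_equal(g2$codes, g$codes, ignore_attr = TRUE)
})

test_that("position files accept two-column, tabular and genotype formats", {
  p1 <- tempfile()
  writeLines(c("chrom\tpos", "1\t100", "1\t200", "2\t50"), p1)
  ps <- read_positions(p1)
  expect_equal(nrow(ps), 3L)
  p2 <- tempfile()
  writeLines(c("1 100", "2 50"), p2) # headerless two-column
  expect_equal(nrow(read_positions(p2)), 2L)
  vp <- write_test_vcf(vcf_rec("3", 77, "A", "C", c("0/0", "0/0")))
  psv <- read_positions(vp)
  expect_equal(psv$chrom, "3")
  expect_equal(psv$pos, 77L)
})

test_that("marker-set algebra follows set semantics on (chrom,pos) keys", {
  a <- position_set(c("1", "1"), c(5L, 9L))
  b <- position_set(c("1", "2"), c(9L, 3L))
  expect_equal(nrow(marker_set_op(a, b, "union")), 3L)
  expect_equal(nrow(marker_set_op(a, b, "intersection")), 1L)
  expect_equal(marker_set_op(a, a, "intersection"), a) # idempotence
  empty <- position_set(character(0), integer(0))
  expect_equal(nrow(marker_set_op(a, empty, "intersection")), 0L)
  # inclusion-exclusion on random sets
  set.seed(42)
  for (i in 1:20) {
    x <- random_position_set(30)
    y <- random_position_set(30)
    expect_equal(nrow(marker_set_op(x, y, "union")) +
                   nrow(marker_set_op(x, y, "intersection")),
                 nrow(x) + nrow(y))
  }
})

test_that("panel subsetting intersects loci and drops allele mismatches", {
  set.seed(3)
  panel <- random_genomat(4, 10)
  panel$markers$ref <- rep("A", 10); panel$markers$alt <- rep("G", 10)
  panel <- genotype_matrix(panel$codes, panel$markers, panel$sample_ids)
  # identity subset
  sub <- subset_panel(panel, position_set(panel))
  expect_equal(sub$codes, panel$codes, ignore_attr = TRUE)
  # plain position targets: pure intersection
  tgt <- position_set(panel$markers[c(2, 5, 9), ])
  sub2 <- subset_panel(panel, tgt)
  expect_equal(marker_keys(sub2), pos_keys_test(tgt))
  # swapped alleles are dropped, not flipped
  tgt_g <- subset_markers(panel, c(2, 5, 9))
  tgt_g$markers$ref[2] <- "G"; tgt_g$markers$alt[2] <- "A"
  tgt_g <- genotype_matrix(tgt_g$codes, tgt_g$markers, tgt_g$sample_ids)
  expect_warning(sub3 <- subset_panel(panel, tgt_g), "mismatch")
  expect_equal(n_markers(sub3), 2L)
  expect_equal(attr(sub3, "n_allele_dropped"), 1L)
  # missing codes forbidden in the panel
  bad <- toy_genomat(matrix(c(1L, 0L), 1, 2))
  expect_error(subset_panel(bad, position_set(bad)), "not permitted")
  expect_error(subset_panel(panel, position_set("9", 1L)), "intersect")
})


test_that("chromosome segmentation partitions markers in order", {
  set.seed(4)
  g <- random_genomat(2, 2500)
  segs <- segment_chromosome(g, 1000)
  expect_equal(vapply(segs, n_markers, 0L), c(1000L, 1000L, 500L))
  expect_equal(do.call(cbind, lapply(segs, function(s) s$codes)), g$codes,
               ignore_attr = TRUE)
  expect_length(segment_chromosome(g, 5000), 1L)
})
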