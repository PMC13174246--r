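test_that("window plans cover chromosomes with a reverse terminal window", {
  w <- plan_windows(2500, 1000)
  expect_equal(w$train_start, c(0L, 1000L, 1500L))
  expect_equal(w$train_end, c(1000L, 2000L, 2500L))
  expect_equal(w$impute_start, c(0L, 1000L, 2000L))
  expect_equal(w$impute_end, c(1000L, 2000L, 2500L))
  expect_equal(w$reverse, c(FALSE, FALSE, TRUE))
  # exact multiple: no reverse window
  w2 <- plan_windows(1000, 1000)
  expect_equal(nrow(w2), 1L)
  expect_false(any(w2$reverse))
  # short chromosome: single covering window
  w3 <- plan_windows(700, 1000)
  expect_equal(c(w3$train_start, w3$train_end), c(0L, 700L))
  expect_error(plan_windows(0, 10))
})

test_that("impute spans always partition the marker range", {
  set.seed(20)
  for (i in 1:25) {
    p <- sample.int(5000, 1)
    w <- sample.int(1500, 1)
    plan <- plan_windows(p, w)
    covered <- unlist(lapply(seq_len(nrow(plan)), function(i)
      seq(plan$impute_start[i], plan$impute_end[i] - 1L)))
    expect_equal(sort(covered), 0:(p - 1))
    # training spans are full width (or the whole chromosome)
    expect_true(all(plan$train_end - plan$train_start == min(p, w)))
  }
})

test_that("general imputation completes the target on shared loci only", {
  set.seed(21)
  panel <- simulate_panel(n_samples = 30, n_markers = 60, seed = 22)
  pops <- derive_populations(panel, n_pop1 = 8, n_pop2 = 2, size_a = 50,
                             size_b = 50, n_overlap = 50, seed = 23)
  truth <- pops$pop1
  masked <- mask_genotypes(truth, 0.3, "sporadic", seed = 24)
  target <- masked$masked
  res <- general_impute(target, panel, tiny_cfg())
  expect_s3_class(res, "impute_result")
  # complete output, observed entries untouched
  expect_false(any(res$genotypes$codes == 0L))
  obs <- target$codes != 0L
  expect_equal(res$genotypes$codes[obs], target$codes[obs])
  expect_equal(res$provenance, target$codes == 0L, ignore_attr = TRUE)
  # concordance against held-out truth is computable and bounded
  cr <- genotype_cr(res$genotypes$codes, truth$codes, masked$mask)
  expect_true(cr >= 0 && cr <= 1)
  # target with no missingness comes back as-is (no training happens)
  res0 <- general_impute(truth, panel, tiny_cfg())
  expect_equal(res0$genotypes$codes, truth$codes, ignore_attr = TRUE)
  expect_equal(res0$report$n_windows, 0L)
})

test_that("general imputation drops target loci absent from the panel", {
  set.seed(25)
  panel <- simulate_panel(n_samples = 20, n_markers = 30, seed = 26)
  target <- subset_samples(panel, 1:3)
  extra <- data.frame(chrom = "1", pos = max(panel$markers$pos) + 10L,
                      id = "xx", ref = "A", alt = "G")
  tg <- genotype_matrix(cbind(target$codes, 1L),
                        rbind(target$markers, extra), target$sample_ids)
  tg$codes[1, 5] <- 0L
  tg <- genotype_matrix(tg$codes, tg$markers, tg$sample_ids)
  expect_message(res <- general_impute(tg, panel, tiny_cfg()), "dropped")
  expect_equal(n_markers(res$genotypes), 30L)
  expect_equal(res$report$n_dropped_target_loci, 1L)
})

test_that("reconstructive output lands exactly on (A | B) & P", {
  set.seed(27)
  panel <- simulate_panel(n_samples = 25, n_markers = 50, seed = 28)
  pops <- derive_populations(panel, n_pop1 = 6, n_pop2 = 6, size_a = 25,
                             size_b = 25, n_overlap = 5, seed = 29)
  res <- reconstructive_impute(pops$pop1, position_set(pops$pop2), panel,
                               tiny_cfg())
  keys_a <- marker_keys(pops$pop1)
  keys_b <- marker_keys(pops$pop2)
  keys_p <- marker_keys(panel)
  expect_setequal(marker_keys(res$genotypes),
                  intersect(union(keys_a, keys_b), keys_p))
  expect_false(any(res$genotypes$codes == 0L))
  expect_equal(res$genotypes$sample_ids, pops$pop1$sample_ids)
  # loci already genotyped in population I pass through unchanged
  ma <- match(keys_a, marker_keys(res$genotypes))
  expect_equal(res$genotypes$codes[, ma], pops$pop1$codes, ignore_attr = TRUE)
})

test_that("guide positions inside A reduce to general imputation on A & P", {
  set.seed(30)
  panel <- simulate_panel(n_samples = 20, n_markers = 40, seed = 31)
  pops <- derive_populations(panel, n_pop1 = 5, n_pop2 = 2, size_a = 30,
                             size_b = 30, n_overlap = 30, seed = 32)
  pop1 <- pops$pop1
  guide <- position_set(pop1$markers[1:10, ]) # B subset of A
  res <- reconstructive_impute(pop1, guide, panel, tiny_cfg())
  expect_setequal(marker_keys(res$genotypes),
                  intersect(marker_keys(pop1), marker_keys(panel)))
})

test_that("disjoint chips append exactly |B & P| systematic columns", {
  set.seed(33)
  panel <- simulate_panel(n_samples = 25, n_markers = 40, seed = 34)
  pops <- derive_populations(panel, n_pop1 = 6, n_pop2 = 6, size_a = 18,
                             size_b = 18, n_overlap = 0, seed = 35)
  res <- reconstructive_impute(pops$pop1, position_set(pops$pop2), panel,
                               tiny_cfg())
  # pop1 is complete on A, so imputed entries are exactly the appended B & P
  # columns for every sample
  q <- length(intersect(marker_keys(pops$pop2), marker_keys(panel)))
  expect_equal(res$report$n_imputed, q * n_samples(pops$pop1))
  expect_equal(sum(res$provenance), q * 6L)
})

test_that("two-way imputation yields one shared marker set, independently", {
  set.seed(36)
  panel <- simulate_panel(n_samples = 20, n_markers = 40, seed = 37)
  pops <- derive_populations(panel, n_pop1 = 5, n_pop2 = 4, size_a = 20,
                             size_b = 20, n_overlap = 6, seed = 38)
  both <- two_way_impute(pops$pop1, pops$pop2, panel, tiny_cfg())
  expect_identical(marker_keys(both$pop1$genotypes),
                   marker_keys(both$pop2$genotypes))
  # each direction equals its standalone one-way run (independence)
  solo <- reconstructive_impute(pops$pop1, pops$pop2, panel, tiny_cfg())
  expect_identical(both$pop1$genotypes$codes, solo$genotypes$codes)
  # identical populations reduce to A & P
  same <- two_way_impute(pops$pop1, pops$pop1, panel, tiny_cfg())
  expect_setequal(marker_keys(same$pop1$genotypes),
                  intersect(marker_keys(pops$pop1), marker_keys(panel)))
})

test_that("imputation results are reproducible under a fixed seed", {
  set.seed(39)
  panel <- simulate_panel(n_samples = 20, n_markers = 30, seed = 40)
  pops <- derive_populations(panel, n_pop1 = 4, n_pop2 = 2, size_a = 25,
                             size_b = 25, n_overlap = 25, seed = 41)
  tg <- mask_genotypes(pops$pop1, 0.2, "sporadic", seed = 42)$masked
  r1 <- general_impute(tg, panel, tiny_cfg())
  r2 <- general_impute(tg, panel, tiny_cfg())
  expect_identical(r1$genotypes$codes, r2$genotypes$codes)
})

test_that("windowed runs split imputation across window boundaries", {
  set.seed(43)
  panel <- simulate_panel(n_samples = 25, n_markers = 55, seed = 44)
  pops <- derive_populations(panel, n_pop1 = 5, n_pop2 = 2, size_a = 55,
                             size_b = 55, n_overlap = 55, seed = 45)
  tg <- mask_genotypes(pops$pop1, 0.3, "sporadic", seed = 46)$masked
  res <- general_impute(tg, panel, tiny_cfg(window = 20L))
  # 55 markers, window 20: two forward + one reverse terminal window
  expect_equal(res$report$n_windows, 3L)
  expect_false(any(res$genotypes$codes == 0L))
  obs <- tg$codes != 0L
  expect_equal(res$genotypes$codes[obs], tg$codes[obs])
})
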