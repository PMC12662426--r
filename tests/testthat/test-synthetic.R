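test_that("tripleSpec validates its parameters", {
  expect_s4_class(tripleSpec(), "TripleSpec")
  expect_error(tripleSpec(n_exp = 0), "sample sizes")
  expect_error(tripleSpec(pleiotropy_mode = "wild"), "pleiotropyMode")
  expect_error(tripleSpec(pleiotropy_fraction = 1.2), "pleiotropyFraction")
  expect_error(tripleSpec(palindromic_rate = -0.1), "palindromicRate")
  expect_error(tripleSpec(gamma_sd = 0), "effect scales")
})

test_that("simulateTriple is deterministic given spec and seed", {
  s1 <- simulateTriple(tripleSpec(seed = 5))
  s2 <- simulateTriple(tripleSpec(seed = 5))
  expect_identical(assocData(s1@exposure), assocData(s2@exposure))
  expect_identical(assocData(s1@outcome), assocData(s2@outcome))
  s3 <- simulateTriple(tripleSpec(seed = 6))
  expect_false(identical(assocData(s1@exposure)$beta,
                         assocData(s3@exposure)$beta))
  # shared variant universe and per-trait sample sizes
  expect_identical(variantIds(s1@exposure), variantIds(s1@mediator))
  expect_identical(variantIds(s1@exposure), variantIds(s1@outcome))
  expect_equal(unique(assocData(s1@exposure)$n), 3757)
  expect_equal(unique(assocData(s1@outcome)$n), 34652)
})

test_that("simulated standard errors follow the allele-frequency model", {
  sim <- simulateTriple(tripleSpec(seed = 2))
  d <- assocData(sim@mediator)
  expect_equal(d$se, 1 / sqrt(2 * 8299 * d$eaf * (1 - d$eaf)),
               tolerance = 1e-12)
})

test_that("empirical beta dispersion matches the generative scale", {
  # huge sample sizes make measurement noise negligible, exposing the
  # half-normal true-effect scale sd = gamma_sd * sqrt(1 - 2/pi)
  spec <- tripleSpec(n_snps_x = 600L, n_snps_m = 10L, n_snps_null = 0L,
                     gamma_sd = 0.2, n_exp = 1e8, seed = 8)
  sim <- simulateTriple(spec)
  betas <- assocData(sim@exposure)$beta[1:600]
  expect_equal(sd(betas), 0.2 * sqrt(1 - 2 / pi), tolerance = 0.1)
})

test_that("palindromic injection is exercised by harmonization", {
  spec <- tripleSpec(n_snps_x = 300L, n_snps_m = 10L, n_snps_null = 0L,
                     palindromic_rate = 0.3, seed = 9)
  sim <- simulateTriple(spec)
  h <- harmonize(sim@exposure, sim@outcome)
  dropped <- droppedCounts(h)
  expect_gt(dropped[["palindromic"]], 0)
  expect_equal(dropped[["incompatible"]], 0)
  expect_equal(nVariants(h) + sum(dropped), 310L)
  # rate roughly honoured (binomial, n = 310)
  expect_gt(dropped[["palindromic"]] / 310, 0.18)
  expect_lt(dropped[["palindromic"]] / 310, 0.42)
})

test_that("Egger intercepts center on zero without pleiotropy and IVW is the more biased under directional pleiotropy", {
  n_reps <- 200
  intercepts <- numeric(n_reps)
  bias_ivw <- bias_egger <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    h0 <- simulateHarmonized(50, alpha = 0.2, seed = 6000 + r)
    intercepts[r] <- mrEgger(h0)@intercept
    hd <- simulateHarmonized(50, alpha = 0.2,
                             pleiotropy_mode = "directional",
                             pleiotropy_scale = 0.05, seed = 6000 + r)
    bias_ivw[r] <- mrIVW(hd)@beta - 0.2
    bias_egger[r] <- mrEgger(hd)@beta - 0.2
  }
  mcse <- sd(intercepts) / sqrt(n_reps)
  expect_lt(abs(mean(intercepts)), 2 * mcse + 1e-4)
  # directional pleiotropy under InSIDE: IVW picks up the shift, the Egger
  # slope much less so
  expect_gt(mean(bias_ivw), 0.02)
  expect_lt(abs(mean(bias_egger)), abs(mean(bias_ivw)))
})

test_that("LD blocks share effects and are emitted as a pair list", {
  spec <- tripleSpec(n_snps_x = 20L, n_snps_m = 5L, n_snps_null = 0L,
                     ld_blocks = list(n_blocks = 3, block_size = 4,
                                      r2 = 0.8), seed = 4)
  sim <- simulateTriple(spec)
  expect_s4_class(sim@ld, "LDPairList")
  expect_equal(nrow(sim@ld@pairs), 3 * choose(4, 2))
  expect_equal(ldR2(sim@ld, "rs000001", "rs000002"), 0.8)
  expect_equal(ldR2(sim@ld, "rs000001", "rs000005"), 0)  # across blocks
  # clumping on the emitted LD keeps one SNP per block
  strong <- pvalueFilter(sim@exposure, 1)
  clumped <- greedyClump(strong, sim@ld, r2_max = 0.001, window_kb = 10000)
  kept_block <- (as.integer(sub("rs", "", variantIds(clumped))) - 1L) %/% 4L
  kept_in_blocks <- kept_block[kept_block < 3]
  expect_equal(anyDuplicated(kept_in_blocks), 0L)
})

test_that("simulatePanel labels truth and produces an all-null panel when asked", {
  pan <- simulatePanel(5, tripleSpec(n_snps_x = 20L), causal_indices = c(2, 4),
                       seed = 21)
  expect_length(pan$exposures, 5L)
  expect_equal(pan$truth$causal, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(pan$truth$alpha, c(0, 0.5, 0, 0.5, 0))
  expect_s4_class(pan$outcome, "AssociationSet")
  # same truth labels, fresh betas under a shifted seed
  pan2 <- simulatePanel(5, tripleSpec(n_snps_x = 20L),
                        causal_indices = c(2, 4), seed = 22)
  expect_equal(pan2$truth, pan$truth)
  expect_false(identical(assocData(pan2$outcome)$beta,
                         assocData(pan$outcome)$beta))
  null_pan <- simulatePanel(3, tripleSpec(n_snps_x = 20L), seed = 23)
  expect_true(all(!null_pan$truth$causal))
  expect_true(all(null_pan$truth$alpha == 0))
})

test_that("writeTriple emits the readable dialect plus truth and LD files", {
  dir <- tempfile()
  spec <- tripleSpec(n_snps_x = 10L, n_snps_m = 5L, n_snps_null = 5L,
                     ld_blocks = list(n_blocks = 2, block_size = 3, r2 = 0.9),
                     seed = 3)
  writeTriple(simulateTriple(spec), dir)
  expect_setequal(list.files(dir), c("exposure.tsv", "mediator.tsv",
                                     "outcome.tsv", "truth.tsv", "ld.tsv"))
  back <- readSummary(file.path(dir, "exposure.tsv"), "X", quiet = TRUE)
  expect_equal(nVariants(back), 20L)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(as.numeric(truth$value[truth$parameter == "b1"]), 0.3)
})
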