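test_that("pvalueFilter applies a strict threshold", {
  a <- makeAssoc(data.frame(variant_id = c("rs1", "rs2", "rs3"),
                            pval = c(1e-6, 1e-5, 1e-4)))
  kept <- pvalueFilter(a, 1e-5)
  expect_equal(variantIds(kept), "rs1")  # 1e-5 itself is excluded
  expect_equal(nVariants(pvalueFilter(a, 1)), 3L)
  empty <- pvalueFilter(a, 1e-10)
  expect_equal(nVariants(pvalueFilter(empty, 0.5)), 0L)
  expect_error(pvalueFilter(a, 0), "threshold")
})

test_that("fStatistic is beta^2 / se^2", {
  expect_equal(fStatistic(0.1, 0.02), 25)
  expect_equal(fStatistic(0, 0.02), 0)
  expect_equal(fStatistic(0.1, 0.1), 1)
  expect_equal(fStatistic(c(0.1, 0.2), c(0.02, 0.02)), c(25, 100))
  expect_error(fStatistic(0.1, 0), "se")
})

test_that("filterWeak discards F < 10 strictly and keeps the audit trail", {
  # F values 25, 9.9..., 10 exactly
  a <- makeAssoc(data.frame(variant_id = c("rs1", "rs2", "rs3"),
                            beta = c(0.5, sqrt(9.9) * 0.1, sqrt(10) * 0.1),
                            se = 0.1))
  iv <- filterWeak(a, 10)
  expect_equal(variantIds(iv), c("rs1", "rs3"))  # boundary F = 10 is kept
  expect_equal(unname(fStatistics(iv)), c(25, 10))
  expect_equal(unname(auditCounts(iv)["n_after_f"]), 2L)

  all_weak <- makeAssoc(data.frame(variant_id = c("rs1", "rs2"),
                                   beta = 0.01, se = 0.1))
  iv2 <- filterWeak(all_weak, 10)
  expect_length(variantIds(iv2), 0L)
  expect_equal(unname(auditCounts(iv2)["n_after_f"]), 0L)
})

test_that("greedy clumping keeps the best SNP and prunes linked neighbours", {
  a <- makeAssoc(data.frame(variant_id = c("rs1", "rs2", "rs3"),
                            chrom = "1", pos = c(1e6, 1.5e6, 2e6),
                            pval = c(1e-8, 1e-7, 1e-6)))
  r2 <- diag(3)
  r2[1, 2] <- r2[2, 1] <- 0.5
  ld <- ldMatrix(c("rs1", "rs2", "rs3"), r2)
  kept <- greedyClump(a, ld, r2_max = 0.001, window_kb = 10000)
  expect_setequal(variantIds(kept), c("rs1", "rs3"))

  # no LD: everything survives; single SNP is trivially kept
  expect_equal(nVariants(greedyClump(a, ldMatrix(variantIds(a)))), 3L)
  expect_equal(nVariants(greedyClump(a[1], ld)), 1L)
})

test_that("clumping honours the genomic window and chromosome boundaries", {
  a <- makeAssoc(data.frame(variant_id = c("rs1", "rs2", "rs3"),
                            chrom = c("1", "1", "2"),
                            pos = c(1e6, 1e6 + 2e7, 1e6),
                            pval = c(1e-8, 1e-7, 1e-6)))
  r2 <- matrix(1, 3, 3)  # perfect LD between everything, if in range
  ld <- ldMatrix(variantIds(a), r2)
  kept <- greedyClump(a, ld, r2_max = 0.001, window_kb = 10000)
  # rs2 is 20 Mb away (> 10,000 kb) and rs3 is on another chromosome
  expect_setequal(variantIds(kept), c("rs1", "rs2", "rs3"))
  kept2 <- greedyClump(a, ld, r2_max = 0.001, window_kb = 30000)
  expect_setequal(variantIds(kept2), c("rs1", "rs3"))
})

test_that("SNPs unknown to the LD source are treated as unlinked", {
  a <- makeAssoc(data.frame(variant_id = c("rs1", "rs2"),
                            chrom = "1", pos = c(1e6, 1.1e6),
                            pval = c(1e-8, 1e-7)))
  ld <- ldMatrix("rs1")  # rs2 absent
  expect_message(kept <- greedyClump(a, ld, quiet = FALSE), "absent")
  expect_equal(nVariants(kept), 2L)
})

test_that("clumping is order-invariant and maximal", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 15
    ids <- sprintf("rs%d", 1:n)
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    # random sparse LD
    for (k in 1:10) {
      ij <- sample.int(n, 2)
      m[ij[1], ij[2]] <- m[ij[2], ij[1]] <- runif(1)
    }
    diag(m) <- 1
    ld <- ldMatrix(ids, m)
    a <- makeAssoc(data.frame(variant_id = ids, chrom = "1",
                              pos = seq(1e6, by = 1e5, length.out = n),
                              pval = 10^-runif(n, 4, 9)))
    kept <- variantIds(greedyClump(a, ld))
    # order invariance
    perm <- a[sample.int(n)]
    expect_setequal(variantIds(greedyClump(perm, ld)), kept)
    # no retained pair is in LD above threshold
    for (x in kept) {
      r2s <- ldR2(ld, x, setdiff(kept, x))
      expect_true(all(r2s < 0.001))
    }
    # maximality: every discarded SNP conflicts with some retained SNP
    for (x in setdiff(ids, kept)) {
      expect_true(any(ldR2(ld, x, kept) >= 0.001))
    }
  }
})

test_that("selectInstruments composes p-screen, clump, and F filter in order", {
  a <- makeAssoc(data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4"),
    chrom = "1", pos = c(1e6, 1.2e6, 2e6, 3e6),
    beta = c(0.5, 0.4, 0.02, 0.5), se = c(0.1, 0.1, 0.004, 0.1),
    pval = c(1e-8, 1e-7, 1e-6, 1e-3)))
  r2 <- diag(4); r2[1, 2] <- r2[2, 1] <- 0.9
  ld <- ldMatrix(variantIds(a), r2)
  iv <- selectInstruments(a, ld)
  # rs4 fails p; rs2 clumped against rs1; rs3 (F = 25) survives
  expect_equal(variantIds(iv), c("rs1", "rs3"))
  expect_equal(unname(auditCounts(iv)),
               c(4L, 3L, 2L, 2L))
  expect_equal(names(auditCounts(iv)),
               c("n_input", "n_after_pvalue", "n_after_clump", "n_after_f"))
})

test_that("LD pair lists round-trip through files", {
  pairs <- data.frame(id_a = c("rs1", "rs2"), id_b = c("rs2", "rs3"),
                      r2 = c(0.5, 0.002))
  path <- tempfile()
  write.table(pairs, path, row.names = FALSE, quote = FALSE)
  ld <- readLDPairs(path)
  expect_s4_class(ld, "LDPairList")
  expect_equal(ldR2(ld, "rs1", c("rs1", "rs2", "rs3")), c(1, 0.5, 0))
  expect_equal(ldR2(ld, "rs3", "rs2"), 0.002)  # symmetric lookup
  # headerless variant
  writeLines(c("rs1 rs2 0.5"), path)
  expect_equal(ldR2(readLDPairs(path), "rs2", "rs1"), 0.5)
})

test_that("instrument sets export with an audit sidecar", {
  a <- makeAssoc(data.frame(variant_id = c("rs1", "rs2"), beta = 0.5,
                            se = 0.1))
  iv <- filterWeak(a, 10, audit = c(n_input = 2L))
  path <- tempfile(fileext = ".tsv")
  writeInstruments(iv, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".log")))
  expect_equal(read.delim(path)$variant_id, c("rs1", "rs2"))
})
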