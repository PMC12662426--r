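test_that("readSummary round-trips a valid table and enforces invariants", {
  tsv <- tempfile(fileext = ".tsv")
  df <- data.frame(variant_id = c("rs1", "rs2", "rs3"),
                   effect_allele = c("A", "C", "G"),
                   other_allele = c("G", "T", "A"),
                   beta = c(0.1, -0.2, 0.05), se = c(0.01, 0.02, 0.01),
                   pval = c(1e-8, 1e-6, 0.5))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  a <- readSummary(tsv, "T1", quiet = TRUE)
  expect_s4_class(a, "AssociationSet")
  expect_equal(nVariants(a), 3L)
  expect_equal(assocData(a)$beta, df$beta)

  # invalid rows dropped with a message: se = 0, pval out of range
  df2 <- rbind(df, data.frame(variant_id = c("rs4", "rs5"),
                              effect_allele = "A", other_allele = "G",
                              beta = 0.1, se = c(0, 0.01),
                              pval = c(1e-4, 2)))
  write.table(df2, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(a2 <- readSummary(tsv, "T1"), "2 invalid")
  expect_equal(variantIds(a2), c("rs1", "rs2", "rs3"))
})

test_that("duplicate variant ids keep the first occurrence", {
  tsv <- tempfile(fileext = ".tsv")
  df <- data.frame(variant_id = c("rs1", "rs1"),
                   effect_allele = c("A", "A"), other_allele = c("G", "G"),
                   beta = c(0.1, 0.9), se = 0.01, pval = 1e-8)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(a <- readSummary(tsv, "T1"), "1 duplicate")
  expect_equal(nVariants(a), 1L)
  expect_equal(assocData(a)$beta, 0.1)
})

test_that("readSummary reports format problems", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines("", tsv)
  expect_error(readSummary(tsv, "T1"), "empty")
  write.table(data.frame(variant_id = "rs1", beta = 0.1), tsv, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readSummary(tsv, "T1"), "missing required column")
  expect_error(readSummary(tempfile(), "T1"), "not found")
})

test_that("comma-separated input and the gwascatalog dialect are understood", {
  csv <- tempfile(fileext = ".csv")
  df <- data.frame(variant_id = "rs1", chromosome = "1",
                   base_pair_location = 1000, effect_allele = "a",
                   other_allele = "g", beta = 0.1, standard_error = 0.01,
                   p_value = 1e-8, effect_allele_frequency = 0.3, n = 100)
  write.table(df, csv, sep = ",", quote = FALSE, row.names = FALSE)
  a <- readSummary(csv, "T1", column_map = gwasDialect("gwascatalog"),
                   quiet = TRUE)
  d <- assocData(a)
  expect_equal(d$pos, 1000)
  expect_equal(d$effect_allele, "A")  # uppercased
  expect_equal(d$eaf, 0.3)
})

test_that("palindromic allele pairs are recognized", {
  expect_true(isPalindromic("A", "T"))
  expect_true(isPalindromic("C", "G"))
  expect_true(isPalindromic("G", "C"))
  expect_false(isPalindromic("A", "G"))
  expect_false(isPalindromic("AT", "A"))   # indels are never palindromic
  expect_equal(isPalindromic(c("a", "t"), c("t", "c")), c(TRUE, FALSE))
})

test_that("harmonize re-orients, removes palindromic SNPs, and counts drops", {
  ex <- makeAssoc(data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    effect_allele = c("A", "A", "A", "C", "A"),
    other_allele  = c("G", "G", "T", "A", "G"),
    beta = c(0.10, 0.20, 0.30, 0.15, 0.25)))
  ou <- makeAssoc(data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    effect_allele = c("G", "A", "A", "C", "C"),
    other_allele  = c("A", "G", "T", "A", "T"),
    beta = c(-0.05, 0.07, 0.40, 0.02, 0.09)), trait_id = "OUT",
    trait_type = "outcome-disease")
  h <- harmonize(ex, ou)
  d <- harmonizedData(h)
  # rs1: swapped alleles -> sign flip; rs2: identical coding passes through
  expect_equal(d$Gamma[d$variant_id == "rs1"], 0.05)
  expect_equal(d$Gamma[d$variant_id == "rs2"], 0.07)
  # rs3 palindromic (A/T) removed; rs5 incompatible (A/G vs C/T is a strand
  # flip: C->G, T->A means swapped -> sign flip, so actually compatible)
  expect_false("rs3" %in% d$variant_id)
  expect_equal(d$Gamma[d$variant_id == "rs5"], -0.09)
  expect_equal(unname(droppedCounts(h)["palindromic"]), 1L)
  # rs4 exposure alleles C/A vs outcome C/A identical
  expect_equal(d$Gamma[d$variant_id == "rs4"], 0.02)
  expect_equal(nrow(d) + sum(droppedCounts(h)), 5L)
})

test_that("irreconcilable allele pairs are dropped and counted", {
  ex <- makeAssoc(data.frame(variant_id = "rs1", effect_allele = "A",
                             other_allele = "G"))
  ou <- makeAssoc(data.frame(variant_id = "rs1", effect_allele = "A",
                             other_allele = "C"), trait_id = "OUT",
                  trait_type = "outcome-disease")
  expect_error(harmonize(ex, ou), NA)
  h <- harmonize(ex, ou)
  expect_equal(nVariants(h), 0L)
  expect_equal(unname(droppedCounts(h)["incompatible"]), 1L)
})

test_that("harmonize rejects empty input and empty intersections", {
  ex <- makeAssoc(data.frame(variant_id = "rs1"))
  ou <- makeAssoc(data.frame(variant_id = "rs2"), trait_id = "OUT")
  expect_error(harmonize(ex, ou), "no shared variants")
})

test_that("harmonization is idempotent and orientation-invariant", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 20
    pairs <- rbind(c("A", "G"), c("C", "T"), c("A", "T"), c("G", "C"),
                   c("T", "G"))
    pick <- pairs[sample.int(nrow(pairs), n, replace = TRUE), , drop = FALSE]
    ids <- sprintf("rs%d", 1:n)
    ex <- makeAssoc(data.frame(variant_id = ids,
                               effect_allele = pick[, 1],
                               other_allele = pick[, 2],
                               beta = rnorm(n, 0, 0.1)))
    # outcome: randomly swap allele order (beta sign follows the coding)
    swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
    ob <- rnorm(n, 0, 0.05)
    ou <- makeAssoc(data.frame(variant_id = ids,
                               effect_allele = ifelse(swap, pick[, 2], pick[, 1]),
                               other_allele = ifelse(swap, pick[, 1], pick[, 2]),
                               beta = ifelse(swap, -ob, ob)),
                    trait_id = "OUT", trait_type = "outcome-disease")
    h <- harmonize(ex, ou)
    d <- harmonizedData(h)

    # conservation: kept + dropped = intersection size
    expect_equal(nrow(d) + sum(droppedCounts(h)), n)

    # orientation invariance: flipping outcome coding changes nothing
    oa <- assocData(ou)
    flipped <- oa
    flipped$effect_allele <- oa$other_allele
    flipped$other_allele <- oa$effect_allele
    flipped$beta <- -oa$beta
    ou2 <- AssociationSet("OUT", "outcome-disease", flipped, quiet = TRUE)
    expect_identical(harmonizedData(harmonize(ex, ou2)), d)

    # idempotence: re-harmonizing the aligned pair is the identity
    if (nrow(d)) {
      ex_kept <- ex[d$variant_id]
      aligned <- assocData(ex_kept)
      aligned$beta <- d$Gamma
      aligned$se <- d$se_Gamma
      ou3 <- AssociationSet("OUT", "outcome-disease", aligned, quiet = TRUE)
      h2 <- harmonize(ex_kept, ou3)
      expect_identical(harmonizedData(h2), d)
    }
  }
})

test_that("harmonized sets serialize with the documented column names", {
  h <- makeHarm(c(0.1, 0.2), c(0.01, 0.01), c(0.02, 0.05), c(0.01, 0.01))
  path <- tempfile(fileext = ".tsv")
  writeHarmonized(h, path)
  back <- read.delim(path)
  expect_named(back, c("SNP", "gamma", "se_gamma", "Gamma", "se_Gamma",
                       "pval_exposure"))
  expect_equal(back$Gamma, c(0.02, 0.05))
})
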