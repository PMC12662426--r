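#' Column-name presets for GWAS summary-statistics files
#'
#' A column map is a named character vector translating the canonical field
#' names used throughout the package (\code{variant_id, chrom, pos,
#' effect_allele, other_allele, beta, se, pval, eaf, n}) to the header names
#' of a particular file dialect.  Two presets are bundled: \code{"plain"}
#' (headers already canonical) and \code{"gwascatalog"}, matching the common
#' GWAS-catalog summary-statistics export headers.
#'
#' @param preset dialect name.
#' @return named character vector, canonical name -> file header.
#' @examples
#' gwasDialect("gwascatalog")[["pval"]]
#' @export
gwasDialect <- function(preset = c("plain", "gwascatalog")) {
  preset <- match.arg(preset)
  switch(preset,
    plain = c(variant_id = "variant_id", chrom = "chrom", pos = "pos",
              effect_allele = "effect_allele", other_allele = "other_allele",
              beta = "beta", se = "se", pval = "pval", eaf = "eaf", n = "n"),
    gwascatalog = c(variant_id = "variant_id", chrom = "chromosome",
                    pos = "base_pair_location",
                    effect_allele = "effect_allele",
                    other_allele = "other_allele", beta = "beta",
                    se = "standard_error", pval = "p_value",
                    eaf = "effect_allele_frequency", n = "n"))
}

#' Construct an AssociationSet from a data.frame
#'
#' Validating constructor.  Columns beyond the canonical set are dropped;
#' missing optional columns (\code{chrom, pos, eaf, n}) are filled with NA.
#' Rows violating the record invariants (non-positive SE, p-value outside
#' \eqn{[0,1]}, identical alleles, non-finite beta) and duplicated variant ids
#' (first occurrence wins) are removed with a message, mirroring
#' [readSummary()].
#'
#' @param trait_id accession or label.
#' @param trait_type one of \code{"exposure-immune"},
#'   \code{"mediator-metabolite"}, \code{"outcome-disease"}.
#' @param assoc data.frame of per-variant records.
#' @param quiet suppress the dropped-row message.
#' @return an [AssociationSet].
#' @export
AssociationSet <- function(trait_id, trait_type, assoc, quiet = FALSE) {
  a <- .canonicalAssoc(assoc)
  keep <- is.finite(a$beta) & is.finite(a$se) & a$se > 0 &
    is.finite(a$pval) & a$pval >= 0 & a$pval <= 1 &
    nzchar(a$effect_allele) & nzchar(a$other_allele) &
    a$effect_allele != a$other_allele & !is.na(a$variant_id)
  n_invalid <- sum(!keep)
  a <- a[keep, , drop = FALSE]
  dup <- duplicated(a$variant_id)
  n_dup <- sum(dup)
  a <- a[!dup, , drop = FALSE]
  rownames(a) <- NULL
  if (!quiet && (n_invalid || n_dup))
    .msgf("%s: dropped %d invalid record(s) and %d duplicate variant id(s)",
          trait_id, n_invalid, n_dup)
  new("AssociationSet", traitId = trait_id, traitType = trait_type, assoc = a)
}

.canonicalAssoc <- function(df) {
  stopifnot(is.data.frame(df))
  for (col in c("chrom", "pos", "eaf", "n"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se",
                "pval")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    .stopf("missing required column(s): %s",
           paste(missing_cols, collapse = ", "))
  out <- data.frame(
    variant_id = as.character(df$variant_id),
    chrom = as.character(df$chrom),
    pos = suppressWarnings(as.numeric(df$pos)),
    effect_allele = toupper(as.character(df$effect_allele)),
    other_allele = toupper(as.character(df$other_allele)),
    beta = suppressWarnings(as.numeric(df$beta)),
    se = suppressWarnings(as.numeric(df$se)),
    pval = suppressWarnings(as.numeric(df$pval)),
    eaf = suppressWarnings(as.numeric(df$eaf)),
    n = suppressWarnings(as.numeric(df$n)),
    stringsAsFactors = FALSE)
  # frequencies outside [0,1] are unusable but not fatal: record as missing
  bad_eaf <- !is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1)
  out$eaf[bad_eaf] <- NA_real_
  out
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-separated summary-association table with a header
#' row into an [AssociationSet].  The delimiter is auto-detected from the
#' header line unless given.  Rows failing the record invariants are dropped
#' and counted; duplicated variant ids keep the first occurrence.
#'
#' @param path file path.
#' @param trait_id accession or label attached to the set (defaults to the
#'   file name without extension).
#' @param trait_type trait role, see [AssociationSet()].
#' @param column_map named character vector mapping canonical field names to
#'   file headers; see [gwasDialect()].
#' @param sep field separator; NULL to auto-detect tab vs comma.
#' @param quiet suppress dropped-row messages.
#' @return an [AssociationSet].
#' @export
readSummary <- function(path, trait_id = NULL,
                        trait_type = "exposure-immune",
                        column_map = gwasDialect("plain"), sep = NULL,
                        quiet = FALSE) {
  if (!file.exists(path)) .stopf("summary file not found: %s", path)
  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header))
    .stopf("empty summary file: %s", path)
  if (is.null(sep)) sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "\"")
  if (!nrow(df)) .stopf("summary file has a header but no records: %s", path)
  present <- column_map[column_map %in% names(df)]
  df2 <- df[, unname(present), drop = FALSE]
  names(df2) <- names(present)
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se",
                "pval")
  missing_cols <- setdiff(required, names(df2))
  if (length(missing_cols))
    .stopf("%s: missing required column(s): %s (after applying column map)",
           path, paste(missing_cols, collapse = ", "))
  if (is.null(trait_id))
    trait_id <- sub("\\.[^.]*$", "", basename(path))
  AssociationSet(trait_id, trait_type, df2, quiet = quiet)
}

#' Write an AssociationSet as tab-separated text
#'
#' Writes the canonical columns in the \code{"plain"} dialect, which
#' [readSummary()] reads back verbatim.
#'
#' @param object an [AssociationSet].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSummary <- function(object, path) {
  stopifnot(is(object, "AssociationSet"))
  utils::write.table(assocData(object), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Is an allele pair palindromic?
#'
#' A SNP is palindromic when its two alleles are base complements ({A,T} or
#' {C,G}): the strand cannot be resolved from the alleles alone, so such SNPs
#' are removed during harmonization.  Indel (multi-base) alleles are never
#' palindromic under this definition.
#'
#' @param effect_allele,other_allele character vectors of alleles.
#' @return logical vector.
#' @examples
#' isPalindromic(c("A", "A", "C"), c("T", "G", "G"))
#' @export
isPalindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele)
  oa <- toupper(other_allele)
  comp <- .compAllele(ea)
  !is.na(comp) & !is.na(oa) & comp == oa
}

#' Harmonize exposure and outcome associations onto one allele orientation
#'
#' Intersects the two sets on \code{variant_id} and re-expresses each outcome
#' effect for the exposure's effect allele.  Outcome records coded on the
#' swapped allele pair have their beta sign flipped; strand flips are
#' reconciled via base complement before a pair is declared incompatible.
#' Palindromic SNPs are removed unconditionally (no frequency-based rescue),
#' as are SNPs whose allele pairs cannot be reconciled; both counts are
#' recorded on the result.
#'
#' @param exposure,outcome [AssociationSet] objects.
#' @return a [HarmonizedSet] with per-SNP \code{gamma}/\code{se_gamma}
#'   (exposure), \code{Gamma}/\code{se_Gamma} (outcome, re-oriented) and
#'   \code{pval_exposure}.
#' @examples
#' ex <- AssociationSet("X", "exposure-immune", data.frame(
#'   variant_id = "rs1", effect_allele = "A", other_allele = "G",
#'   beta = 0.1, se = 0.01, pval = 1e-8))
#' ou <- AssociationSet("Y", "outcome-disease", data.frame(
#'   variant_id = "rs1", effect_allele = "G", other_allele = "A",
#'   beta = -0.05, se = 0.02, pval = 0.01))
#' harmonizedData(harmonize(ex, ou))$Gamma  # +0.05 after the sign flip
#' @export
harmonize <- function(exposure, outcome) {
  stopifnot(is(exposure, "AssociationSet"), is(outcome, "AssociationSet"))
  if (!nVariants(exposure) || !nVariants(outcome))
    .stopf("cannot harmonize empty association sets")
  ex <- assocData(exposure)
  ou <- assocData(outcome)
  shared <- intersect(ex$variant_id, ou$variant_id)
  if (!length(shared))
    .stopf("no shared variants between %s and %s",
           traitId(exposure), traitId(outcome))
  ex <- ex[match(shared, ex$variant_id), , drop = FALSE]
  ou <- ou[match(shared, ou$variant_id), , drop = FALSE]

  pal <- isPalindromic(ex$effect_allele, ex$other_allele) |
    isPalindromic(ou$effect_allele, ou$other_allele)

  cea <- .compAllele(ou$effect_allele)
  coa <- .compAllele(ou$other_allele)
  same <- ou$effect_allele == ex$effect_allele &
    ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele &
    ou$other_allele == ex$effect_allele
  flip_same <- !is.na(cea) & !is.na(coa) &
    cea == ex$effect_allele & coa == ex$other_allele
  flip_swapped <- !is.na(cea) & !is.na(coa) &
    cea == ex$other_allele & coa == ex$effect_allele

  sgn <- rep(NA_real_, length(shared))
  sgn[same | flip_same] <- 1
  sgn[swapped | flip_swapped] <- -1

  incompatible <- is.na(sgn) & !pal
  keep <- !pal & !is.na(sgn)

  d <- data.frame(variant_id = shared[keep],
                  gamma = ex$beta[keep],
                  se_gamma = ex$se[keep],
                  Gamma = sgn[keep] * ou$beta[keep],
                  se_Gamma = ou$se[keep],
                  pval_exposure = ex$pval[keep],
                  stringsAsFactors = FALSE)
  rownames(d) <- NULL
  new("HarmonizedSet",
      exposureId = traitId(exposure), outcomeId = traitId(outcome),
      data = d,
      nDroppedPalindromic = as.integer(sum(pal)),
      nDroppedIncompatible = as.integer(sum(incompatible)))
}

#' Write a HarmonizedSet as tab-separated text
#'
#' Columns: SNP, gamma, se_gamma, Gamma, se_Gamma, pval_exposure.
#'
#' @param object a [HarmonizedSet].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeHarmonized <- function(object, path) {
  stopifnot(is(object, "HarmonizedSet"))
  d <- harmonizedData(object)
  names(d)[names(d) == "variant_id"] <- "SNP"
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
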