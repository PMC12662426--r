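#' Dense LD matrix source
#'
#' @param ids variant ids.
#' @param r2 symmetric matrix of pairwise r-squared (diagonal 1); if NULL an
#'   identity matrix (linkage equilibrium) is used.
#' @return an [LDMatrix].
#' @export
ldMatrix <- function(ids, r2 = NULL) {
  if (is.null(r2)) {
    r2 <- diag(length(ids))
  }
  dimnames(r2) <- list(ids, ids)
  new("LDMatrix", ids = as.character(ids), r2 = r2)
}

#' Sparse LD pair-list source
#'
#' @param pairs data.frame with columns \code{id_a, id_b, r2}; unlisted pairs
#'   are treated as r-squared 0.
#' @return an [LDPairList].
#' @export
ldPairList <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  new("LDPairList", pairs = pairs)
}

#' Read an LD pair list from a whitespace-delimited file
#'
#' Expected format: three columns \code{id_a id_b r2}, no header required (a
#' header line naming the columns is also accepted).
#'
#' @param path file path.
#' @return an [LDPairList].
#' @export
readLDPairs <- function(path) {
  if (!file.exists(path)) .stopf("LD pair file not found: %s", path)
  first <- strsplit(trimws(readLines(path, n = 1L)), "\\s+")[[1]]
  has_header <- length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L])))
  df <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) .stopf("LD pair file needs 3 columns: id_a id_b r2")
  names(df)[1:3] <- c("id_a", "id_b", "r2")
  ldPairList(df[, 1:3])
}

#' @rdname ldR2
#' @export
setMethod("ldR2", "LDMatrix", function(source, id, ids) {
  out <- numeric(length(ids))
  i <- match(id, source@ids)
  if (is.na(i)) { out[ids == id] <- 1; return(out) }
  j <- match(ids, source@ids)
  known <- !is.na(j)
  out[known] <- source@r2[i, j[known]]
  out[!known & ids == id] <- 1
  out
})

#' @rdname ldR2
#' @export
setMethod("ldR2", "LDPairList", function(source, id, ids) {
  out <- numeric(length(ids))
  out[ids == id] <- 1
  p <- source@pairs
  hit_a <- p$id_a == id
  hit_b <- p$id_b == id
  if (any(hit_a)) {
    m <- match(ids, p$id_b[hit_a])
    out[!is.na(m)] <- pmax(out[!is.na(m)], p$r2[hit_a][m[!is.na(m)]])
  }
  if (any(hit_b)) {
    m <- match(ids, p$id_a[hit_b])
    out[!is.na(m)] <- pmax(out[!is.na(m)], p$r2[hit_b][m[!is.na(m)]])
  }
  out
})

#' P-value screen for instrument candidates
#'
#' Retains records with exposure p-value strictly below the threshold
#' (default \eqn{1 \times 10^{-5}}).
#'
#' @param assoc an [AssociationSet].
#' @param threshold p-value threshold in (0, 1]; strict inequality.
#' @return the filtered [AssociationSet] (possibly empty).
#' @export
pvalueFilter <- function(assoc, threshold = 1e-5) {
  stopifnot(is(assoc, "AssociationSet"))
  if (!(threshold > 0 && threshold <= 1))
    .stopf("p-value threshold must lie in (0, 1]")
  a <- assocData(assoc)
  assoc[which(a$pval < threshold)]
}

#' Greedy LD clumping by p-value
#'
#' Sorts candidates by ascending p-value (ties broken by position, then
#' variant id, so the result is independent of input order), then iteratively
#' keeps the best remaining SNP and discards every remaining SNP with
#' r-squared at or above \code{r2_max} within \code{window_kb} of it.  SNPs on
#' different chromosomes, or farther apart than the window, are never
#' discarded against each other.  SNPs unknown to the LD source are treated as
#' independent of everything (r-squared 0) and counted in a message.
#'
#' @param assoc an [AssociationSet].
#' @param ld an [LDSource]; NULL means complete linkage equilibrium.
#' @param r2_max r-squared clumping threshold (discard at >= this value).
#' @param window_kb window half-width in kilobases.
#' @param quiet suppress the unknown-SNP message.
#' @return the clumped [AssociationSet].
#' @export
greedyClump <- function(assoc, ld = NULL, r2_max = 0.001, window_kb = 10000,
                        quiet = FALSE) {
  stopifnot(is(assoc, "AssociationSet"))
  a <- assocData(assoc)
  if (nrow(a) <= 1L || is.null(ld)) return(assoc)
  stopifnot(is(ld, "LDSource"))
  known_ids <- if (is(ld, "LDMatrix")) ld@ids
               else unique(c(ld@pairs$id_a, ld@pairs$id_b))
  n_unknown <- sum(!a$variant_id %in% known_ids)
  if (n_unknown && !quiet)
    .msgf("%s: %d SNP(s) absent from the LD source treated as unlinked",
          traitId(assoc), n_unknown)

  ord <- order(a$pval, a$pos, a$variant_id, na.last = TRUE)
  a <- a[ord, , drop = FALSE]
  active <- rep(TRUE, nrow(a))
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    if (!active[i]) next
    keep[i] <- TRUE
    active[i] <- FALSE
    rest <- which(active)
    if (!length(rest)) break
    r2 <- ldR2(ld, a$variant_id[i], a$variant_id[rest])
    in_window <- rep(TRUE, length(rest))
    if (!is.na(a$chrom[i]) && !is.na(a$pos[i])) {
      same_chr <- !is.na(a$chrom[rest]) & a$chrom[rest] == a$chrom[i]
      dist_ok <- !is.na(a$pos[rest]) &
        abs(a$pos[rest] - a$pos[i]) <= window_kb * 1000
      in_window <- same_chr & dist_ok
    }
    active[rest[r2 >= r2_max & in_window]] <- FALSE
  }
  assoc[a$variant_id[keep]]
}

#' Instrument-strength F statistic
#'
#' \eqn{F = \beta^2 / SE^2}, computed from the instrument's association with
#' the exposure.
#'
#' @param beta,se per-allele effect and standard error on the exposure.
#' @return numeric vector of F statistics.
#' @examples
#' fStatistic(0.1, 0.02)  # 25
#' @export
fStatistic <- function(beta, se) {
  if (any(!is.finite(se) | se <= 0)) .stopf("se must be finite and > 0")
  beta^2 / se^2
}

#' Weak-instrument filter
#'
#' Discards SNPs with \eqn{F < f_{min}} (strict: F exactly at the threshold is
#' retained) and returns an [InstrumentSet] carrying per-SNP F statistics and
#' audit counts.
#'
#' @param assoc an [AssociationSet] (typically already p-screened and clumped).
#' @param f_min minimum F statistic (default 10).
#' @param audit optional named integer vector of upstream stage counts to
#'   carry through into the result's audit trail.
#' @return an [InstrumentSet].
#' @export
filterWeak <- function(assoc, f_min = 10, audit = NULL) {
  stopifnot(is(assoc, "AssociationSet"))
  a <- assocData(assoc)
  f <- if (nrow(a)) fStatistic(a$beta, a$se) else numeric(0)
  keep <- f >= f_min
  ids <- a$variant_id[keep]
  fs <- f[keep]
  names(fs) <- ids
  counts <- c(audit, c(n_after_f = as.integer(sum(keep))))
  storage.mode(counts) <- "integer"
  new("InstrumentSet", variantIds = ids, fStat = fs, audit = counts)
}

#' Full instrument selection: p-screen, LD clump, F filter
#'
#' Applies the three filters in order: strict p-value screen
#' (\code{p_threshold}), greedy LD clumping (\code{r2_max} within
#' \code{window_kb}), and the weak-instrument F filter (\code{f_min}), and
#' records the SNP count surviving each stage.
#'
#' @param assoc an [AssociationSet] of exposure associations.
#' @param ld an [LDSource] or NULL (no LD information; clumping keeps all).
#' @param p_threshold instrument p-value threshold (strict <).
#' @param r2_max clumping r-squared threshold (discard at >=).
#' @param window_kb clumping window, kb.
#' @param f_min minimum F statistic.
#' @param quiet suppress messages.
#' @return an [InstrumentSet] with audit counts
#'   \code{n_input, n_after_pvalue, n_after_clump, n_after_f}.
#' @export
selectInstruments <- function(assoc, ld = NULL, p_threshold = 1e-5,
                              r2_max = 0.001, window_kb = 10000, f_min = 10,
                              quiet = TRUE) {
  stopifnot(is(assoc, "AssociationSet"))
  n0 <- nVariants(assoc)
  sig <- pvalueFilter(assoc, p_threshold)
  clumped <- greedyClump(sig, ld, r2_max = r2_max, window_kb = window_kb,
                         quiet = quiet)
  filterWeak(clumped, f_min = f_min,
             audit = c(n_input = n0,
                       n_after_pvalue = nVariants(sig),
                       n_after_clump = nVariants(clumped)))
}

#' Write an InstrumentSet as tab-separated text
#'
#' Writes a two-column TSV (variant_id, F) plus a sidecar \code{<path>.log}
#' with the per-stage audit counts.
#'
#' @param object an [InstrumentSet].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeInstruments <- function(object, path) {
  stopifnot(is(object, "InstrumentSet"))
  utils::write.table(
    data.frame(variant_id = variantIds(object), F = unname(fStatistics(object))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  audit <- auditCounts(object)
  writeLines(sprintf("%s\t%d", names(audit), audit), paste0(path, ".log"))
  invisible(path)
}
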