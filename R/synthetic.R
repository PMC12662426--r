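#' Specify a synthetic three-trait causal system
#'
#' Defines the stated world of the simulator: an immune-cell-like exposure
#' (small GWAS, n = 3757), a plasma-metabolite-like mediator (n = 8299) and a
#' binary disease outcome (n = 34652), with true total effect
#' \code{alpha_total}, mediated path \code{b1 * b2} and direct effect
#' \code{alpha_total - b1 * b2}.  Instrument (true) effects are drawn as
#' half-normal magnitudes -- the effect allele is defined as the
#' trait-increasing allele, the orientation under which directional
#' pleiotropy biases the IVW slope.  Defaults: exposure instruments on the
#' scale detectable in a 3757-sample GWAS (\code{gamma_sd = 0.08} SD units),
#' mediator instruments on the larger scale typical of metabolite QTLs
#' (\code{delta_sd = 0.25}), and the reference effect sizes
#' \code{alpha_total = 0.5}, \code{b1 = 0.3}, \code{b2 = 0.25} (true
#' proportion mediated 15\%).
#'
#' @param n_snps_x,n_snps_m,n_snps_null counts of exposure-instrument,
#'   mediator-instrument and null background loci.
#' @param gamma_sd,delta_sd half-normal scales of the exposure / mediator
#'   instrument effects.
#' @param alpha_total,b1,b2 true total, exposure-to-mediator and
#'   mediator-to-outcome effects (log-OR scale for the binary outcome).
#' @param pleiotropy_mode \code{"none"}, \code{"balanced"} (mean-zero normal)
#'   or \code{"directional"} (mean \code{pleiotropy_scale}).
#' @param pleiotropy_scale scale of the per-SNP pleiotropic outcome effects.
#' @param pleiotropy_fraction fraction of exposure instruments made invalid.
#' @param n_exp,n_med,n_out GWAS sample sizes; per-SNP standard errors are
#'   \eqn{1/\sqrt{2 n f (1 - f)}} with minor-allele frequency
#'   \eqn{f \sim U(0.05, 0.5)}.
#' @param palindromic_rate fraction of loci given palindromic allele pairs.
#' @param ld_blocks optional \code{list(n_blocks, block_size, r2)} of
#'   equicorrelated blocks among exposure instruments.
#' @param seed integer seed.
#' @return a validated [TripleSpec].
#' @export
tripleSpec <- function(n_snps_x = 150L, n_snps_m = 150L, n_snps_null = 100L,
                       gamma_sd = 0.08, delta_sd = 0.25,
                       alpha_total = 0.5, b1 = 0.3, b2 = 0.25,
                       pleiotropy_mode = "none", pleiotropy_scale = 0.05,
                       pleiotropy_fraction = 1,
                       n_exp = 3757, n_med = 8299, n_out = 34652,
                       palindromic_rate = 0.1, ld_blocks = NULL, seed = 1L) {
  new("TripleSpec",
      nSnpsX = as.integer(n_snps_x), nSnpsM = as.integer(n_snps_m),
      nSnpsNull = as.integer(n_snps_null),
      gammaSd = gamma_sd, deltaSd = delta_sd,
      alphaTotal = alpha_total, b1 = b1, b2 = b2,
      pleiotropyMode = pleiotropy_mode, pleiotropyScale = pleiotropy_scale,
      pleiotropyFraction = pleiotropy_fraction,
      nExp = n_exp, nMed = n_med, nOut = n_out,
      palindromicRate = palindromic_rate, ldBlocks = ld_blocks,
      seed = as.integer(seed))
}

.NONPAL_PAIRS <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                       c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
.PAL_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

.gwasSe <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

.observe <- function(true_beta, se) {
  beta <- stats::rnorm(length(true_beta), true_beta, se)
  list(beta = beta, pval = 2 * stats::pnorm(-abs(beta / se)))
}

.pleioDraw <- function(mode, scale, n) {
  switch(mode,
         none = numeric(n),
         balanced = stats::rnorm(n, 0, scale),
         directional = stats::rnorm(n, scale, scale / 2))
}

#' Simulate a three-trait GWAS summary-statistics triple
#'
#' Generates exposure, mediator and outcome [AssociationSet]s over one shared
#' variant universe under the causal system of a [TripleSpec]: exposure loci
#' carry effects \eqn{\gamma_j} (half-normal), the mediator inherits
#' \eqn{b_1 \gamma_j} at exposure loci plus its own locus effects
#' \eqn{\delta_j}, and the outcome inherits
#' \eqn{\Gamma_j = \alpha_{total}\,\gamma_j + p_j} at exposure loci (with
#' optional pleiotropy \eqn{p_j}) and \eqn{b_2 \delta_j} at mediator loci.
#' Observed betas add normal noise with per-SNP standard errors
#' \eqn{1/\sqrt{2 n f (1-f)}}; palindromic allele pairs are injected at the
#' configured rate to exercise harmonization; optional equicorrelated LD
#' blocks among exposure instruments (shared true effects, pair list emitted)
#' exercise clumping.  Deterministic given \code{spec@seed}.
#'
#' @param spec a [TripleSpec].
#' @param exposure_id,mediator_id,outcome_id trait labels of the three sets.
#' @return a [TripleSimulation].
#' @export
simulateTriple <- function(spec, exposure_id = "SYN-EXP",
                           mediator_id = "SYN-MED", outcome_id = "SYN-OUT") {
  stopifnot(is(spec, "TripleSpec"))
  validObject(spec)
  nx <- spec@nSnpsX
  nm <- spec@nSnpsM
  nn <- spec@nSnpsNull
  n_total <- nx + nm + nn
  .withSeed(spec@seed, {
    ids <- sprintf("rs%06d", seq_len(n_total))
    chrom <- as.character(sample(1:22, n_total, replace = TRUE))
    pos <- sample.int(2e8, n_total, replace = TRUE)
    maf <- stats::runif(n_total, 0.05, 0.5)

    pal <- stats::runif(n_total) < spec@palindromicRate
    alleles <- matrix("", n_total, 2)
    alleles[pal, ] <- .PAL_PAIRS[sample.int(4, sum(pal), replace = TRUE), ,
                                 drop = FALSE]
    alleles[!pal, ] <- .NONPAL_PAIRS[sample.int(8, sum(!pal), replace = TRUE),
                                     , drop = FALSE]

    gamma_true <- numeric(n_total)
    xi <- seq_len(nx)
    gamma_true[xi] <- abs(stats::rnorm(nx, 0, spec@gammaSd))
    delta_true <- numeric(n_total)
    mi <- nx + seq_len(nm)
    delta_true[mi] <- abs(stats::rnorm(nm, 0, spec@deltaSd))

    # Optional equicorrelated LD blocks among exposure instruments: block
    # members share one true effect and sit close together on one chromosome.
    ld <- NULL
    if (!is.null(spec@ldBlocks)) {
      nb <- spec@ldBlocks$n_blocks
      bs <- spec@ldBlocks$block_size
      r2 <- spec@ldBlocks$r2
      stopifnot(nb * bs <= nx)
      pair_rows <- list()
      for (b in seq_len(nb)) {
        members <- (b - 1L) * bs + seq_len(bs)
        gamma_true[members] <- gamma_true[members[1L]]
        chrom[members] <- as.character((b - 1L) %% 22L + 1L)
        pos[members] <- 1e6 + (b - 1L) * 5e7 + (seq_len(bs) - 1L) * 5000
        if (bs > 1L) {
          cmb <- utils::combn(members, 2L)
          pair_rows[[b]] <- data.frame(id_a = ids[cmb[1, ]],
                                       id_b = ids[cmb[2, ]], r2 = r2,
                                       stringsAsFactors = FALSE)
        }
      }
      if (length(pair_rows)) ld <- ldPairList(do.call(rbind, pair_rows))
    }

    pleio <- numeric(n_total)
    n_pl <- round(spec@pleiotropyFraction * nx)
    if (spec@pleiotropyMode != "none" && n_pl > 0) {
      target <- sample(xi, n_pl)
      pleio[target] <- .pleioDraw(spec@pleiotropyMode, spec@pleiotropyScale,
                                  n_pl)
    }

    beta_med_true <- spec@b1 * gamma_true + delta_true
    direct <- spec@alphaTotal - spec@b1 * spec@b2
    beta_out_true <- direct * gamma_true + spec@b2 * beta_med_true + pleio

    se_exp <- .gwasSe(spec@nExp, maf)
    se_med <- .gwasSe(spec@nMed, maf)
    se_out <- .gwasSe(spec@nOut, maf)
    obs_exp <- .observe(gamma_true, se_exp)
    obs_med <- .observe(beta_med_true, se_med)
    obs_out <- .observe(beta_out_true, se_out)

    mk <- function(obs, se, n, id, type) {
      AssociationSet(id, type, data.frame(
        variant_id = ids, chrom = chrom, pos = pos,
        effect_allele = alleles[, 1], other_allele = alleles[, 2],
        beta = obs$beta, se = se, pval = obs$pval, eaf = maf, n = n,
        stringsAsFactors = FALSE), quiet = TRUE)
    }
    new("TripleSimulation",
        exposure = mk(obs_exp, se_exp, spec@nExp, exposure_id,
                      "exposure-immune"),
        mediator = mk(obs_med, se_med, spec@nMed, mediator_id,
                      "mediator-metabolite"),
        outcome = mk(obs_out, se_out, spec@nOut, outcome_id,
                     "outcome-disease"),
        truth = spec, ld = ld)
  })
}

#' Simulate a directly harmonized exposure-outcome system
#'
#' Lower-level generator used for estimator calibration: produces a
#' [HarmonizedSet] of exactly \code{n_snps} instruments with known truth and
#' no selection step.  True instrument effects are half-normal magnitudes
#' (trait-increasing orientation); observed effects add normal noise with the
#' given constant standard errors; the outcome satisfies
#' \eqn{\Gamma_j = \alpha\,\gamma_j + p_j + \epsilon_j} with optional
#' balanced or directional pleiotropy \eqn{p_j} on a fraction of instruments.
#'
#' @param n_snps number of instruments J.
#' @param gamma_sd half-normal scale of the true exposure effects.
#' @param alpha true causal effect.
#' @param pleiotropy_mode,pleiotropy_scale,pleiotropy_fraction see
#'   [tripleSpec()].
#' @param se_exposure,se_outcome per-SNP standard errors (recycled).
#' @param seed integer seed.
#' @return a [HarmonizedSet].
#' @export
simulateHarmonized <- function(n_snps, gamma_sd = 0.3, alpha = 0,
                               pleiotropy_mode = "none",
                               pleiotropy_scale = 0.05,
                               pleiotropy_fraction = 1,
                               se_exposure = 0.025, se_outcome = 0.01,
                               seed = 1L) {
  stopifnot(n_snps >= 1)
  se_exposure <- rep_len(se_exposure, n_snps)
  se_outcome <- rep_len(se_outcome, n_snps)
  .withSeed(seed, {
    gamma_true <- abs(stats::rnorm(n_snps, 0, gamma_sd))
    pleio <- numeric(n_snps)
    n_pl <- round(pleiotropy_fraction * n_snps)
    if (pleiotropy_mode != "none" && n_pl > 0) {
      target <- sample(seq_len(n_snps), n_pl)
      pleio[target] <- .pleioDraw(pleiotropy_mode, pleiotropy_scale, n_pl)
    }
    gamma_hat <- stats::rnorm(n_snps, gamma_true, se_exposure)
    Gamma_hat <- stats::rnorm(n_snps, alpha * gamma_true + pleio, se_outcome)
    d <- data.frame(variant_id = sprintf("rs%06d", seq_len(n_snps)),
                    gamma = gamma_hat, se_gamma = se_exposure,
                    Gamma = Gamma_hat, se_Gamma = se_outcome,
                    pval_exposure = 2 * stats::pnorm(-abs(gamma_hat /
                                                            se_exposure)),
                    stringsAsFactors = FALSE)
    new("HarmonizedSet", exposureId = "SYN-EXP", outcomeId = "SYN-OUT",
        data = d, nDroppedPalindromic = 0L, nDroppedIncompatible = 0L)
  })
}

#' Simulate a panel of exposures sharing one outcome
#'
#' Miniature of a many-trait screening panel: each of \code{n_traits}
#' exposures gets its own disjoint instrument loci drawn from the template
#' spec; only the traits listed in \code{causal_indices} carry a true effect
#' (\code{alpha_total} from the template) on the shared outcome.  The outcome
#' set spans the union of all loci.
#'
#' @param n_traits number of exposure traits.
#' @param template a [TripleSpec] providing effect scales, sample sizes and
#'   the causal effect size; its mediator settings are ignored.
#' @param causal_indices integer indices of the truly causal traits.
#' @param seed integer seed.
#' @return list with elements \code{exposures} (list of [AssociationSet]),
#'   \code{outcome} (an [AssociationSet]) and \code{truth} (data.frame with
#'   columns \code{trait_id, causal, alpha}).
#' @export
simulatePanel <- function(n_traits, template = tripleSpec(),
                          causal_indices = integer(0), seed = 1L) {
  stopifnot(is(template, "TripleSpec"),
            all(causal_indices %in% seq_len(n_traits)))
  nx <- template@nSnpsX
  .withSeed(seed, {
    n_total <- n_traits * nx
    ids <- sprintf("rs%06d", seq_len(n_total))
    chrom <- as.character(sample(1:22, n_total, replace = TRUE))
    pos <- sample.int(2e8, n_total, replace = TRUE)
    maf <- stats::runif(n_total, 0.05, 0.5)
    pal <- stats::runif(n_total) < template@palindromicRate
    alleles <- matrix("", n_total, 2)
    alleles[pal, ] <- .PAL_PAIRS[sample.int(4, sum(pal), replace = TRUE), ,
                                 drop = FALSE]
    alleles[!pal, ] <- .NONPAL_PAIRS[sample.int(8, sum(!pal),
                                                replace = TRUE), ,
                                     drop = FALSE]
    se_exp <- .gwasSe(template@nExp, maf)
    se_out <- .gwasSe(template@nOut, maf)

    gamma_true <- numeric(n_total)
    Gamma_true <- numeric(n_total)
    truth <- data.frame(trait_id = sprintf("TRAIT-%03d", seq_len(n_traits)),
                        causal = seq_len(n_traits) %in% causal_indices,
                        alpha = 0, stringsAsFactors = FALSE)
    truth$alpha[truth$causal] <- template@alphaTotal

    exposures <- vector("list", n_traits)
    for (t in seq_len(n_traits)) {
      loci <- (t - 1L) * nx + seq_len(nx)
      g <- abs(stats::rnorm(nx, 0, template@gammaSd))
      gamma_true[loci] <- g
      Gamma_true[loci] <- truth$alpha[t] * g
      # each trait associates only with its own loci
      own <- numeric(n_total)
      own[loci] <- g
      obs <- .observe(own, se_exp)
      exposures[[t]] <- AssociationSet(
        truth$trait_id[t], "exposure-immune",
        data.frame(variant_id = ids, chrom = chrom, pos = pos,
                   effect_allele = alleles[, 1], other_allele = alleles[, 2],
                   beta = obs$beta, se = se_exp, pval = obs$pval,
                   eaf = maf, n = template@nExp, stringsAsFactors = FALSE),
        quiet = TRUE)
    }
    obs_out <- .observe(Gamma_true, se_out)
    outcome <- AssociationSet(
      "SYN-OUT", "outcome-disease",
      data.frame(variant_id = ids, chrom = chrom, pos = pos,
                 effect_allele = alleles[, 1], other_allele = alleles[, 2],
                 beta = obs_out$beta, se = se_out, pval = obs_out$pval,
                 eaf = maf, n = template@nOut, stringsAsFactors = FALSE),
      quiet = TRUE)
    list(exposures = exposures, outcome = outcome, truth = truth)
  })
}

#' Write a TripleSimulation to disk
#'
#' Emits the three summary tables in the dialect [readSummary()] reads back
#' (\code{exposure.tsv}, \code{mediator.tsv}, \code{outcome.tsv}), the truth
#' parameters as \code{truth.tsv}, and the LD pair list as \code{ld.tsv}
#' when present.
#'
#' @param sim a [TripleSimulation].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeTriple <- function(sim, dir) {
  stopifnot(is(sim, "TripleSimulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSummary(sim@exposure, file.path(dir, "exposure.tsv"))
  writeSummary(sim@mediator, file.path(dir, "mediator.tsv"))
  writeSummary(sim@outcome, file.path(dir, "outcome.tsv"))
  tr <- sim@truth
  truth <- data.frame(
    parameter = c("alpha_total", "b1", "b2", "direct", "pleiotropy_mode",
                  "pleiotropy_scale", "pleiotropy_fraction", "seed"),
    value = c(tr@alphaTotal, tr@b1, tr@b2, tr@alphaTotal - tr@b1 * tr@b2,
              tr@pleiotropyMode, tr@pleiotropyScale, tr@pleiotropyFraction,
              tr@seed), stringsAsFactors = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim@ld))
    utils::write.table(sim@ld@pairs, file.path(dir, "ld.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}
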