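# Builders ------------------------------------------------------------------

# Quick AssociationSet from partial columns, filling sensible defaults.
makeAssoc <- function(df, trait_id = "T1", trait_type = "exposure-immune",
                      quiet = TRUE) {
  n <- nrow(df)
  defaults <- data.frame(
    variant_id = sprintf("rs%d", seq_len(n)),
    effect_allele = rep("A", n), other_allele = rep("G", n),
    beta = rep(0.1, n), se = rep(0.01, n), pval = rep(1e-8, n),
    stringsAsFactors = FALSE)
  for (col in names(df)) defaults[[col]] <- df[[col]]
  AssociationSet(trait_id, trait_type, defaults, quiet = quiet)
}

# HarmonizedSet directly from effect vectors.
makeHarm <- function(gamma, se_gamma, Gamma, se_Gamma,
                     ids = sprintf("rs%d", seq_along(gamma))) {
  new("HarmonizedSet", exposureId = "X", outcomeId = "Y",
      data = data.frame(variant_id = ids, gamma = gamma,
                        se_gamma = rep_len(se_gamma, length(gamma)),
                        Gamma = Gamma,
                        se_Gamma = rep_len(se_Gamma, length(gamma)),
                        pval_exposure = rep_len(1e-8, length(gamma)),
                        stringsAsFactors = FALSE),
      nDroppedPalindromic = 0L, nDroppedIncompatible = 0L)
}

# Random harmonized fixture for property tests.
randomHarm <- function(j, seed) {
  set.seed(seed)
  makeHarm(gamma = rnorm(j, 0.1, 0.05) + 0.05,
           se_gamma = runif(j, 0.005, 0.03),
           Gamma = rnorm(j, 0.03, 0.03),
           se_Gamma = runif(j, 0.005, 0.03))
}

# Independent oracles --------------------------------------------------------

# IVW via origin-constrained weighted least squares (normal equations),
# independent of the package's ratio-form implementation.
ivwOracle <- function(d) {
  w <- 1 / d$se_Gamma^2
  beta <- sum(w * d$gamma * d$Gamma) / sum(w * d$gamma^2)
  se <- 1 / sqrt(sum(w * d$gamma^2))
  list(beta = beta, se = se)
}

# MR-Egger via explicit 2x2 weighted normal equations with the same
# gamma >= 0 orientation and multiplicative random-effects floor.
eggerOracle <- function(d) {
  flip <- d$gamma < 0
  g <- ifelse(flip, -d$gamma, d$gamma)
  G <- ifelse(flip, -d$Gamma, d$Gamma)
  w <- 1 / d$se_Gamma^2
  sw <- sum(w); swg <- sum(w * g); swg2 <- sum(w * g^2)
  swG <- sum(w * G); swgG <- sum(w * g * G)
  det <- sw * swg2 - swg^2
  intercept <- (swg2 * swG - swg * swgG) / det
  slope <- (sw * swgG - swg * swG) / det
  resid <- G - intercept - slope * g
  sigma2 <- sum(w * resid^2) / (length(g) - 2)
  scale <- max(1, sqrt(sigma2))
  list(intercept = intercept, slope = slope,
       se_intercept = sqrt(swg2 / det) * scale,
       se_slope = sqrt(sw / det) * scale)
}

# Literal Benjamini-Hochberg step-up: for each p, q_i = min over j with
# p_(j) >= p_i (by rank) of m * p_(j) / j.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranks <- match(seq_len(m), o)  # rank of each original element
  vapply(seq_len(m), function(i) {
    ri <- ranks[i]
    min(1, min(vapply(ri:m, function(j) m * p[o[j]] / j, numeric(1))))
  }, numeric(1))
}
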