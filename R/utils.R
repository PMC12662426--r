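.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Base complement for single-base alleles; NA for indels / unknown characters.
.compAllele <- function(a) {
  out <- unname(.COMPLEMENT[a])
  out
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' All randomness in the pipeline flows from one top-level seed; bootstrap
#' resampling and per-pair screening draw from named substreams so that
#' results do not depend on evaluation order.  Sub-seeds stay below
#' \code{2^31 - 1}.
#'
#' @param seed top-level integer seed.
#' @param stage character stage label.
#' @param index optional integer index (e.g. pair number) within the stage.
#' @return a positive integer seed.
#' @export
deriveSeed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  s <- (abs(seed) * 7919 + h * 104729 + index * 65537) %% 2147483646
  as.integer(s) + 1L
}

# Weighted mean / SD with weights normalized internally (population form:
# denominator sum(w), so equal weights reduce to the population SD).
.wmean <- function(x, w) sum(w * x) / sum(w)
.wsd <- function(x, w) {
  m <- .wmean(x, w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

.z975 <- function() stats::qnorm(0.975)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.msgf <- function(fmt, ...) message(sprintf(fmt, ...))
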