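#' Analysis configuration
#'
#' Bundles the pipeline thresholds and estimator settings with their
#' reference defaults: instrument p-value threshold \eqn{1\times 10^{-5}}
#' (strict), clumping at \eqn{r^2 < 0.001} within 10,000 kb, weak-instrument
#' cutoff F < 10, screening rule p < .01 with FDR < 0.05, multiplicative
#' random-effects IVW, and 1000 bootstrap replicates for the median/mode
#' standard errors.
#'
#' @param p_instrument instrument p-value threshold (strict <), in (0, 1].
#' @param r2_max clumping r-squared threshold (discard at >=).
#' @param window_kb clumping window half-width, kb.
#' @param f_min minimum instrument F statistic.
#' @param p_screen nominal p threshold of the strong evidence tier.
#' @param fdr_max FDR threshold of the strong evidence tier.
#' @param ivw_mode \code{"random"} or \code{"fixed"}.
#' @param n_boot bootstrap replicates for median/mode standard errors.
#' @param bandwidth_factor mode-estimator bandwidth tuning factor.
#' @param seed top-level integer seed (mandatory whenever any bootstrap is
#'   used; all randomness flows from it via named substreams).
#' @param out_dir output directory for the command-level entry points.
#' @return validated named list with class \code{"mr_config"}.
#' @export
mrConfig <- function(p_instrument = 1e-5, r2_max = 0.001, window_kb = 10000,
                     f_min = 10, p_screen = 0.01, fdr_max = 0.05,
                     ivw_mode = "random", n_boot = 1000L,
                     bandwidth_factor = 1, seed = NULL, out_dir = NULL) {
  cfg <- list(p_instrument = p_instrument, r2_max = r2_max,
              window_kb = window_kb, f_min = f_min, p_screen = p_screen,
              fdr_max = fdr_max, ivw_mode = ivw_mode,
              n_boot = as.integer(n_boot),
              bandwidth_factor = bandwidth_factor,
              seed = if (is.null(seed)) NULL else as.integer(seed),
              out_dir = out_dir)
  .validateConfig(cfg)
  class(cfg) <- "mr_config"
  cfg
}

.validateConfig <- function(cfg) {
  chk <- function(ok, what) if (!ok) .stopf("invalid config: %s", what)
  chk(cfg$p_instrument > 0 && cfg$p_instrument <= 1,
      "p_instrument must be in (0, 1]")
  chk(cfg$r2_max >= 0 && cfg$r2_max <= 1, "r2_max must be in [0, 1]")
  chk(cfg$window_kb > 0, "window_kb must be > 0")
  chk(cfg$f_min >= 0, "f_min must be >= 0")
  chk(cfg$p_screen > 0 && cfg$p_screen <= 1, "p_screen must be in (0, 1]")
  chk(cfg$fdr_max > 0 && cfg$fdr_max <= 1, "fdr_max must be in (0, 1]")
  chk(cfg$ivw_mode %in% c("random", "fixed"),
      "ivw_mode must be 'random' or 'fixed'")
  chk(cfg$n_boot >= 0, "n_boot must be >= 0")
  chk(cfg$bandwidth_factor > 0, "bandwidth_factor must be > 0")
  chk(!(cfg$n_boot > 0 && is.null(cfg$seed)),
      "seed is mandatory when bootstrap is used (n_boot > 0)")
  invisible(cfg)
}

#' Read a plain-text pipeline configuration file
#'
#' Format: one entry per line; \code{key = value} lines set thresholds and
#' estimator options (any [mrConfig()] argument), and whitespace-separated
#' data lines declare inputs:
#' \preformatted{
#'   seed = 42
#'   p_instrument = 1e-5
#'   out_dir = results
#'   dialect = plain
#'   exposure  TRAIT-A  path/to/traitA.tsv
#'   mediator  MET-1    path/to/met1.tsv
#'   outcome   IBD      path/to/ibd.tsv
#'   ld        path/to/ld_pairs.tsv
#' }
#' Lines starting with \code{#} and blank lines are ignored.  Unknown keys
#' and malformed lines raise an error naming the offending line.
#'
#' @param path config file path.
#' @return list with elements \code{config} (an [mrConfig()] list),
#'   \code{traits} (data.frame role/id/path), \code{ld_path} (or NULL) and
#'   \code{dialect}.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  lines <- readLines(path)
  kv <- list()
  traits <- list()
  ld_path <- NULL
  dialect <- "plain"
  known_keys <- c(names(formals(mrConfig)), "dialect")
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (grepl("=", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(parts[1])
      val <- trimws(paste(parts[-1], collapse = "="))
      if (!key %in% known_keys)
        .stopf("config line %d: unknown key '%s'", i, key)
      if (key == "dialect") dialect <- val
      else if (key %in% c("ivw_mode", "out_dir")) kv[[key]] <- val
      else kv[[key]] <- as.numeric(val)
    } else {
      tok <- strsplit(ln, "\\s+")[[1]]
      role <- tok[1]
      if (role == "ld") {
        if (length(tok) != 2L) .stopf("config line %d: ld needs one path", i)
        ld_path <- tok[2]
      } else if (role %in% c("exposure", "mediator", "outcome")) {
        if (length(tok) != 3L)
          .stopf("config line %d: expected '%s <trait_id> <path>'", i, role)
        traits[[length(traits) + 1L]] <-
          data.frame(role = role, id = tok[2], path = tok[3],
                     stringsAsFactors = FALSE)
      } else {
        .stopf("config line %d: unrecognized entry '%s'", i, role)
      }
    }
  }
  cfg <- do.call(mrConfig, kv)
  list(config = cfg,
       traits = if (length(traits)) do.call(rbind, traits)
                else data.frame(role = character(0), id = character(0),
                                path = character(0)),
       ld_path = ld_path, dialect = dialect)
}

.roleType <- c(exposure = "exposure-immune", mediator = "mediator-metabolite",
               outcome = "outcome-disease")

.loadTraits <- function(pc) {
  tr <- pc$traits
  sets <- list()
  for (i in seq_len(nrow(tr))) {
    if (!file.exists(tr$path[i]))
      .stopf("input path for trait '%s' does not exist: %s",
             tr$id[i], tr$path[i])
    sets[[tr$id[i]]] <- readSummary(
      tr$path[i], trait_id = tr$id[i],
      trait_type = .roleType[[tr$role[i]]],
      column_map = gwasDialect(pc$dialect), quiet = TRUE)
  }
  sets
}

.configHash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x), collapse = ","), character(1)), collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 4294967291)
}

.writeRunLog <- function(pc, path, extra = character(0)) {
  cfg <- pc$config
  lines <- c(
    sprintf("package: MRmediate %s",
            as.character(utils::packageVersion("MRmediate"))),
    sprintf("r_version: %s", R.version.string),
    sprintf("config_hash: %s", .configHash(cfg)),
    sprintf("seed: %s", if (is.null(cfg$seed)) "NA" else cfg$seed),
    sprintf("%s: %s", names(unlist(cfg[!vapply(cfg, is.null, logical(1))])),
            unlist(cfg[!vapply(cfg, is.null, logical(1))])),
    extra)
  writeLines(lines, path)
  invisible(path)
}

#' Run the screening pipeline from a configuration file
#'
#' Loads every configured exposure and outcome, runs [runScreen()] with the
#' configured thresholds, and writes \code{screen_results.tsv},
#' \code{sensitivity.tsv} (per-pair diagnostics extracted from the screen)
#' and \code{run_log.txt} (package version, seed, config hash, per-stage SNP
#' counts) into the output directory.
#'
#' @param config_path path to a [readPipelineConfig()] file, or the list it
#'   returns.
#' @return invisibly, a list with the output paths and the screen data.frame.
#' @export
cmdMR <- function(config_path) {
  pc <- if (is.character(config_path)) readPipelineConfig(config_path)
        else config_path
  sets <- .loadTraits(pc)
  roles <- pc$traits$role[match(names(sets), pc$traits$id)]
  exposures <- sets[roles %in% c("exposure", "mediator")]
  outcomes <- sets[roles == "outcome"]
  if (!length(exposures)) .stopf("config declares no exposure traits")
  if (!length(outcomes)) .stopf("config declares no outcome traits")
  ld <- if (!is.null(pc$ld_path)) readLDPairs(pc$ld_path) else NULL
  screen <- runScreen(unname(exposures), unname(outcomes), ld, pc$config)

  out_dir <- if (is.null(pc$config$out_dir)) "." else pc$config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  screen_path <- file.path(out_dir, "screen_results.tsv")
  utils::write.table(screen, screen_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sens_cols <- c("exposure", "outcome", "nsnp", "q_pval", "egger_intercept",
                 "egger_intercept_pval", "loo_unstable", "status")
  sens_path <- file.path(out_dir, "sensitivity.tsv")
  utils::write.table(screen[, sens_cols], sens_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts <- sprintf("pair %s->%s: nsnp=%s status=%s", screen$exposure,
                    screen$outcome, screen$nsnp, screen$status)
  log_path <- file.path(out_dir, "run_log.txt")
  .writeRunLog(pc, log_path, counts)
  invisible(list(screen = screen, screen_path = screen_path,
                 sensitivity_path = sens_path, log_path = log_path))
}

#' Run two-step mediation for configured triples
#'
#' For each requested exposure/mediator/outcome triple, runs [runMediation()]
#' and writes a mediated-effect table (\code{mediation_results.tsv}: mediated
#' effect with 95\% CI, mediated proportion \% with 95\% CI, p-value) plus a
#' per-leg appendix (\code{mediation_legs.tsv}) and a run log.  A triple
#' whose total effect is exactly zero (undefined proportion) or that fails
#' upstream is flagged in its row rather than aborting the run; input order
#' is preserved.
#'
#' @param config_path path to a [readPipelineConfig()] file, or the list it
#'   returns.
#' @param triples data.frame with columns \code{exposure, mediator, outcome}
#'   naming configured trait ids.
#' @return invisibly, a list with the results data.frame and output paths.
#' @export
cmdMediate <- function(config_path, triples) {
  pc <- if (is.character(config_path)) readPipelineConfig(config_path)
        else config_path
  stopifnot(all(c("exposure", "mediator", "outcome") %in% names(triples)))
  sets <- .loadTraits(pc)
  unknown <- setdiff(unique(unlist(triples[c("exposure", "mediator",
                                             "outcome")])), names(sets))
  if (length(unknown))
    .stopf("triple refers to unconfigured trait id(s): %s",
           paste(unknown, collapse = ", "))
  ld <- if (!is.null(pc$ld_path)) readLDPairs(pc$ld_path) else NULL

  rows <- list()
  legs <- list()
  for (i in seq_len(nrow(triples))) {
    tri <- triples[i, ]
    res <- tryCatch(
      runMediation(sets[[tri$exposure]], sets[[tri$mediator]],
                   sets[[tri$outcome]], ld, pc$config),
      error = function(e) e)
    if (is(res, "error")) {
      rows[[i]] <- data.frame(
        exposure = tri$exposure, mediator = tri$mediator,
        outcome = tri$outcome, alpha = NA_real_, alpha_se = NA_real_,
        beta1 = NA_real_, beta1_se = NA_real_, beta2 = NA_real_,
        beta2_se = NA_real_, mediated_effect = NA_real_,
        mediated_ci_low = NA_real_, mediated_ci_high = NA_real_,
        proportion_pct = NA_real_, proportion_ci_low = NA_real_,
        proportion_ci_high = NA_real_, pval = NA_real_,
        status = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      r <- as.data.frame(res)
      r$status <- "ok"
      rows[[i]] <- r
      legs[[i]] <- data.frame(
        exposure = tri$exposure, mediator = tri$mediator,
        outcome = tri$outcome,
        leg = c("alpha", "beta1", "beta2"),
        beta = c(res@alpha, res@beta1, res@beta2),
        se = c(res@alphaSe, res@beta1Se, res@beta2Se),
        nsnp = c(length(attr(res, "instruments")$total),
                 length(attr(res, "instruments")$exposure),
                 length(attr(res, "instruments")$mediator)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out_dir <- if (is.null(pc$config$out_dir)) "." else pc$config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  med_path <- file.path(out_dir, "mediation_results.tsv")
  utils::write.table(out, med_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  legs_path <- file.path(out_dir, "mediation_legs.tsv")
  if (length(legs))
    utils::write.table(do.call(rbind, legs), legs_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  .writeRunLog(pc, log_path,
               sprintf("triple %s/%s/%s: %s", out$exposure, out$mediator,
                       out$outcome, out$status))
  invisible(list(mediation = out, mediation_path = med_path,
                 legs_path = legs_path, log_path = log_path))
}

#' Simulate a triple and write it to disk
#'
#' Convenience entry point pairing [simulateTriple()] with [writeTriple()].
#'
#' @param out_dir output directory.
#' @param spec a [TripleSpec] (defaults to [tripleSpec()]).
#' @param seed overrides the spec's seed when given.
#' @return the output directory, invisibly.
#' @export
cmdSimulate <- function(out_dir, spec = tripleSpec(), seed = NULL) {
  if (!is.null(seed)) spec@seed <- as.integer(seed)
  sim <- simulateTriple(spec)
  writeTriple(sim, out_dir)
}
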