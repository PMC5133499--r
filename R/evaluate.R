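#' Empirical rejection rates at nominal levels
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param alpha_levels nominal significance levels.
#' @return a `RejectionReport` data.frame with columns `alpha`, `rate`,
#'   `n_tests`, `mc_se` (binomial Monte-Carlo standard error
#'   sqrt(alpha (1 - alpha) / n)).
#' @export
empirical_rejection_rate <- function(p_values,
                                     alpha_levels = c(0.05, 0.01, 0.001)) {
  if (length(p_values) == 0L) stop("empty p-value list")
  stopifnot(all(p_values >= 0 & p_values <= 1), length(alpha_levels) >= 1)
  out <- data.frame(
    alpha = alpha_levels,
    rate = vapply(alpha_levels, function(a) mean(p_values <= a), 1.0),
    n_tests = length(p_values),
    mc_se = sqrt(alpha_levels * (1 - alpha_levels) / length(p_values)))
  class(out) <- c("RejectionReport", "data.frame")
  out
}

# Precomputed per-block quantities for the replicate loop: centered kept
# dosages, diagonal covariance, scaled-chi-square fit, and the MB-weight
# pieces of the WS-score denominator.
prepare_block <- function(dosages) {
  cov <- suppressWarnings(estimate_genotype_covariance(dosages))
  Gc <- scale(dosages[, cov$kept_variants, drop = FALSE],
              center = TRUE, scale = FALSE)
  fit <- moment_match_scaled_chisq(cov)
  w_all <- madsen_browning_weights(dosages)
  w <- w_all[cov$kept_variants]
  list(Gc = Gc, sigma0 = cov$sigma0_hat, fit = fit,
       w = w, wSw = drop(crossprod(w, cov$sigma_hat %*% w)),
       n_kept = length(cov$kept_variants))
}

simulate_null_blocks <- function(peds, maf_range, M, n_blocks) {
  lapply(seq_len(n_blocks), function(b) {
    for (try in 1:20) {
      maf <- stats::runif(M, maf_range[1], maf_range[2])
      dos <- do.call(rbind, lapply(peds, function(p) {
        gene_drop(p, draw_founder_genotypes(maf, sum(p$founder)))$dosages
      }))
      if (any(apply(dos, 2, stats::var) > 0)) return(prepare_block(dos))
    }
    stop("could not simulate a polymorphic variant block")
  })
}

#' Empirical type-I-error study on simulated null pedigree data
#'
#' Emulates the null evaluation protocol: a fixed set of pedigrees and a fixed
#' set of genotype blocks (regions far from any causal variant, so all
#' variant effects are zero), with the trait re-simulated in each replicate;
#' covariates are regressed out per replicate and each test is applied to each
#' block, pooling one p-value per replicate x block.
#'
#' Trait replicates share the per-individual covariates (fixed like sex or
#' age) and redraw the polygenic and residual components. `phi_mode =
#' "identity"` deliberately ignores relatedness in the test (the trait is
#' still simulated with it), a misspecification probe that should inflate the
#' type I error.
#'
#' @param config a null `SimulationConfig` (all `beta` must be 0).
#' @param n_replicates number of trait replicates.
#' @param n_blocks number of genotype blocks.
#' @param tests subset of `c("ow", "ws")`.
#' @param alpha_levels nominal levels for the report.
#' @param seed integer seed (all randomness flows from it).
#' @param phi_mode `"kinship"` (correct analysis) or `"identity"`.
#' @return a `CalibrationStudy`: list with `reports` (named list of
#'   `RejectionReport`), `p_values` (named list of n_replicates x n_blocks
#'   matrices), `n_tests`, `phi_mode`, `seed`.
#' @export
run_calibration_study <- function(config = simulation_config(),
                                  n_replicates = 200L, n_blocks = 50L,
                                  tests = c("ow", "ws"),
                                  alpha_levels = c(0.05, 0.01, 0.001),
                                  seed = 1L,
                                  phi_mode = c("kinship", "identity")) {
  stopifnot(inherits(config, "SimulationConfig"))
  phi_mode <- match.arg(phi_mode)
  tests <- match.arg(tests, c("ow", "ws"), several.ok = TRUE)
  if (length(config$beta) && any(config$beta != 0))
    stop("calibration requires a null configuration (all beta = 0)")
  if (length(config$maf) != 2L)
    stop("calibration draws block MAFs from a range; give maf = c(lo, hi)")
  set.seed(seed)

  peds <- lapply(seq_len(config$n_pedigrees), function(i)
    relabel_pedigree(config$pedigree_template, paste0("ped", i)))
  phi <- phi_blocks(peds)
  ids <- phi_block_ids(phi)
  n <- length(ids)
  chol_blocks <- phi_chol(phi)

  blocks <- simulate_null_blocks(peds, config$maf, config$M, n_blocks)
  X <- draw_covariates(n, config$covariate_effects)
  mu <- rep(config$intercept, n)
  if (!is.null(X)) mu <- mu + drop(X %*% config$covariate_effects)

  pv <- lapply(tests, function(t) matrix(NA_real_, n_replicates, n_blocks))
  names(pv) <- tests
  for (r in seq_len(n_replicates)) {
    pg <- draw_polygenic(chol_blocks, config$h2, config$sigma_total)
    eps <- stats::rnorm(n, 0, sqrt(1 - config$h2) * config$sigma_total)
    tv <- adjust_covariates(trait_vector(mu + pg + eps, ids), X)
    y <- tv$values
    q <- if (phi_mode == "kinship") trait_quadratic_form(tv, phi) else sum(y^2)
    for (b in seq_len(n_blocks)) {
      bl <- blocks[[b]]
      u <- drop(crossprod(bl$Gc, y))
      if ("ow" %in% tests) {
        stat <- sum(u^2 / bl$sigma0) / q
        pv$ow[r, b] <- scaled_chisq_pvalue(stat, bl$fit)
      }
      if ("ws" %in% tests) {
        stat <- sum(bl$w * u)^2 / (bl$wSw * q)
        pv$ws[r, b] <- stats::pchisq(stat, 1, lower.tail = FALSE)
      }
    }
  }
  reports <- lapply(pv, function(m) empirical_rejection_rate(c(m), alpha_levels))
  structure(list(reports = reports, p_values = pv,
                 n_tests = n_replicates * n_blocks, phi_mode = phi_mode,
                 config = config, n_replicates = n_replicates,
                 n_blocks = n_blocks, seed = seed),
            class = "CalibrationStudy")
}

#' @export
print.CalibrationStudy <- function(x, ...) {
  cat("CalibrationStudy:", x$n_replicates, "replicates x", x$n_blocks,
      "blocks (seed", x$seed, ", phi:", x$phi_mode, ")\n")
  for (t in names(x$reports)) {
    cat("--", toupper(t), "--\n")
    print.data.frame(x$reports[[t]], row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Empirical power study on simulated pedigree data
#'
#' Draws the region's variant frequencies once (the "gene" under test), then
#' for each replicate simulates fresh founder genotypes, gene drop, covariates
#' and trait under the configured causal effects, adjusts covariates, applies
#' the requested tests, and reports the rejection rate at `alpha`.
#'
#' @param config a `SimulationConfig` (typically with nonzero `beta`).
#' @param n_replicates number of study replicates.
#' @param tests subset of `c("ow", "ws")`.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return data.frame with columns `test`, `alpha`, `power`, `mc_se`,
#'   `n_replicates`; attribute `p_values` holds the per-replicate p matrix.
#' @export
run_power_study <- function(config, n_replicates = 200L, tests = c("ow", "ws"),
                            alpha = 0.05, seed = 1L) {
  stopifnot(inherits(config, "SimulationConfig"))
  tests <- match.arg(tests, c("ow", "ws"), several.ok = TRUE)
  set.seed(seed)
  maf <- draw_maf(config)
  cfg_fixed <- config
  cfg_fixed$maf <- maf  # same gene across replicates
  pmat <- matrix(NA_real_, n_replicates, length(tests),
                 dimnames = list(NULL, tests))
  for (r in seq_len(n_replicates)) {
    study <- simulate_study(cfg_fixed)
    tv <- adjust_covariates(study$trait, study$covariates)
    res <- suppressWarnings(apply_tests(study$geno, tv, study$phi, tests))
    pmat[r, ] <- vapply(res, `[[`, 1.0, "p_value")
  }
  out <- data.frame(test = tests, alpha = alpha,
                    power = colMeans(pmat <= alpha),
                    mc_se = apply(pmat <= alpha, 2,
                                  function(z) stats::sd(z) / sqrt(length(z))),
                    n_replicates = n_replicates, row.names = NULL)
  attr(out, "p_values") <- pmat
  out
}

apply_tests <- function(geno, trait, phi, tests) {
  res <- list()
  if ("ow" %in% tests)
    res$ow <- ow_score_statistic(geno, trait, phi)
  if ("ws" %in% tests)
    res$ws <- weighted_score_statistic(geno, trait, phi,
                                       madsen_browning_weights(geno),
                                       covariance_mode = "full")
  res[tests]
}

#' Write a rejection/power report as TSV with metadata header
#'
#' @param report a `RejectionReport` or power data.frame.
#' @param path output path.
#' @param meta named character vector of `# key: value` header lines.
#' @return invisibly, the path.
#' @export
write_report_tsv <- function(report, path, meta = NULL) {
  hdr <- c(paste0("# owscore ", as.character(utils::packageVersion("owscore"))),
           if (length(meta)) paste0("# ", names(meta), ": ", meta))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(report), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
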