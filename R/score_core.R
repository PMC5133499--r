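#' Estimate the per-individual genotype covariance matrix
#'
#' Sigma-hat = (1/N) * sum_ij (g_ij - g_bar)(g_ij - g_bar)^T, with g_bar the
#' grand mean dosage vector and N the total number of analyzed individuals
#' (divisor N, not N - 1). Variants with zero sample variance (monomorphic in
#' the analyzed sample) carry no association information and are set aside.
#'
#' @param geno a `GenotypeMatrix` (or bare dosage matrix, individuals x
#'   variants) with no missing entries.
#' @return a `GenotypeCovariance`: list with `sigma_hat` (covariance of the
#'   kept variants), `sigma0_hat` (its diagonal), `kept_variants` and
#'   `dropped_variants` (column indices into the input), `n` (sample count).
#' @export
estimate_genotype_covariance <- function(geno) {
  G <- if (inherits(geno, "GenotypeMatrix")) geno$dosages else as.matrix(geno)
  if (anyNA(G)) stop("genotype matrix has missing entries; align samples first")
  n <- nrow(G)
  if (n < 2L) stop("need at least 2 individuals")
  Gc <- scale(G, center = TRUE, scale = FALSE)
  sigma_full <- crossprod(Gc) / n
  v <- diag(sigma_full)
  kept <- unname(which(v > 0))
  dropped <- unname(which(v <= 0))
  if (length(kept) == 0L)
    stop(errorCondition("all variants are monomorphic in the analyzed sample",
                        class = c("owscore_all_monomorphic", "owscore_error")))
  if (length(dropped))
    warning("dropping ", length(dropped), " monomorphic variant(s)")
  structure(list(sigma_hat = sigma_full[kept, kept, drop = FALSE],
                 sigma0_hat = v[kept],
                 kept_variants = kept,
                 dropped_variants = dropped,
                 n = n),
            class = "GenotypeCovariance")
}

#' Kinship-weighted trait quadratic form
#'
#' Computes sum_i y_i^T Phi_i y_i over families, the trait part of the score
#' test variance: Phi_i is twice the family kinship matrix and y_i the
#' centered (covariate-adjusted) trait of family i's analyzed members.
#'
#' @param trait a centered `TraitVector` (`grand_mean_removed` must be set).
#' @param phi a `KinshipBlocks` whose individuals match `trait$ids` in order.
#' @return positive scalar.
#' @export
trait_quadratic_form <- function(trait, phi) {
  stopifnot(inherits(trait, "TraitVector"), inherits(phi, "KinshipBlocks"))
  if (!trait$grand_mean_removed)
    stop("trait must be centered (see adjust_covariates)")
  ids <- phi_block_ids(phi)
  if (!identical(ids, trait$ids))
    stop("kinship block order does not match trait order; align samples first")
  y <- trait$values
  total <- 0
  offset <- 0L
  for (b in phi$blocks) {
    nb <- nrow(b)
    yb <- y[(offset + 1L):(offset + nb)]
    total <- total + drop(crossprod(yb, b %*% yb))
    offset <- offset + nb
  }
  if (total <= .Machine$double.eps * sum(y^2 + 1))
    stop(errorCondition("degenerate (constant) trait: quadratic form is zero",
                        class = c("owscore_degenerate_trait", "owscore_error")))
  total
}

# Per-variant score contributions u_m = sum_ij (g_ijm - gbar_m)(y_ij - ybar),
# over the kept variants of `cov`.
score_numerators <- function(geno, trait, cov) {
  G <- if (inherits(geno, "GenotypeMatrix")) geno$dosages else as.matrix(geno)
  y <- trait$values - mean(trait$values)  # defensive; ~0 shift if centered
  drop(crossprod(G[, cov$kept_variants, drop = FALSE], y))
}

new_test_result <- function(test, statistic, delta, df, p, u, quad_form_y,
                            n_variants_used, pvalue_method) {
  structure(list(test = test, statistic = statistic, scale_delta = delta,
                 df_d = df, p_value = p, per_variant_u = u,
                 quad_form_y = quad_form_y, n_variants_used = n_variants_used,
                 pvalue_method = pvalue_method),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.6g (delta = %.4g, df = %.4g), p = %.4g [%d variants]\n",
              x$test, x$statistic, x$scale_delta, x$df_d, x$p_value,
              x$n_variants_used))
  invisible(x)
}

#' Weighted (burden-type) retrospective score test
#'
#' Collapses the region into x_ij = sum_m w_m g_ijm and tests its association
#' with the centered trait: T = U^2 / V with
#' U = sum_ij (x_ij - xbar)(y_ij - ybar) and
#' V = (w^T Sigma w) * sum_i y_i^T Phi_i y_i, where Sigma is the estimated
#' genotype covariance (`covariance_mode = "full"`) or its diagonal
#' (`"diagonal"`). Under the null T is asymptotically chi-square with 1 df.
#'
#' @param geno aligned `GenotypeMatrix`.
#' @param trait centered `TraitVector`.
#' @param phi `KinshipBlocks` matching the trait order.
#' @param weights numeric weight vector, one entry per variant column of
#'   `geno` (monomorphic variants are dropped internally).
#' @param covariance_mode `"full"` or `"diagonal"`.
#' @return a `TestResult` (`scale_delta` = 1, `df_d` = 1).
#' @export
weighted_score_statistic <- function(geno, trait, phi, weights,
                                     covariance_mode = c("full", "diagonal")) {
  covariance_mode <- match.arg(covariance_mode)
  M <- ncol(if (inherits(geno, "GenotypeMatrix")) geno$dosages else geno)
  stopifnot(length(weights) == M)
  cov <- estimate_genotype_covariance(geno)
  q <- trait_quadratic_form(trait, phi)
  u <- score_numerators(geno, trait, cov)
  w <- weights[cov$kept_variants]
  U <- sum(w * u)
  wSw <- if (covariance_mode == "full")
    drop(crossprod(w, cov$sigma_hat %*% w))
  else
    sum(w^2 * cov$sigma0_hat)
  V <- wSw * q
  if (V <= 0)
    stop(errorCondition("degenerate variance (zero weights or trait)",
                        class = c("owscore_degenerate_variance", "owscore_error")))
  stat <- U^2 / V
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  new_test_result("WS-score", stat, 1, 1, p, u, q, length(cov$kept_variants),
                  "chisq1")
}

#' Madsen-Browning variant weights
#'
#' w_m = 1 / sqrt(N * q_m (1 - q_m)) with the allele frequency estimated with
#' a pseudocount over the full analyzed sample, q_m = (sum_ij g_ijm + 1) /
#' (2N + 2), so monomorphic variants still get a finite weight. Rarer variants
#' receive larger weights.
#'
#' @param geno aligned `GenotypeMatrix` (or dosage matrix).
#' @return numeric weight vector, one per variant column.
#' @export
madsen_browning_weights <- function(geno) {
  G <- if (inherits(geno, "GenotypeMatrix")) geno$dosages else as.matrix(geno)
  N <- nrow(G)
  q <- (colSums(G) + 1) / (2 * N + 2)
  1 / sqrt(N * q * (1 - q))
}

#' Optimally weighted score test (OW-score)
#'
#' The weighted score statistic with diagonal genotype covariance, maximised
#' over the weight vector. The maximiser is w = Sigma0^-1 u, giving
#'
#'   T = u^T Sigma0^-1 u / sum_i y_i^T Phi_i y_i
#'     = sum_m (u_m^2 / sigma_mm) / sum_i y_i^T Phi_i y_i,
#'
#' a sum of per-variant standardized score contributions. Its null
#' distribution is approximated by a moment-matched scaled chi-square
#' (default) or by the exact chi-square mixture with weights from the
#' eigenvalues of Sigma0^-1/2 Sigma Sigma0^-1/2 (see
#' [mixture_chisq_pvalue()]).
#'
#' @inheritParams weighted_score_statistic
#' @param pvalue_method `"scaled-chisq"` (moment matched) or `"mixture"`.
#' @param max_maf optional minor allele frequency ceiling; variants with
#'   sample MAF above it are excluded before testing.
#' @return a `TestResult` with `scale_delta`, `df_d`, `per_variant_u` and
#'   `quad_form_y` filled in.
#' @examples
#' rows <- data.frame(family_id = 1:4, individual_id = paste0("s", 1:4),
#'                    father_id = 0, mother_id = 0, sex = 1)
#' peds <- as_pedigree_list(rows)
#' phi <- phi_blocks(peds)
#' g <- genotype_matrix(matrix(c(0, 1, 0, 1), 4, 1,
#'                      dimnames = list(paste0("s", 1:4), "v1")))
#' y <- trait_vector(c(-1, 1, -1, 1), paste0("s", 1:4),
#'                   grand_mean_removed = TRUE)
#' ow_score_statistic(g, y, phi)  # statistic 4, p ~ 0.0455
#' @export
ow_score_statistic <- function(geno, trait, phi,
                               pvalue_method = c("scaled-chisq", "mixture"),
                               max_maf = NULL) {
  pvalue_method <- match.arg(pvalue_method)
  if (!is.null(max_maf)) geno <- filter_max_maf(geno, max_maf)
  cov <- estimate_genotype_covariance(geno)
  q <- trait_quadratic_form(trait, phi)
  u <- score_numerators(geno, trait, cov)
  stat <- sum(u^2 / cov$sigma0_hat) / q
  fit <- moment_match_scaled_chisq(cov)
  p <- if (pvalue_method == "mixture") mixture_chisq_pvalue(stat, cov)
       else scaled_chisq_pvalue(stat, fit)
  new_test_result("OW-score", stat, fit$delta, fit$df, p, u, q,
                  length(cov$kept_variants), pvalue_method)
}

filter_max_maf <- function(geno, max_maf) {
  stopifnot(inherits(geno, "GenotypeMatrix"))
  maf <- colMeans(geno$dosages) / 2
  maf <- pmin(maf, 1 - maf)
  keep <- maf <= max_maf
  if (!any(keep)) stop("no variants pass the MAF ceiling")
  genotype_matrix(geno$dosages[, keep, drop = FALSE],
                  geno$variant_meta[keep, , drop = FALSE], geno$sample_ids)
}

#' Write per-region test results as TSV
#'
#' One row per result; deterministic 15-significant-digit numeric formatting;
#' `#`-prefixed metadata header lines.
#'
#' @param results named list of `TestResult` objects (names = region/gene IDs).
#' @param path output path.
#' @param meta optional named character vector written as `# key: value` lines.
#' @return invisibly, the output path.
#' @export
write_results_tsv <- function(results, path, meta = NULL) {
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  hdr <- c(paste0("# owscore ", as.character(utils::packageVersion("owscore"))),
           if (length(meta)) paste0("# ", names(meta), ": ", meta))
  rows <- vapply(names(results), function(g) {
    r <- results[[g]]
    paste(g, r$n_variants_used, fmt(r$statistic), fmt(r$scale_delta),
          fmt(r$df_d), fmt(r$p_value), sep = "\t")
  }, "")
  writeLines(c(hdr,
               "gene_id\tn_variants_used\tstatistic\tdelta\tdf\tp_value",
               rows), path)
  invisible(path)
}
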