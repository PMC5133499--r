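#' Construct a trait vector
#'
#' @param values numeric trait values, one per individual.
#' @param ids individual IDs (same length/order as `values`).
#' @param is_adjusted has the trait been covariate-adjusted?
#' @param grand_mean_removed is the trait centered (mean zero)?
#' @return a `TraitVector`.
#' @export
trait_vector <- function(values, ids, is_adjusted = FALSE,
                         grand_mean_removed = FALSE) {
  stopifnot(length(values) == length(ids), is.numeric(values))
  if (grand_mean_removed &&
      abs(mean(values)) > 1e-10 * max(1, max(abs(values))))
    stop("trait flagged as centered but mean is not ~0")
  structure(list(values = as.numeric(values), ids = as.character(ids),
                 is_adjusted = is_adjusted,
                 grand_mean_removed = grand_mean_removed),
            class = "TraitVector")
}

#' @export
print.TraitVector <- function(x, ...) {
  cat("TraitVector:", length(x$values), "individuals",
      if (x$is_adjusted) "(covariate-adjusted)" else "",
      if (x$grand_mean_removed) "(centered)" else "", "\n")
  invisible(x)
}

#' Average repeated trait measurements per individual
#'
#' Takes the arithmetic mean of the named measurement columns (e.g. a blood
#' pressure measured at several exams) for each individual. Individuals
#' missing any of the named columns are dropped (complete case).
#'
#' @param pheno phenotype data.frame with `individual_id`.
#' @param trait_columns character vector of numeric column names to average.
#' @return a `TraitVector` (raw scale, not adjusted, not centered).
#' @export
average_repeated_measures <- function(pheno, trait_columns) {
  if (length(trait_columns) == 0L) stop("trait_columns must be non-empty")
  missing_cols <- setdiff(trait_columns, names(pheno))
  if (length(missing_cols))
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "))
  vals <- as.matrix(pheno[, trait_columns, drop = FALSE])
  if (!is.numeric(vals)) stop("trait columns must be numeric")
  ok <- rowSums(is.na(vals)) == 0L
  if (!any(ok)) stop("no individual has complete trait measurements")
  trait_vector(rowMeans(vals[ok, , drop = FALSE]), pheno$individual_id[ok])
}

#' Regress covariates out of a trait
#'
#' Fits ordinary least squares of the trait on an intercept plus the covariate
#' columns and returns the residuals as the analysis trait. The residuals have
#' exactly zero mean and are orthogonal to every covariate column; family
#' structure is deliberately ignored at this stage (two-stage procedure: plain
#' covariate regression, then a score test whose variance accounts for
#' relatedness).
#'
#' @param trait a `TraitVector`.
#' @param covariates numeric matrix/data.frame of covariates (rows matching
#'   `trait`), or `NULL` for intercept-only (centering).
#' @return a `TraitVector` of residuals with `is_adjusted` and
#'   `grand_mean_removed` set.
#' @examples
#' tv <- trait_vector(c(1, 2, 3), c("a", "b", "c"))
#' adjust_covariates(tv, NULL)$values  # -1 0 1
#' @export
adjust_covariates <- function(trait, covariates = NULL) {
  stopifnot(inherits(trait, "TraitVector"))
  y <- trait$values
  n <- length(y)
  if (is.null(covariates)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    if (anyNA(covariates)) stop("covariate matrix must be complete")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
    X <- cbind("(Intercept)" = 1, covariates)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(errorCondition(
      paste0("rank-deficient covariate design; collinear column(s): ",
             paste(bad, collapse = ", ")),
      class = c("owscore_collinear_covariates", "owscore_error")))
  }
  res <- qr.resid(qrX, y)
  trait_vector(res - mean(res), trait$ids,
               is_adjusted = !is.null(covariates), grand_mean_removed = TRUE)
}
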