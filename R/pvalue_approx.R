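#' Moment-matched scaled chi-square fit for the OW-score null
#'
#' Under the null the OW-score statistic behaves as a quadratic form whose
#' mean and variance are mu_T = trace(Sigma Sigma0^-1) and
#' sigma2_T = 2 trace((Sigma Sigma0^-1)^2). Matching both moments to
#' delta * chi-square(d) gives delta = sigma2_T / (2 mu_T) and
#' d = 2 mu_T^2 / sigma2_T.
#'
#' @param cov a `GenotypeCovariance`.
#' @return a `ScaledChiSquareFit`: list with `mu_T`, `sigma2_T`, `delta`, `df`.
#' @export
moment_match_scaled_chisq <- function(cov) {
  stopifnot(inherits(cov, "GenotypeCovariance"))
  # B = Sigma Sigma0^-1 (columns of Sigma scaled by 1/sigma_mm)
  B <- sweep(cov$sigma_hat, 2, cov$sigma0_hat, `/`)
  mu <- sum(diag(B))
  sigma2 <- 2 * sum(B * t(B))  # 2 trace(B B)
  if (!is.finite(mu) || !is.finite(sigma2) || mu <= 0 || sigma2 <= 0)
    stop("non-finite or non-positive null moments")
  structure(list(mu_T = mu, sigma2_T = sigma2,
                 delta = sigma2 / (2 * mu), df = 2 * mu^2 / sigma2),
            class = "ScaledChiSquareFit")
}

#' @export
print.ScaledChiSquareFit <- function(x, ...) {
  cat(sprintf("scaled chi-square fit: delta = %.6g, df = %.6g (mu = %.6g, sigma2 = %.6g)\n",
              x$delta, x$df, x$mu_T, x$sigma2_T))
  invisible(x)
}

#' Scaled chi-square upper-tail p-value
#'
#' p = P(chi-square(df) >= statistic / delta), evaluated on the log scale so
#' extreme statistics still yield reportable p-values (~1e-300).
#'
#' @param statistic nonnegative test statistic.
#' @param fit a `ScaledChiSquareFit`.
#' @return p-value in (0, 1].
#' @export
scaled_chisq_pvalue <- function(statistic, fit) {
  stopifnot(statistic >= 0, inherits(fit, "ScaledChiSquareFit"))
  if (statistic == 0) return(1)
  lp <- stats::pchisq(statistic / fit$delta, df = fit$df,
                      lower.tail = FALSE, log.p = TRUE)
  max(exp(lp), .Machine$double.xmin)
}

#' Chi-square mixture p-value by characteristic-function inversion
#'
#' Under the null the OW-score statistic is asymptotically distributed as
#' sum_k lambda_k chi-square_1 with lambda_k the eigenvalues of
#' Sigma0^-1/2 Sigma Sigma0^-1/2. The upper-tail probability is evaluated by
#' Imhof's numerical inversion of the characteristic function,
#'
#'   P(Q > x) = 1/2 + (1/pi) int_0^inf sin(theta(v)) / (v rho(v)) dv,
#'
#' with theta(v) = (1/2) sum arctan(lambda_k v) - x v / 2 and
#' rho(v) = prod (1 + lambda_k^2 v^2)^(1/4). Eigenvalues below 1e-10 times the
#' largest are truncated to zero. Serves as a cross-check of the scaled
#' chi-square approximation; on integration failure it falls back to the
#' moment-matched p-value with a warning.
#'
#' @param statistic nonnegative test statistic.
#' @param cov a `GenotypeCovariance`.
#' @param abs_tol absolute accuracy requested from the quadrature.
#' @return p-value in (0, 1].
#' @export
mixture_chisq_pvalue <- function(statistic, cov, abs_tol = 1e-9) {
  stopifnot(statistic >= 0, inherits(cov, "GenotypeCovariance"))
  if (statistic == 0) return(1)
  s <- 1 / sqrt(cov$sigma0_hat)
  K <- cov$sigma_hat * tcrossprod(s)  # Sigma0^-1/2 Sigma Sigma0^-1/2
  lambda <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > 1e-10 * max(lambda)]
  p <- tryCatch(imhof_upper_tail(statistic, lambda, abs_tol),
                error = function(e) NA_real_)
  if (is.na(p) || p < -1e-6 || p > 1 + 1e-6) {
    warning("characteristic-function inversion failed; ",
            "falling back to the scaled chi-square approximation")
    return(scaled_chisq_pvalue(statistic, moment_match_scaled_chisq(cov)))
  }
  min(max(p, .Machine$double.xmin), 1)
}

# Imhof (1961) upper-tail probability of sum_k lambda_k chi^2_1 at x.
#
# The integrand oscillates with an algebraically decaying envelope, so the
# infinite range is handled by integrating successive chunks (each spanning at
# most ~one oscillation, chunk length pi / max|d theta / d v|) and
# accelerating the alternating partial sums by iterated averaging (Euler
# transformation). Absolute accuracy ~abs_tol down to p of about 1e-8; the
# caller falls back to the scaled chi-square fit if the result is unusable.
imhof_upper_tail <- function(x, lambda, abs_tol = 1e-9) {
  if (length(lambda) == 1L)
    return(stats::pchisq(x / lambda, df = 1, lower.tail = FALSE))
  integrand <- function(v) {
    out <- numeric(length(v))
    nz <- v > 0
    vv <- v[nz]
    theta <- 0.5 * colSums(atan(outer(lambda, vv))) - x * vv / 2
    log_rho <- 0.25 * colSums(log1p(outer(lambda^2, vv^2)))
    out[nz] <- sin(theta) / (vv * exp(log_rho))
    out[!nz] <- 0.5 * (sum(lambda) - x)  # limit as v -> 0
    out
  }
  chunk <- pi / (0.5 * (x + sum(lambda)) + 1e-12)
  max_chunks <- 50000L
  partial <- numeric(0)
  S <- 0
  est_prev <- Inf
  for (j in seq_len(max_chunks)) {
    lo <- (j - 1) * chunk
    piece <- stats::integrate(integrand, lo, lo + chunk,
                              rel.tol = 1e-10, abs.tol = abs_tol / 100,
                              subdivisions = 200L)$value
    S <- S + piece
    partial <- c(partial, S)
    if (length(partial) > 20L) partial <- partial[-1]
    # iterated averaging of the tail of partial sums
    acc <- partial
    while (length(acc) > 1L) acc <- (acc[-1] + acc[-length(acc)]) / 2
    est <- acc
    if (j >= 12L && abs(est - est_prev) < abs_tol / 4 &&
        abs(piece) < abs_tol) {
      return(0.5 + est / pi)
    }
    est_prev <- est
  }
  stop("characteristic-function inversion did not converge")
}
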