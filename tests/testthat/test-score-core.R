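test_that("genotype covariance uses divisor N and the grand mean", {
  ids <- paste0("s", 1:4)
  dos <- matrix(c(0, 1, 0, 1, 0, 0, 1, 1), 4, 2,
                dimnames = list(ids, c("v1", "v2")))
  cov <- estimate_genotype_covariance(dos)
  expect_equal(cov$sigma_hat, matrix(c(0.25, 0, 0, 0.25), 2, 2,
                                     dimnames = list(c("v1", "v2"),
                                                     c("v1", "v2"))))
  expect_equal(cov$sigma0_hat, c(v1 = 0.25, v2 = 0.25))

  dup <- cbind(dos, v3 = dos[, 1])
  cov2 <- estimate_genotype_covariance(dup)
  expect_equal(cov2$sigma_hat["v1", "v3"], cov2$sigma_hat["v1", "v1"])

  withconst <- cbind(dos, v4 = rep(1, 4))
  expect_warning(cov3 <- estimate_genotype_covariance(withconst),
                 "monomorphic")
  expect_equal(cov3$dropped_variants, 3L)
  expect_equal(cov3$kept_variants, c(1L, 2L))

  expect_error(estimate_genotype_covariance(matrix(1, 4, 2)),
               class = "owscore_all_monomorphic")
})

test_that("trait quadratic form expands blockwise over Phi", {
  toy <- toy_single_variant()
  expect_equal(trait_quadratic_form(toy$trait, toy$phi), 4)

  ped <- validate_pedigree(nuclear_rows())
  phi <- phi_blocks(list(ped))
  ids <- phi_block_ids(phi)
  y <- c(f = 1, m = 1, c1 = -1, c2 = -1)[ids]
  tv <- trait_vector(unname(y), ids, grand_mean_removed = TRUE)
  expect_equal(trait_quadratic_form(tv, phi), 1)

  tv0 <- trait_vector(rep(0, 4), ids, grand_mean_removed = TRUE)
  expect_error(trait_quadratic_form(tv0, phi),
               class = "owscore_degenerate_trait")
})

test_that("weighted score statistic matches the hand-computed toy", {
  toy <- toy_single_variant()
  r <- weighted_score_statistic(toy$geno, toy$trait, toy$phi, weights = 1)
  expect_equal(r$per_variant_u, c(v1 = 2))  # U
  expect_equal(r$quad_form_y, 4)
  expect_equal(r$statistic, 4)              # U^2 / (0.25 * 4)
  expect_equal(r$p_value, pchisq(4, 1, lower.tail = FALSE))

  r5 <- weighted_score_statistic(toy$geno, toy$trait, toy$phi, weights = 5)
  expect_equal(r5$statistic, r$statistic)   # scalar weight cancels in U^2/V

  y0 <- trait_vector(c(1, -1, -1, 1), paste0("s", 1:4),
                     grand_mean_removed = TRUE)
  r0 <- weighted_score_statistic(toy$geno, y0, toy$phi, weights = 1)
  expect_equal(r0$statistic, 0)             # orthogonal trait: U = 0
  expect_equal(r0$p_value, 1)
})

test_that("Madsen-Browning weights use the pseudocount frequency", {
  ids <- paste0("s", 1:4)
  dos <- matrix(c(0, 1, 1, 1, 0, 0, 0, 0), 4, 2,
                dimnames = list(ids, c("v1", "v2")))
  w <- madsen_browning_weights(dos)
  expect_equal(w[["v1"]], 1 / sqrt(4 * 0.4 * 0.6))   # q = (3+1)/(8+2)
  expect_equal(w[["v2"]], 1 / sqrt(4 * 0.1 * 0.9))   # q = 1/10, finite
  # rarer variant gets the strictly larger weight
  expect_gt(w[["v2"]], w[["v1"]])
})

test_that("OW-score toys match the hand computations", {
  toy <- toy_single_variant()
  r <- ow_score_statistic(toy$geno, toy$trait, toy$phi)
  expect_equal(r$statistic, 4)
  expect_equal(r$scale_delta, 1)
  expect_equal(r$df_d, 1)
  expect_equal(r$p_value, pchisq(4, 1, lower.tail = FALSE))

  toy2 <- toy_two_variant()
  r2 <- ow_score_statistic(toy2$geno, toy2$trait, toy2$phi)
  expect_equal(r2$per_variant_u, c(v1 = 2, v2 = 0))
  expect_equal(r2$statistic, 4)             # (16 + 0)/0.25 / 4 / 4
  expect_equal(r2$scale_delta, 1)
  expect_equal(r2$df_d, 2)
  expect_equal(r2$p_value, exp(-2))         # chi2_2 upper tail at 4

  y0 <- trait_vector(c(-1, 1, 1, -1), paste0("s", 1:4),
                     grand_mean_removed = TRUE)
  r0 <- ow_score_statistic(toy2$geno, y0, toy2$phi)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
})

test_that("the two OW-score forms agree and the optimum dominates all weights", {
  set.seed(8)
  for (i in 1:10) {
    inst <- random_instance(n = 30 + i, M = 5)
    cov <- estimate_genotype_covariance(inst$geno)
    q <- trait_quadratic_form(inst$trait, inst$phi)
    u <- drop(crossprod(scale(inst$geno$dosages, scale = FALSE),
                        inst$trait$values))
    quad_form <- drop(crossprod(u, (u / cov$sigma0_hat))) / q  # u' S0^-1 u / q
    sum_form <- sum(u^2 / cov$sigma0_hat) / q
    expect_equal(quad_form, sum_form, tolerance = 1e-12)
    r <- ow_score_statistic(inst$geno, inst$trait, inst$phi)
    expect_equal(r$statistic, sum_form, tolerance = 1e-12)

    # T0(w) <= T_OW for random w, equality at w = Sigma0^-1 u
    for (k in 1:20) {
      w <- rnorm(5)
      t0 <- sum(w * u)^2 / (sum(w^2 * cov$sigma0_hat) * q)
      expect_lte(t0, r$statistic + 1e-10)
      # and T0(w) equals the diagonal-covariance weighted score test
      rw <- weighted_score_statistic(inst$geno, inst$trait, inst$phi, w,
                                     covariance_mode = "diagonal")
      expect_equal(rw$statistic, t0, tolerance = 1e-10)
    }
    w_opt <- u / cov$sigma0_hat
    t_opt <- sum(w_opt * u)^2 / (sum(w_opt^2 * cov$sigma0_hat) * q)
    expect_equal(t_opt, r$statistic, tolerance = 1e-10)
  }
})

test_that("statistics are invariant to trait location/scale changes", {
  set.seed(13)
  inst <- random_instance(n = 45, M = 4)
  raw <- inst$trait$values + 7               # uncentered raw trait
  t1 <- adjust_covariates(trait_vector(raw, inst$trait$ids))
  t2 <- adjust_covariates(trait_vector(3.7 * raw - 11, inst$trait$ids))
  r1 <- ow_score_statistic(inst$geno, t1, inst$phi)
  r2 <- ow_score_statistic(inst$geno, t2, inst$phi)
  expect_equal(r2$statistic, r1$statistic, tolerance = 1e-10)
  w <- madsen_browning_weights(inst$geno)
  s1 <- weighted_score_statistic(inst$geno, t1, inst$phi, w)
  s2 <- weighted_score_statistic(inst$geno, t2, inst$phi, w)
  expect_equal(s2$statistic, s1$statistic, tolerance = 1e-10)
})

test_that("for unrelated singletons and one variant, T equals N r^2", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(20:80, 1)
    ids <- paste0("s", seq_len(n))
    peds <- singleton_peds(n)
    repeat {
      g <- sample(0:2, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
      if (var(g) > 0) break
    }
    y <- rnorm(n)
    tv <- adjust_covariates(trait_vector(y, ids))
    r <- ow_score_statistic(genotype_matrix(matrix(g, n, 1,
                                                   dimnames = list(ids, "v"))),
                            tv, phi_blocks(peds))
    expect_equal(r$statistic, n * cor(g, y)^2, tolerance = 1e-10)
  }
})

test_that("max_maf excludes common variants from the test", {
  ids <- paste0("s", 1:10)
  dos <- cbind(rare = c(1, rep(0, 9)), common = rep(c(0, 1), 5))
  rownames(dos) <- ids
  inst <- list(geno = genotype_matrix(dos), peds = singleton_peds(10))
  tv <- adjust_covariates(trait_vector(rnorm(10), ids))
  r <- ow_score_statistic(inst$geno, tv, phi_blocks(inst$peds), max_maf = 0.1)
  expect_equal(r$n_variants_used, 1L)
})

test_that("results table round-trips through the TSV writer", {
  toy <- toy_single_variant()
  r <- ow_score_statistic(toy$geno, toy$trait, toy$phi)
  path <- tempfile(fileext = ".tsv")
  write_results_tsv(list(GENE1 = r), path, meta = c(seed = "1"))
  lines <- readLines(path)
  expect_true(any(grepl("^# seed: 1", lines)))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(tab$statistic, 4)
  expect_equal(tab$p_value, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-14)
})
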