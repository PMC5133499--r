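test_that("founder genotypes follow Hardy-Weinberg and are reproducible", {
  expect_error(draw_founder_genotypes(c(0.6, 0.1), 10), "maf")
  expect_error(draw_founder_genotypes(0, 10))

  g <- draw_founder_genotypes(rep(0.5, 200), 500, seed = 2)
  se <- sqrt(0.5 / (500 * 200))  # var of dosage = 2pq = 0.5 at p = 0.5
  expect_lt(abs(mean(g) - 1.0), 3 * se)

  g2 <- draw_founder_genotypes(rep(0.01, 2000), 5000, seed = 3)
  het <- mean(g2 == 1)
  p_het <- 2 * 0.01 * 0.99
  expect_lt(abs(het - p_het), 3 * sqrt(p_het * (1 - p_het) / length(g2)))

  expect_identical(draw_founder_genotypes(c(0.1, 0.2), 50, seed = 11),
                   draw_founder_genotypes(c(0.1, 0.2), 50, seed = 11))
})

test_that("gene drop transmits one allele per parent per meiosis", {
  ped <- validate_pedigree(nuclear_rows())
  # both parents dosage 0 -> all offspring dosage 0
  zero <- matrix(0, 2, 5)
  g <- gene_drop(ped, zero, seed = 1)
  expect_true(all(g$dosages == 0))

  # one heterozygous parent, other 0: offspring carrier probability 1/2.
  # 4000 variants = 4000 independent drops through each child.
  M <- 4000
  fg <- rbind(rep(1, M), rep(0, M))
  g2 <- gene_drop(ped, fg, seed = 5)
  kids <- g2$dosages[c("c1", "c2"), ]
  expect_true(all(kids %in% 0:1))  # at most the single parental copy
  carrier <- mean(kids == 1)
  expect_lt(abs(carrier - 0.5), 3 * sqrt(0.25 / length(kids)))

  # allele conservation: total copies never exceed founder copies
  fg3 <- matrix(rbinom(2 * M, 2, 0.3), 2, M)
  g3 <- gene_drop(ped, fg3, seed = 6)
  founder_copies <- colSums(fg3)
  expect_true(all(colSums(g3$dosages[c("c1", "c2"), , drop = FALSE]) <=
                    2 * founder_copies))
  expect_true(all(g3$dosages[, founder_copies == 0] == 0))

  expect_error(gene_drop(ped, matrix(0, 3, 2)), "founder")
})

test_that("simulated trait matches its variance decomposition", {
  # h2 = 0, beta = 0: iid N(a, sigma^2)
  cfg0 <- simulation_config(n_pedigrees = 400,
                            pedigree_template = make_template_pedigree(
                              n_children = 2, n_g3 = 2, n_g4 = 2),
                            M = 2, maf = c(0.1, 0.2), h2 = 0,
                            sigma_total = 10, intercept = 80,
                            covariate_effects = numeric(0))
  set.seed(21)
  st0 <- simulate_study(cfg0)
  n <- length(st0$trait$values)
  expect_gt(n, 5000)
  expect_lt(abs(mean(st0$trait$values) - 80), 3 * 10 / sqrt(n))
  # sampling SE of a variance estimate ~ sigma^2 sqrt(2/n)
  expect_lt(abs(var(st0$trait$values) - 100), 3 * 100 * sqrt(2 / n))

  # h2 = 0.5 full sibs: cov(sib1, sib2) = 0.5 * 0.5 * sigma^2
  sib_rows <- nuclear_rows()
  cfg_sib <- simulation_config(n_pedigrees = 4000,
                               pedigree_template = validate_pedigree(sib_rows),
                               M = 1, maf = c(0.1, 0.1), h2 = 0.5,
                               sigma_total = 1, intercept = 0,
                               covariate_effects = numeric(0))
  set.seed(22)
  st <- simulate_study(cfg_sib)
  idx1 <- grep("_c1$", st$trait$ids)
  idx2 <- grep("_c2$", st$trait$ids)
  sib_cov <- cov(st$trait$values[idx1], st$trait$values[idx2])
  expect_lt(abs(sib_cov - 0.25), 3 * sqrt(2 / length(idx1)))

  # single causal variant: +beta per allele on the mean
  cfg_b <- simulation_config(n_pedigrees = 1500,
                             pedigree_template = validate_pedigree(sib_rows),
                             M = 1, maf = c(0.3, 0.3), causal_indices = 1,
                             beta = 1, h2 = 0, sigma_total = 1, intercept = 0,
                             covariate_effects = numeric(0))
  set.seed(23)
  stb <- simulate_study(cfg_b)
  fit <- coef(lm(stb$trait$values ~ stb$geno$dosages[, 1]))
  expect_lt(abs(fit[2] - 1), 3 * 0.05)
})

test_that("trait covariance within a pedigree follows h2 * Phi + (1-h2) * I", {
  ped <- validate_pedigree(nuclear_rows())
  cfg <- simulation_config(n_pedigrees = 1, pedigree_template = ped,
                           M = 1, maf = c(0.2, 0.2), h2 = 0.4, sigma_total = 1,
                           intercept = 0, covariate_effects = numeric(0))
  set.seed(31)
  reps <- 4000
  Y <- matrix(NA_real_, reps, 4)
  for (r in seq_len(reps)) Y[r, ] <- simulate_study(cfg)$trait$values
  emp <- cov(Y)
  Phi <- phi_blocks(list(ped))$blocks[[1]]
  theo <- 0.4 * Phi + 0.6 * diag(4)
  expect_true(all(abs(emp - theo) < 3 * sqrt(2 / reps) + 0.02))
})

test_that("simulated studies are seed-deterministic and round-trip disk IO", {
  cfg <- small_config()
  s1 <- simulate_study(cfg, seed = 77)
  s2 <- simulate_study(cfg, seed = 77)
  expect_identical(s1$geno$dosages, s2$geno$dosages)
  expect_identical(s1$trait$values, s2$trait$values)

  dir <- tempfile()
  paths <- write_study(s1, dir)
  peds <- read_pedigrees(paths[["fam"]])
  geno <- read_genotypes(paths[["genotypes"]])
  pheno <- read_phenotypes(paths[["phenotypes"]])
  al <- align_samples(geno, pheno, peds)
  expect_equal(al$geno$sample_ids, s1$geno$sample_ids)
  expect_equal(al$pheno$y, s1$trait$values)
  # dosages equal up to minor-allele recoding on read
  flip <- colSums(s1$geno$dosages) > nrow(s1$geno$dosages)
  expected <- s1$geno$dosages
  expected[, flip] <- 2 - expected[, flip]
  expect_equal(unname(al$geno$dosages), unname(expected))
})

test_that("ascertainment rules filter pedigrees as stated", {
  cfg <- small_config(causal_indices = 1, beta = 3,
                      maf = c(rep(0.05, 1), rep(0.01, 19)))
  set.seed(41)
  st <- simulate_study(cfg)
  all_kept <- ascertain_pedigrees(st, "random", keep_fraction = 1)
  expect_identical(names(all_kept$peds), names(st$peds))

  asc <- tryCatch(ascertain_pedigrees(st, "proband_extreme",
                                      threshold_quantile = 0.5),
                  error = function(e) NULL)
  if (!is.null(asc)) {
    thr <- quantile(st$trait$values, 0.5)
    probands <- vapply(asc$peds, function(p) p$id[!p$founder][1], "")
    pt <- asc$trait$values[match(probands, asc$trait$ids)]
    expect_true(all(pt > thr))
    expect_equal(phi_block_ids(asc$phi), asc$geno$sample_ids)
  }
})

test_that("extreme-proband ascertainment enriches causal carriers", {
  # positive-effect rare variant: kept pedigrees carry it more often
  ped <- validate_pedigree(nuclear_rows())
  cfg <- simulation_config(n_pedigrees = 40, pedigree_template = ped,
                           M = 1, maf = c(0.05, 0.05), causal_indices = 1,
                           beta = 2, h2 = 0, sigma_total = 1, intercept = 0,
                           covariate_effects = numeric(0))
  set.seed(51)
  pop_freq <- c(); asc_freq <- c()
  for (r in 1:300) {
    st <- simulate_study(cfg)
    pop_freq <- c(pop_freq, mean(st$geno$dosages) / 2)
    asc <- tryCatch(ascertain_pedigrees(st, "proband_extreme",
                                        threshold_quantile = 0.9),
                    error = function(e) NULL)
    if (!is.null(asc)) asc_freq <- c(asc_freq, mean(asc$geno$dosages) / 2)
  }
  expect_gt(mean(asc_freq), mean(pop_freq))
  expect_gt(mean(asc_freq) - mean(pop_freq),
            2 * sd(asc_freq) / sqrt(length(asc_freq)))
})
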