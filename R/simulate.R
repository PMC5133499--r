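#' Simulation configuration
#'
#' Holds every parameter of a synthetic pedigree study. The defaults emulate
#' the scale of a large multiplex family study: 20 pedigrees of 42 members
#' (840 individuals, 4 generations), regions of 100 rare variants with minor
#' allele frequencies uniform on (0.001, 0.05), a quantitative trait on a
#' blood-pressure-like scale (intercept 80, total SD 10 before covariate and
#' variant effects) with polygenic heritability 0.3, and four covariates
#' (binary sex, continuous age, two binary exposure indicators).
#'
#' @param n_pedigrees number of pedigrees.
#' @param pedigree_template a `Pedigree` used (re-labelled) for every family,
#'   or `NULL` for the default 42-member template from
#'   [make_template_pedigree()].
#' @param M number of variants per region.
#' @param maf either a length-2 vector `c(lo, hi)` (MAFs drawn uniformly) or a
#'   length-`M` vector of fixed frequencies, all in (0, 0.5].
#' @param causal_indices variant indices (in 1..M) with nonzero trait effect.
#' @param beta per-causal-variant effect sizes (trait units per minor allele),
#'   same length as `causal_indices`.
#' @param h2 polygenic heritability in [0, 1): fraction of `sigma_total^2`
#'   contributed by a kinship-correlated polygenic component. Variance
#'   explained by `beta` is additional to `sigma_total^2`, not carved out.
#' @param sigma_total trait standard deviation around the covariate + variant
#'   mean (polygenic + residual).
#' @param intercept trait intercept `a`.
#' @param covariate_effects named numeric vector of effects for the generated
#'   covariates `sex`, `age`, `bpmed`, `smoke` (trait units per covariate
#'   unit); use `numeric(0)` for no covariates.
#' @param ascertainment `"random"` or `"proband_extreme"`.
#' @param threshold_quantile proband trait quantile for
#'   `"proband_extreme"` ascertainment.
#' @return a `SimulationConfig`.
#' @export
simulation_config <- function(n_pedigrees = 20L,
                              pedigree_template = NULL,
                              M = 100L,
                              maf = c(0.001, 0.05),
                              causal_indices = integer(0),
                              beta = numeric(0),
                              h2 = 0.3,
                              sigma_total = 10,
                              intercept = 80,
                              covariate_effects = c(sex = -2, age = 0.05,
                                                    bpmed = 3, smoke = 1.5),
                              ascertainment = c("random", "proband_extreme"),
                              threshold_quantile = 0.9) {
  ascertainment <- match.arg(ascertainment)
  if (is.null(pedigree_template)) pedigree_template <- make_template_pedigree()
  stopifnot(inherits(pedigree_template, "Pedigree"),
            n_pedigrees >= 1, M >= 1,
            length(maf) %in% c(2L, M), all(maf > 0), all(maf <= 0.5),
            length(beta) == length(causal_indices),
            all(causal_indices %in% seq_len(M)),
            h2 >= 0, h2 < 1, sigma_total > 0)
  structure(list(n_pedigrees = as.integer(n_pedigrees),
                 pedigree_template = pedigree_template,
                 M = as.integer(M), maf = maf,
                 causal_indices = as.integer(causal_indices), beta = beta,
                 h2 = h2, sigma_total = sigma_total, intercept = intercept,
                 covariate_effects = covariate_effects,
                 ascertainment = ascertainment,
                 threshold_quantile = threshold_quantile),
            class = "SimulationConfig")
}

#' Default multi-generation pedigree template
#'
#' Builds a 4-generation pedigree: a founder couple; `n_children` children
#' each with a married-in spouse; `n_g3` grandchildren per second-generation
#' couple, the first of whom marries in a spouse; and `n_g4`
#' great-grandchildren per third-generation couple. The defaults give 42
#' members (10 founders), so 20 such pedigrees approximate the ~850-member
#' studies the test family targets.
#'
#' @param family_id family identifier.
#' @param n_children,n_g3,n_g4 sibship sizes per generation.
#' @return a `Pedigree`.
#' @export
make_template_pedigree <- function(family_id = "ped1", n_children = 4L,
                                   n_g3 = 3L, n_g4 = 4L) {
  rows <- list()
  add <- function(id, fa, mo, sex)
    rows[[length(rows) + 1L]] <<- data.frame(
      family_id = family_id, individual_id = id, father_id = fa,
      mother_id = mo, sex = sex, stringsAsFactors = FALSE)
  add("g1_f", "0", "0", "1"); add("g1_m", "0", "0", "2")
  for (i in seq_len(n_children)) {
    kid <- paste0("g2_", i)
    sp <- paste0("g2_", i, "sp")
    ksex <- if (i %% 2) "1" else "2"
    add(kid, "g1_f", "g1_m", ksex)
    add(sp, "0", "0", if (ksex == "1") "2" else "1")
    fa2 <- if (ksex == "1") kid else sp
    mo2 <- if (ksex == "1") sp else kid
    for (j in seq_len(n_g3)) {
      g3 <- paste0("g3_", i, "_", j)
      gsex <- if (j %% 2) "2" else "1"
      add(g3, fa2, mo2, gsex)
      if (j == 1L) {
        g3sp <- paste0(g3, "sp")
        add(g3sp, "0", "0", if (gsex == "1") "2" else "1")
        fa3 <- if (gsex == "1") g3 else g3sp
        mo3 <- if (gsex == "1") g3sp else g3
        for (k in seq_len(n_g4))
          add(paste0("g4_", i, "_", k), fa3, mo3, if (k %% 2) "1" else "2")
      }
    }
  }
  validate_pedigree(do.call(rbind, rows))
}

relabel_pedigree <- function(ped, family_id) {
  map <- function(x) ifelse(is.na(x), NA, paste0(family_id, "_", x))
  structure(list(family_id = family_id, id = map(ped$id),
                 father = map(ped$father), mother = map(ped$mother),
                 sex = ped$sex, founder = ped$founder),
            class = "Pedigree")
}

#' Draw founder genotypes under Hardy-Weinberg equilibrium
#'
#' Each founder dosage is the sum of two independent Bernoulli(maf) allele
#' draws per variant.
#'
#' @param maf per-variant minor allele frequencies, each in (0, 0.5].
#' @param n_founders number of founders.
#' @param seed optional integer seed.
#' @return `n_founders` x `length(maf)` dosage matrix.
#' @export
draw_founder_genotypes <- function(maf, n_founders, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(maf > 0), all(maf <= 0.5), n_founders >= 1)
  M <- length(maf)
  matrix(stats::rbinom(n_founders * M, 2L, rep(maf, each = n_founders)),
         nrow = n_founders, ncol = M)
}

#' Drop founder genotypes through a pedigree
#'
#' Mendelian transmission: every non-founder receives one allele from each
#' parent, chosen uniformly and independently per variant per meiosis
#' (unlinked variants).
#'
#' @param ped a `Pedigree` (topologically ordered).
#' @param founder_genotypes dosage matrix whose rows match `ped`'s founders in
#'   pedigree order.
#' @param seed optional integer seed.
#' @param variant_meta optional variant metadata for the returned object.
#' @return a `GenotypeMatrix` for all pedigree members.
#' @export
gene_drop <- function(ped, founder_genotypes, seed = NULL, variant_meta = NULL) {
  stopifnot(inherits(ped, "Pedigree"))
  if (!is.null(seed)) set.seed(seed)
  founder_genotypes <- as.matrix(founder_genotypes)
  if (nrow(founder_genotypes) != sum(ped$founder))
    stop("founder genotype rows (", nrow(founder_genotypes),
         ") do not match founder count (", sum(ped$founder), ")")
  n <- length(ped$id)
  M <- ncol(founder_genotypes)
  A1 <- matrix(0L, n, M)
  A2 <- matrix(0L, n, M)
  pos <- seq_len(n); names(pos) <- ped$id
  frow <- 0L
  for (i in seq_len(n)) {
    if (ped$founder[i]) {
      frow <- frow + 1L
      d <- founder_genotypes[frow, ]
      A1[i, ] <- as.integer(d >= 1)  # heterozygote's copy on the first strand
      A2[i, ] <- as.integer(d == 2)
    } else {
      p <- pos[[ped$father[i]]]
      q <- pos[[ped$mother[i]]]
      A1[i, ] <- ifelse(stats::runif(M) < 0.5, A1[p, ], A2[p, ])
      A2[i, ] <- ifelse(stats::runif(M) < 0.5, A1[q, ], A2[q, ])
    }
  }
  dos <- A1 + A2
  rownames(dos) <- ped$id
  if (is.null(variant_meta)) {
    colnames(dos) <- paste0("1:", seq_len(M))
    genotype_matrix(dos)
  } else {
    genotype_matrix(dos, variant_meta, ped$id)
  }
}

# length-M maf = fixed per-variant list (wins when M == 2); length-2 = U(lo, hi)
draw_maf <- function(config) {
  if (length(config$maf) == config$M) return(config$maf)
  stats::runif(config$M, config$maf[1], config$maf[2])
}

# Cholesky factors of the Phi blocks (upper triangular), with a small ridge
# fallback for numerically semi-definite blocks.
phi_chol <- function(phi) {
  lapply(phi$blocks, function(b) {
    tryCatch(chol(b),
             error = function(e) chol(b + diag(1e-8, nrow(b))))
  })
}

# Kinship-correlated polygenic draw: per family, t(chol(Phi)) %*% z scaled to
# variance h2 * sigma^2.
draw_polygenic <- function(chol_blocks, h2, sigma_total) {
  if (h2 == 0) return(rep(0, sum(vapply(chol_blocks, nrow, 1L))))
  unlist(lapply(chol_blocks, function(R)
    drop(crossprod(R, stats::rnorm(nrow(R)))) * sqrt(h2) * sigma_total),
    use.names = FALSE)
}

draw_covariates <- function(n, covariate_effects) {
  if (length(covariate_effects) == 0L) return(NULL)
  gen <- list(
    sex = function(n) stats::rbinom(n, 1L, 0.5),
    age = function(n) round(stats::runif(n, 20, 80)),
    bpmed = function(n) stats::rbinom(n, 1L, 0.3),
    smoke = function(n) stats::rbinom(n, 1L, 0.25))
  X <- vapply(names(covariate_effects), function(nm) {
    if (!is.null(gen[[nm]])) gen[[nm]](n) else stats::rnorm(n)
  }, numeric(n))
  matrix(X, nrow = n, dimnames = list(NULL, names(covariate_effects)))
}

#' Simulate a quantitative trait on given genotypes
#'
#' y = a + X c + sum_causal beta_m g_m + polygenic + e, where the polygenic
#' component is multivariate normal with covariance h2 * sigma_total^2 * Phi
#' per family and e is iid normal with variance (1 - h2) * sigma_total^2.
#' Variance explained by `beta` is additional to `sigma_total^2`.
#'
#' @param geno a `GenotypeMatrix` covering all study members, in the order of
#'   `phi`'s blocks.
#' @param phi a `KinshipBlocks` over the same individuals.
#' @param config a `SimulationConfig`.
#' @param seed optional integer seed.
#' @return list with `trait` (raw `TraitVector`) and `covariates` (matrix or
#'   `NULL`).
#' @export
simulate_trait <- function(geno, phi, config, seed = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!is.null(seed)) set.seed(seed)
  ids <- phi_block_ids(phi)
  stopifnot(identical(geno$sample_ids, ids))
  n <- length(ids)
  X <- draw_covariates(n, config$covariate_effects)
  mu <- rep(config$intercept, n)
  if (!is.null(X)) mu <- mu + drop(X %*% config$covariate_effects)
  if (length(config$causal_indices))
    mu <- mu + drop(geno$dosages[, config$causal_indices, drop = FALSE] %*%
                      config$beta)
  pg <- draw_polygenic(phi_chol(phi), config$h2, config$sigma_total)
  e <- stats::rnorm(n, 0, sqrt(1 - config$h2) * config$sigma_total)
  list(trait = trait_vector(mu + pg + e, ids), covariates = X)
}

#' Simulate a complete pedigree study
#'
#' Replicates the configured pedigree template across families, draws variant
#' frequencies and founder genotypes, gene-drops the region through each
#' pedigree, and simulates covariates and the trait. Individual IDs are
#' prefixed with the family ID so they are globally unique.
#'
#' @param config a `SimulationConfig`.
#' @param seed optional integer seed.
#' @return a `SimulatedStudy`: list with `peds`, `phi`, `geno`, `trait` (raw),
#'   `covariates`, `pheno` (data.frame: individual_id, trait `y`, covariates),
#'   `maf`, `config`, `seed`.
#' @export
simulate_study <- function(config = simulation_config(), seed = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!is.null(seed)) set.seed(seed)
  peds <- lapply(seq_len(config$n_pedigrees), function(i)
    relabel_pedigree(config$pedigree_template, paste0("ped", i)))
  names(peds) <- vapply(peds, `[[`, "", "family_id")
  phi <- phi_blocks(peds)
  maf <- draw_maf(config)
  geno_blocks <- lapply(peds, function(p) {
    fg <- draw_founder_genotypes(maf, sum(p$founder))
    gene_drop(p, fg)
  })
  dos <- do.call(rbind, lapply(geno_blocks, `[[`, "dosages"))
  rownames(dos) <- unlist(lapply(peds, `[[`, "id"), use.names = FALSE)
  geno <- genotype_matrix(dos)
  sim <- simulate_trait(geno, phi, config)
  pheno <- data.frame(individual_id = geno$sample_ids,
                      y = sim$trait$values, stringsAsFactors = FALSE)
  if (!is.null(sim$covariates)) pheno <- cbind(pheno, sim$covariates)
  structure(list(peds = peds, phi = phi, geno = geno, trait = sim$trait,
                 covariates = sim$covariates, pheno = pheno, maf = maf,
                 config = config, seed = seed),
            class = "SimulatedStudy")
}

#' @export
print.SimulatedStudy <- function(x, ...) {
  cat("SimulatedStudy:", length(x$peds), "pedigrees,",
      length(x$geno$sample_ids), "individuals,", ncol(x$geno$dosages),
      "variants\n")
  invisible(x)
}

#' Ascertain pedigrees from a simulated study
#'
#' `"random"` keeps a uniform random subset of pedigrees; `"proband_extreme"`
#' keeps pedigrees whose proband (first non-founder in pedigree order, by
#' convention) has a raw trait value above the given quantile of the study
#' trait distribution.
#'
#' @param study a `SimulatedStudy`.
#' @param rule `"random"` or `"proband_extreme"`.
#' @param keep_fraction fraction of pedigrees kept under `"random"`.
#' @param threshold_quantile trait quantile for `"proband_extreme"`.
#' @param seed optional integer seed.
#' @return a `SimulatedStudy` restricted to the retained pedigrees.
#' @export
ascertain_pedigrees <- function(study, rule = c("random", "proband_extreme"),
                                keep_fraction = 1, threshold_quantile = 0.9,
                                seed = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(study, "SimulatedStudy"))
  if (!is.null(seed)) set.seed(seed)
  fams <- names(study$peds)
  if (rule == "random") {
    n_keep <- max(1L, round(keep_fraction * length(fams)))
    keep <- if (n_keep >= length(fams)) fams else sort(sample(fams, n_keep))
  } else {
    thr <- stats::quantile(study$trait$values, threshold_quantile)
    probands <- vapply(study$peds, function(p) p$id[!p$founder][1], "")
    pt <- study$trait$values[match(probands, study$trait$ids)]
    keep <- fams[!is.na(pt) & pt > thr]
    if (length(keep) == 0L)
      stop(errorCondition("no pedigree satisfies the ascertainment rule",
                          class = c("owscore_ascertainment_empty",
                                    "owscore_error")))
  }
  subset_study(study, keep)
}

subset_study <- function(study, fams) {
  peds <- study$peds[fams]
  ids <- unlist(lapply(peds, `[[`, "id"), use.names = FALSE)
  sel <- match(ids, study$geno$sample_ids)
  geno <- genotype_matrix(study$geno$dosages[sel, , drop = FALSE],
                          study$geno$variant_meta, ids)
  structure(list(peds = peds,
                 phi = restrict_phi_blocks(study$phi, ids),
                 geno = geno,
                 trait = trait_vector(study$trait$values[sel], ids),
                 covariates = if (is.null(study$covariates)) NULL
                              else study$covariates[sel, , drop = FALSE],
                 pheno = study$pheno[sel, , drop = FALSE],
                 maf = study$maf, config = study$config, seed = study$seed),
            class = "SimulatedStudy")
}

#' Write a simulated study to disk
#'
#' Writes the FAM + genotype TSV + phenotype TSV triple that [read_pedigrees()],
#' [read_genotypes()] and [read_phenotypes()] read back (round-trip safe).
#'
#' @param study a `SimulatedStudy`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the three file paths.
#' @export
write_study <- function(study, dir, prefix = "study") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam_path <- file.path(dir, paste0(prefix, ".fam"))
  fam <- do.call(rbind, lapply(study$peds, function(p)
    data.frame(family_id = p$family_id, individual_id = p$id,
               father_id = ifelse(is.na(p$father), "0", p$father),
               mother_id = ifelse(is.na(p$mother), "0", p$mother),
               sex = match(p$sex, c("male", "female"), nomatch = 0L),
               stringsAsFactors = FALSE)))
  utils::write.table(fam, fam_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  geno_path <- file.path(dir, paste0(prefix, "_genotypes.tsv"))
  gd <- data.frame(individual_id = study$geno$sample_ids,
                   study$geno$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(gd, geno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pheno_path <- file.path(dir, paste0(prefix, "_phenotypes.tsv"))
  utils::write.table(study$pheno, pheno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fam = fam_path, genotypes = geno_path, phenotypes = pheno_path))
}
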