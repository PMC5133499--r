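# Shared fixtures, built in code.

# n unrelated singletons named s1..sn
singleton_peds <- function(n) {
  rows <- data.frame(family_id = seq_len(n),
                     individual_id = paste0("s", seq_len(n)),
                     father_id = "0", mother_id = "0", sex = "1",
                     stringsAsFactors = FALSE)
  as_pedigree_list(rows)
}

# nuclear family: founders f, m; children c1, c2
nuclear_rows <- function(fam = "fam1") {
  data.frame(family_id = fam,
             individual_id = c("f", "m", "c1", "c2"),
             father_id = c("0", "0", "f", "f"),
             mother_id = c("0", "0", "m", "m"),
             sex = c("1", "2", "1", "2"), stringsAsFactors = FALSE)
}

# the 4-individual single-variant worked example
toy_single_variant <- function() {
  peds <- singleton_peds(4)
  ids <- paste0("s", 1:4)
  list(peds = peds,
       phi = phi_blocks(peds),
       geno = genotype_matrix(matrix(c(0, 1, 0, 1), 4, 1,
                                     dimnames = list(ids, "v1"))),
       trait = trait_vector(c(-1, 1, -1, 1), ids, grand_mean_removed = TRUE))
}

# two orthogonal variants on the same 4 singletons
toy_two_variant <- function() {
  t1 <- toy_single_variant()
  ids <- paste0("s", 1:4)
  t1$geno <- genotype_matrix(matrix(c(0, 1, 0, 1, 0, 0, 1, 1), 4, 2,
                                    dimnames = list(ids, c("v1", "v2"))))
  t1
}

# random aligned instance on n singletons with M variants (for property tests)
random_instance <- function(n = 40, M = 6) {
  ids <- paste0("s", seq_len(n))
  peds <- singleton_peds(n)
  repeat {
    dos <- matrix(sample(0:2, n * M, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
                  n, M, dimnames = list(ids, paste0("v", seq_len(M))))
    if (all(apply(dos, 2, stats::var) > 0)) break
  }
  y <- rnorm(n)
  list(peds = peds, phi = phi_blocks(peds),
       geno = genotype_matrix(dos),
       trait = trait_vector(y - mean(y), ids, grand_mean_removed = TRUE))
}

# small simulation config for fast end-to-end runs
small_config <- function(M = 20, ...) {
  simulation_config(n_pedigrees = 5,
                    pedigree_template = make_template_pedigree(n_children = 2,
                                                               n_g3 = 2,
                                                               n_g4 = 2),
                    M = M, ...)
}

write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
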