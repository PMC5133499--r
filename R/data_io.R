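#' Construct a genotype matrix object
#'
#' @param dosages numeric matrix, individuals x variants, entries in {0,1,2}
#'   (NA allowed before complete-case filtering).
#' @param variant_meta data.frame with columns `id`, `chrom`, `pos`,
#'   `coded_allele` (one row per variant column).
#' @param sample_ids character vector of individual IDs (row order).
#' @return a `GenotypeMatrix`.
#' @export
genotype_matrix <- function(dosages, variant_meta = NULL, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) stop("sample IDs are required")
  if (is.null(variant_meta)) {
    ids <- colnames(dosages)
    if (is.null(ids)) ids <- paste0("v", seq_len(ncol(dosages)))
    variant_meta <- parse_variant_ids(ids)
  }
  stopifnot(nrow(variant_meta) == ncol(dosages),
            length(sample_ids) == nrow(dosages))
  ok <- is.na(dosages) | (dosages >= 0 & dosages <= 2)
  if (!all(ok)) stop("dosages must lie in [0, 2] (allele-count scale) or be NA")
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variant_meta$id
  structure(list(dosages = dosages, variant_meta = variant_meta,
                 sample_ids = as.character(sample_ids)),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "variants\n")
  invisible(x)
}

# "chr:pos" or "chr:pos:allele" IDs carry their own coordinates; anything else
# gets NA coordinates (region filtering then unavailable).
parse_variant_ids <- function(ids) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  chrom <- vapply(parts, function(p) if (length(p) >= 2) p[1] else NA_character_, "")
  pos <- vapply(parts, function(p) {
    if (length(p) >= 2) suppressWarnings(as.integer(p[2])) else NA_integer_
  }, 1L)
  allele <- vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_, "")
  data.frame(id = ids, chrom = chrom, pos = pos, coded_allele = allele,
             stringsAsFactors = FALSE)
}

#' Read region genotype dosages from VCF or a TSV dosage matrix
#'
#' Dosages are returned as counts of the minor allele in the read sample:
#' any variant whose coded (ALT) allele has frequency above 0.5 is recoded
#' `dosage -> 2 - dosage` (logged via `message`). The optional region filter is
#' 1-based and inclusive on both ends. Non-biallelic VCF records are skipped
#' with a warning.
#'
#' The TSV layout is samples as rows and variants as columns: a header of
#' variant IDs with a leading `individual_id` column, tab-delimited, missing
#' values as `NA`. Variant IDs of the form `chrom:pos` carry coordinates.
#'
#' @param path input file (`.vcf`, `.vcf.gz`, or tab-separated dosage matrix).
#' @param region optional `c(chrom, start, end)` (character chrom; 1-based
#'   inclusive), or a string `"chr:start-end"`.
#' @param variants optional character vector of variant IDs to keep.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return a `GenotypeMatrix` (possibly containing NA dosages; see
#'   [align_samples()] for complete-case filtering).
#' @export
read_genotypes <- function(path, region = NULL, variants = NULL,
                           format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) "vcf" else "tsv"
  gm <- if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
  if (!is.null(region)) gm <- filter_region(gm, region)
  if (!is.null(variants)) {
    keep <- gm$variant_meta$id %in% variants
    if (!any(keep)) stop("no variants match the requested ID list")
    gm <- genotype_matrix(gm$dosages[, keep, drop = FALSE],
                          gm$variant_meta[keep, , drop = FALSE], gm$sample_ids)
  }
  recode_to_minor(gm)
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 2L) stop("dosage TSV needs an ID column plus >= 1 variant")
  ids <- as.character(tab[[1]])
  dos <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  genotype_matrix(dos, sample_ids = ids)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !is.na(alt) & !grepl(",", alt) & nchar(ref) >= 1
  if (any(!biallelic))
    warning("skipping ", sum(!biallelic), " non-biallelic VCF record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  # allele counting; "/" and "|" treated identically
  count_alt <- function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al != "0")
  }
  dos <- t(apply(gt, 1, function(row) vapply(row, count_alt, 1.0)))
  if (nrow(gt) == 1L) dos <- matrix(dos, nrow = 1L)  # apply drops dims
  id <- fix[, "ID"]
  noid <- is.na(id) | id == "."
  id[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  meta <- data.frame(id = id, chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     coded_allele = fix[, "ALT"], stringsAsFactors = FALSE)
  genotype_matrix(t(dos), meta, sample_ids = colnames(gt))
}

filter_region <- function(gm, region) {
  if (is.character(region) && length(region) == 1L) {
    m <- regmatches(region, regexec("^(.+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) stop("region must be 'chrom:start-end'")
    region <- m[2:4]
  }
  chrom <- as.character(region[[1]])
  start <- as.numeric(region[[2]]); end <- as.numeric(region[[3]])
  vm <- gm$variant_meta
  if (anyNA(vm$pos)) stop("variant coordinates unavailable; cannot filter by region")
  keep <- vm$chrom == chrom & vm$pos >= start & vm$pos <= end
  if (!any(keep))
    stop(errorCondition(sprintf("no variants in region %s:%g-%g", chrom, start, end),
                        class = c("owscore_empty_region", "owscore_error")))
  genotype_matrix(gm$dosages[, keep, drop = FALSE], vm[keep, , drop = FALSE],
                  gm$sample_ids)
}

recode_to_minor <- function(gm) {
  n_called <- colSums(!is.na(gm$dosages))
  ac <- colSums(gm$dosages, na.rm = TRUE)
  flip <- n_called > 0 & ac > n_called  # coded-allele frequency > 0.5
  if (any(flip)) {
    message("recoding ", sum(flip),
            " variant(s) to minor-allele dosage (coded allele was major)")
    gm$dosages[, flip] <- 2 - gm$dosages[, flip]
    gm$variant_meta$coded_allele[flip] <-
      paste0("flip(", gm$variant_meta$coded_allele[flip], ")")
  }
  gm
}

#' Read a phenotype/covariate table
#'
#' Tab-delimited, one row per individual, key column `individual_id` (or the
#' first column if absent), missing values `NA`.
#'
#' @param path file path.
#' @return data.frame with `individual_id` first.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  key <- if ("individual_id" %in% names(tab)) "individual_id" else names(tab)[1]
  tab$individual_id <- as.character(tab[[key]])
  if (anyDuplicated(tab$individual_id))
    stop("phenotype table has duplicated individual IDs")
  tab[, c("individual_id", setdiff(names(tab), "individual_id"))]
}

#' Align genotypes, phenotypes and pedigrees on a complete-case sample
#'
#' Retains individuals present in all three sources with no missing genotype
#' or phenotype/covariate value (complete-case analysis), in one canonical
#' order (pedigree order). Kinship blocks are computed on the full pedigrees
#' and then restricted to the retained individuals, so relationship entries
#' through unretained connectors are preserved.
#'
#' @param geno a `GenotypeMatrix`.
#' @param pheno phenotype/covariate data.frame with `individual_id`.
#' @param peds list of `Pedigree` objects.
#' @param pheno_columns columns whose completeness is required (default: all
#'   non-key columns).
#' @param impute_mean if `TRUE`, missing genotypes are mean-imputed instead of
#'   excluding the individual (default off; complete case).
#' @return list with aligned `geno`, `pheno`, `peds` (originals), and `phi`
#'   (a `KinshipBlocks` restricted to the analyzed individuals).
#' @export
align_samples <- function(geno, pheno, peds, pheno_columns = NULL,
                          impute_mean = FALSE) {
  stopifnot(inherits(geno, "GenotypeMatrix"))
  if (inherits(peds, "Pedigree")) peds <- list(peds)
  if (is.null(pheno_columns))
    pheno_columns <- setdiff(names(pheno), "individual_id")
  ped_ids <- unlist(lapply(peds, `[[`, "id"), use.names = FALSE)

  g_ok <- geno$sample_ids
  if (impute_mean) {
    cm <- colMeans(geno$dosages, na.rm = TRUE)
    for (j in which(colSums(is.na(geno$dosages)) > 0))
      geno$dosages[is.na(geno$dosages[, j]), j] <- cm[j]
  } else {
    g_ok <- g_ok[rowSums(is.na(geno$dosages)) == 0L]
  }
  p_ok <- pheno$individual_id[
    rowSums(is.na(pheno[, pheno_columns, drop = FALSE])) == 0L]

  keep <- ped_ids[ped_ids %in% g_ok & ped_ids %in% p_ok]  # pedigree order
  if (length(keep) == 0L)
    stop(errorCondition(
      "no individuals shared by pedigree, genotype and phenotype sources",
      class = c("owscore_empty_intersection", "owscore_error")))

  gi <- match(keep, geno$sample_ids)
  geno2 <- genotype_matrix(geno$dosages[gi, , drop = FALSE],
                           geno$variant_meta, keep)
  pheno2 <- pheno[match(keep, pheno$individual_id), , drop = FALSE]
  rownames(pheno2) <- NULL
  phi <- restrict_phi_blocks(phi_blocks(peds), keep)
  stopifnot(identical(phi_block_ids(phi), keep))
  list(geno = geno2, pheno = pheno2, peds = peds, phi = phi)
}
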