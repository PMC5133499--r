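#' Read a FAM-style pedigree file
#'
#' Reads a whitespace/tab-delimited pedigree table with columns family ID,
#' individual ID, father ID, mother ID, sex. `"0"` (or `NA`) denotes a missing
#' parent. A header line is auto-detected: if the first line's tokens look like
#' column names (e.g. `fid`, `iid`, `father`, `sex`) it is skipped.
#'
#' @param path path to the pedigree file.
#' @return a `data.frame` with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex` (character codes as read).
#' @seealso [validate_pedigree()], [read_pedigrees()]
#' @export
read_fam <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty pedigree file: ", path)
  toks <- tolower(strsplit(trimws(first), "[ \t]+")[[1]])
  header_words <- c("fid", "famid", "family", "family_id", "iid", "id",
                    "individual_id", "father", "father_id", "pat", "paternal",
                    "mother", "mother_id", "mat", "maternal", "sex", "gender")
  has_header <- any(toks %in% header_words)
  raw <- utils::read.table(path, header = has_header, sep = "",
                           colClasses = "character", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 5L)
    stop("pedigree file must have >= 5 columns (family, id, father, mother, sex)")
  raw <- raw[, 1:5]
  names(raw) <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  raw
}

#' Read and validate all pedigrees in a FAM-style file
#'
#' @inheritParams read_fam
#' @param ... passed to [validate_pedigree()].
#' @return a named list of `Pedigree` objects, one per family, in order of
#'   first appearance.
#' @export
read_pedigrees <- function(path, ...) {
  raw <- read_fam(path)
  as_pedigree_list(raw, ...)
}

#' Split a pedigree table by family and validate each family
#'
#' @param rows data.frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`.
#' @param ... passed to [validate_pedigree()].
#' @return named list of `Pedigree` objects.
#' @export
as_pedigree_list <- function(rows, ...) {
  fams <- unique(rows$family_id)
  peds <- lapply(fams, function(f)
    validate_pedigree(rows[rows$family_id == f, , drop = FALSE], ...))
  names(peds) <- fams
  peds
}

norm_sex <- function(sex) {
  s <- tolower(as.character(sex))
  out <- rep("unknown", length(s))
  out[s %in% c("1", "m", "male")] <- "male"
  out[s %in% c("2", "f", "female")] <- "female"
  out
}

#' Validate one family's pedigree records
#'
#' Checks the structural invariants of a pedigree: unique individual IDs,
#' both-or-no parents per individual, parents resolvable within the family,
#' and an acyclic parent graph. Members are returned in topological order
#' (founders first, computed by repeated founder-stripping with ties broken
#' by input order), which downstream kinship computation relies on.
#'
#' Individuals referenced as parents but lacking their own record are
#' auto-inserted as founders with a warning (a common FAM-file dialect);
#' set `insert_missing_parents = FALSE` to make this an error instead.
#'
#' @param rows data.frame of one family's records (columns `family_id`,
#'   `individual_id`, `father_id`, `mother_id`, `sex`; `"0"`, `""` or `NA`
#'   denote a missing parent).
#' @param insert_missing_parents auto-insert record-less parents as founders?
#' @return a `Pedigree`: list with character vectors `family_id`, `id`,
#'   `father`, `mother` (NA for founders), `sex`
#'   (`"male"/"female"/"unknown"`) and logical `founder`, members in
#'   topological order.
#' @examples
#' rows <- data.frame(family_id = "f1",
#'                    individual_id = c("c1", "dad", "mom"),
#'                    father_id = c("dad", "0", "0"),
#'                    mother_id = c("mom", "0", "0"),
#'                    sex = c("1", "1", "2"))
#' ped <- validate_pedigree(rows)
#' ped$id  # founders first
#' @export
validate_pedigree <- function(rows, insert_missing_parents = TRUE) {
  stopifnot(is.data.frame(rows), nrow(rows) > 0L)
  fam <- unique(as.character(rows$family_id))
  if (length(fam) != 1L)
    stop("validate_pedigree() expects records from a single family; got: ",
         paste(fam, collapse = ", "))
  id <- as.character(rows$individual_id)
  miss <- function(x) is.na(x) | x == "0" | x == ""
  father <- as.character(rows$father_id); father[miss(father)] <- NA_character_
  mother <- as.character(rows$mother_id); mother[miss(mother)] <- NA_character_
  sex <- norm_sex(rows$sex)

  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop(errorCondition(
      paste0("duplicate individual ID(s) in family ", fam, ": ",
             paste(dup, collapse = ", ")),
      class = c("owscore_duplicate_id", "owscore_error")))
  }
  single <- xor(is.na(father), is.na(mother))
  if (any(single))
    stop(errorCondition(
      paste0("individual(s) with exactly one recorded parent in family ", fam,
             ": ", paste(id[single], collapse = ", ")),
      class = c("owscore_single_parent", "owscore_error")))

  referenced <- setdiff(stats::na.omit(c(father, mother)), id)
  if (length(referenced)) {
    if (!insert_missing_parents)
      stop(errorCondition(
        paste0("parent ID(s) without their own record in family ", fam, ": ",
               paste(referenced, collapse = ", ")),
        class = c("owscore_unknown_parent", "owscore_error")))
    warning("family ", fam, ": inserting record-less parent(s) as founders: ",
            paste(referenced, collapse = ", "))
    # guess sex from the slot they occupy
    psex <- ifelse(referenced %in% father, "male", "female")
    id <- c(id, referenced)
    father <- c(father, rep(NA_character_, length(referenced)))
    mother <- c(mother, rep(NA_character_, length(referenced)))
    sex <- c(sex, psex)
  }

  # topological order by repeated founder-stripping; input order breaks ties
  n <- length(id)
  placed <- logical(n)
  order_idx <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(father) | father %in% id[placed]) &
      (is.na(mother) | mother %in% id[placed])
    if (!any(ready)) break
    order_idx <- c(order_idx, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed))
    stop(errorCondition(
      paste0("pedigree cycle (individual its own ancestor) in family ", fam,
             " involving: ", paste(id[!placed], collapse = ", ")),
      class = c("owscore_pedigree_cycle", "owscore_error")))

  structure(list(family_id = fam,
                 id = id[order_idx],
                 father = father[order_idx],
                 mother = mother[order_idx],
                 sex = sex[order_idx],
                 founder = is.na(father[order_idx])),
            class = "Pedigree")
}

#' @export
print.Pedigree <- function(x, ...) {
  cat("Pedigree ", x$family_id, ": ", length(x$id), " members (",
      sum(x$founder), " founders)\n", sep = "")
  invisible(x)
}

#' Kinship coefficient matrix of a pedigree
#'
#' Computes pairwise kinship coefficients phi by the standard recursion over
#' members in topological order: for founders phi(a,a) = 1/2 and phi(a,b) = 0
#' (founders assumed mutually unrelated and non-inbred); for a non-founder c
#' with parents p and q, phi(c,b) = (phi(p,b) + phi(q,b))/2 for b != c and
#' phi(c,c) = 1/2 + phi(p,q)/2. Inbreeding loops recorded within the pedigree
#' are handled by the recursion. Autosomal model only.
#'
#' @param ped a `Pedigree` from [validate_pedigree()].
#' @return symmetric numeric matrix of kinship coefficients, dimnames =
#'   member IDs in pedigree (topological) order.
#' @examples
#' rows <- data.frame(family_id = 1, individual_id = c("f", "m", "c1", "c2"),
#'                    father_id = c(0, 0, "f", "f"),
#'                    mother_id = c(0, 0, "m", "m"), sex = c(1, 2, 1, 2))
#' kinship_matrix(validate_pedigree(rows))["c1", "c2"]  # full sibs: 0.25
#' @export
kinship_matrix <- function(ped) {
  stopifnot(inherits(ped, "Pedigree"))
  n <- length(ped$id)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  pos <- seq_len(n); names(pos) <- ped$id
  for (c_i in seq_len(n)) {
    if (ped$founder[c_i]) {
      phi[c_i, c_i] <- 0.5
      next
    }
    p <- pos[[ped$father[c_i]]]
    q <- pos[[ped$mother[c_i]]]
    if (p >= c_i || q >= c_i)
      stop("internal error: pedigree not topologically ordered")
    if (c_i > 1L) {
      b <- seq_len(c_i - 1L)
      phi[c_i, b] <- (phi[p, b] + phi[q, b]) / 2
      phi[b, c_i] <- phi[c_i, b]
    }
    phi[c_i, c_i] <- 0.5 + phi[p, q] / 2
  }
  phi
}

#' Block-diagonal relationship matrices for a set of pedigrees
#'
#' For each family, Phi = 2 x kinship matrix (the numerator-relationship
#' matrix entering the trait quadratic form of the score tests). Unrelated
#' singletons yield 1x1 blocks equal to 1.
#'
#' @param ped_set list of `Pedigree` objects (e.g. from [read_pedigrees()]).
#' @return a `KinshipBlocks`: list with `blocks` (list of symmetric matrices),
#'   `member_order` (list of ID vectors) and `family_ids`.
#' @export
phi_blocks <- function(ped_set) {
  if (inherits(ped_set, "Pedigree")) ped_set <- list(ped_set)
  blocks <- lapply(ped_set, function(p) 2 * kinship_matrix(p))
  structure(list(blocks = blocks,
                 member_order = lapply(ped_set, `[[`, "id"),
                 family_ids = vapply(ped_set, `[[`, "", "family_id")),
            class = "KinshipBlocks")
}

#' @export
print.KinshipBlocks <- function(x, ...) {
  cat("KinshipBlocks:", length(x$blocks), "families,",
      sum(lengths(x$member_order)), "individuals\n")
  invisible(x)
}

#' Restrict kinship blocks to a subset of individuals
#'
#' Subsets each family block to the listed individuals (complete-case
#' analysis set), preserving entries; families with no retained member are
#' dropped.
#'
#' @param phi a `KinshipBlocks`.
#' @param keep_ids character vector of individual IDs to retain.
#' @return a `KinshipBlocks` over the retained individuals.
#' @export
restrict_phi_blocks <- function(phi, keep_ids) {
  stopifnot(inherits(phi, "KinshipBlocks"))
  keep <- lapply(phi$member_order, function(ids) ids[ids %in% keep_ids])
  nz <- lengths(keep) > 0L
  structure(list(
    blocks = Map(function(b, k) b[k, k, drop = FALSE], phi$blocks[nz], keep[nz]),
    member_order = keep[nz],
    family_ids = phi$family_ids[nz]), class = "KinshipBlocks")
}

#' All individual IDs covered by kinship blocks, in block order
#' @param phi a `KinshipBlocks`.
#' @return character vector of IDs.
#' @export
phi_block_ids <- function(phi) unlist(phi$member_order, use.names = FALSE)

#' Monte-Carlo kinship estimate by gene dropping
#'
#' Drops `n_drops` independent founder-labelled alleles through the pedigree
#' (one allele from each parent per meiosis, chosen uniformly) and estimates
#' each pairwise kinship coefficient as the empirical probability that one
#' allele sampled from each individual is identical by descent. Serves as an
#' independent check of [kinship_matrix()].
#'
#' @param ped a `Pedigree`.
#' @param n_drops number of independent gene drops (unlinked loci).
#' @param seed optional integer seed.
#' @return list with `phi_hat` (matrix of estimates) and `se` (matrix of
#'   Monte-Carlo standard errors).
#' @export
gene_drop_kinship <- function(ped, n_drops = 200000L, seed = NULL) {
  stopifnot(inherits(ped, "Pedigree"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(ped$id)
  pos <- seq_len(n); names(pos) <- ped$id
  a1 <- matrix(0L, n, n_drops)
  a2 <- matrix(0L, n, n_drops)
  lab <- 0L
  for (i in seq_len(n)) {
    if (ped$founder[i]) {
      a1[i, ] <- lab + 1L
      a2[i, ] <- lab + 2L
      lab <- lab + 2L
    } else {
      p <- pos[[ped$father[i]]]
      q <- pos[[ped$mother[i]]]
      pick1 <- stats::runif(n_drops) < 0.5
      pick2 <- stats::runif(n_drops) < 0.5
      a1[i, ] <- ifelse(pick1, a1[p, ], a2[p, ])
      a2[i, ] <- ifelse(pick2, a1[q, ], a2[q, ])
    }
  }
  phi_hat <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  se <- phi_hat
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      s <- ((a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
            (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])) / 4
      if (i == j) s <- (1 + (a1[i, ] == a2[i, ])) / 2  # (1 + F)/2 per drop
      phi_hat[i, j] <- phi_hat[j, i] <- mean(s)
      se[i, j] <- se[j, i] <- stats::sd(s) / sqrt(n_drops)
    }
  }
  list(phi_hat = phi_hat, se = se)
}
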