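#' Diploid genotype matrix
#'
#' The canonical genotype container used throughout the package: an
#' individuals x loci integer matrix of alternate-allele dosages (0, 1, 2),
#' with `NA` marking missing calls. Loci are unordered de-novo markers (no
#' genomic coordinate system is assumed); each locus carries a tag identifier
#' grouping SNPs that were assembled on the same short tag, which drives the
#' one-SNP-per-tag thinning step.
#'
#' @param genotypes Integer matrix, individuals in rows, loci in columns.
#'   Entries must be 0, 1, 2 or `NA`. Row and column names, when present,
#'   seed the individual and locus ids.
#' @param locus_ids Character vector of unique locus identifiers; defaults to
#'   column names, or `locus_1 ...` when absent.
#' @param tag_ids Character vector assigning each locus to a tag; defaults to
#'   one tag per locus (i.e. data already thinned).
#' @param individual_ids Character vector of individual identifiers; defaults
#'   to row names, or `ind_1 ...`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `genotypes`, `locus_ids`, `tag_ids`, `individual_ids`.
#' @export
#' @examples
#' g <- genotype_matrix(rbind(a = c(0L, 1L), b = c(2L, NA)))
#' n_loci(g)
genotype_matrix <- function(genotypes, locus_ids = NULL, tag_ids = NULL,
                            individual_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  bad <- !is.na(genotypes) & !(genotypes %in% 0:2)
  if (any(bad)) {
    abort("genotype dosages must be 0, 1, 2 or NA (missing).")
  }
  if (nrow(genotypes) < 2) {
    abort("a genotype_matrix needs at least 2 individuals.")
  }
  if (is.null(locus_ids)) {
    locus_ids <- colnames(genotypes) %||% paste0("locus_", seq_len(ncol(genotypes)))
  }
  if (anyDuplicated(locus_ids)) abort("locus_ids must be unique.")
  if (is.null(individual_ids)) {
    individual_ids <- rownames(genotypes) %||% paste0("ind_", seq_len(nrow(genotypes)))
  }
  if (anyDuplicated(individual_ids)) abort("individual_ids must be unique.")
  if (is.null(tag_ids)) tag_ids <- locus_ids
  stopifnot(
    length(locus_ids) == ncol(genotypes),
    length(tag_ids) == ncol(genotypes),
    length(individual_ids) == nrow(genotypes)
  )
  dimnames(genotypes) <- list(individual_ids, locus_ids)
  structure(
    list(
      genotypes = genotypes,
      locus_ids = as.character(locus_ids),
      tag_ids = as.character(tag_ids),
      individual_ids = as.character(individual_ids)
    ),
    class = "genotype_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$genotypes))
  cat(sprintf(
    "<genotype_matrix> %d individuals x %d loci (%d tags), %.1f%% missing\n",
    nrow(x$genotypes), ncol(x$genotypes), length(unique(x$tag_ids)), 100 * miss
  ))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g A `genotype_matrix`.
#' @export
n_loci <- function(g) ncol(g$genotypes)

#' @rdname genotype_matrix
#' @export
n_individuals <- function(g) nrow(g$genotypes)

#' Long-format view of a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per individual x locus call
#'   (`individual_id`, `locus_id`, `tag_id`, `dosage`).
#' @method tidy genotype_matrix
#' @export
tidy.genotype_matrix <- function(x, ...) {
  tibble(
    individual_id = rep(x$individual_ids, times = n_loci(x)),
    locus_id = rep(x$locus_ids, each = n_individuals(x)),
    tag_id = rep(x$tag_ids, each = n_individuals(x)),
    dosage = as.integer(x$genotypes)
  )
}

# subset a genotype_matrix by logical/integer/character index ---------------
subset_loci <- function(g, keep) {
  if (is.character(keep)) keep <- match(keep, g$locus_ids)
  genotype_matrix(
    g$genotypes[, keep, drop = FALSE],
    locus_ids = g$locus_ids[keep],
    tag_ids = g$tag_ids[keep],
    individual_ids = g$individual_ids
  )
}

subset_individuals <- function(g, keep) {
  if (is.character(keep)) keep <- match(keep, g$individual_ids)
  genotype_matrix(
    g$genotypes[keep, , drop = FALSE],
    locus_ids = g$locus_ids,
    tag_ids = g$tag_ids,
    individual_ids = g$individual_ids[keep]
  )
}

#' Population map
#'
#' Assigns every individual to a population and every population to a group
#' (a deeply diverged clade). A two-column input is accepted, in which case
#' each population is its own group.
#'
#' @param individual_id,population_id,group_id Character vectors of equal
#'   length.
#' @return A tibble with columns `individual_id`, `population_id`,
#'   `group_id`.
#' @export
population_map <- function(individual_id, population_id, group_id = NULL) {
  if (is.null(group_id)) group_id <- population_id
  pm <- tibble(
    individual_id = as.character(individual_id),
    population_id = as.character(population_id),
    group_id = as.character(group_id)
  )
  if (anyDuplicated(pm$individual_id)) {
    abort("each individual must have exactly one population assignment.")
  }
  multi <- pm %>%
    distinct(.data$population_id, .data$group_id) %>%
    count(.data$population_id) %>%
    filter(.data$n > 1)
  if (nrow(multi) > 0) {
    abort(paste0(
      "population(s) assigned to more than one group: ",
      paste(multi$population_id, collapse = ", ")
    ))
  }
  pm
}

# validate that a population map covers a genotype matrix; returns pm ordered
# to the matrix's individuals
check_popmap <- function(g, pm) {
  missing <- setdiff(g$individual_ids, pm$individual_id)
  if (length(missing) > 0) {
    abort(paste0(
      "population map does not cover individual(s): ",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  pm[match(g$individual_ids, pm$individual_id), , drop = FALSE]
}

# per-population allele frequency and call-count matrices -------------------
# returns list(p = pops x loci alt-allele frequency (NaN where no calls),
#              n = pops x loci called-diploid counts,
#              het = pops x loci heterozygote counts)
pop_allele_stats <- function(g, pm) {
  pm <- check_popmap(g, pm)
  pops <- unique(pm$population_id)
  geno <- g$genotypes
  n_mat <- het <- alt <- matrix(
    0, length(pops), ncol(geno),
    dimnames = list(pops, g$locus_ids)
  )
  for (i in seq_along(pops)) {
    rows <- geno[pm$population_id == pops[i], , drop = FALSE]
    called <- !is.na(rows)
    n_mat[i, ] <- colSums(called)
    alt[i, ] <- colSums(rows, na.rm = TRUE)
    het[i, ] <- colSums(rows == 1L, na.rm = TRUE)
  }
  list(p = alt / (2 * n_mat), n = n_mat, het = het, populations = pops)
}
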