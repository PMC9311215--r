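#' Population allele frequency spectrum
#'
#' Counts loci by allele count within one population. Loci with any missing
#' call in the population are excluded (listwise), so every retained locus is
#' observed on the same `2n` haplotypes. `mode = "unfolded"` counts the
#' alternate allele; `mode = "folded"` counts the minor allele (classes `0`
#' to `n`).
#'
#' @param g A [genotype_matrix()].
#' @param pm A [population_map()].
#' @param pop Population id.
#' @param mode `"folded"` (default) or `"unfolded"`.
#' @return A tibble with `allele_count`, `n_loci`, and attributes
#'   `n_haplotypes` and `n_polymorphic` (loci outside class 0 and, when
#'   folded, outside the top class... i.e. segregating in this population).
#' @export
population_sfs <- function(g, pm, pop, mode = c("folded", "unfolded")) {
  mode <- match.arg(mode)
  pm <- check_popmap(g, pm)
  rows <- which(pm$population_id == pop)
  if (length(rows) == 0) abort(paste0("population not found or empty: ", pop))
  geno <- g$genotypes[rows, , drop = FALSE]
  complete <- colSums(is.na(geno)) == 0
  geno <- geno[, complete, drop = FALSE]
  if (ncol(geno) == 0) abort("no completely genotyped loci in this population.")
  n_hap <- 2L * length(rows)
  ac <- colSums(geno)
  if (mode == "folded") ac <- pmin(ac, n_hap - ac)
  top <- if (mode == "folded") floor(n_hap / 2) else n_hap
  counts <- tabulate(ac + 1L, nbins = top + 1L)
  out <- tibble(allele_count = 0:top, n_loci = counts)
  attr(out, "n_haplotypes") <- n_hap
  attr(out, "n_polymorphic") <- sum(ac > 0 & ac < n_hap)
  out
}

#' Joint (2D) allele frequency spectrum between two groups
#'
#' Grid of loci by alternate-allele count in group A versus group B, over
#' loci completely genotyped in both groups. Strongly diverged groups with
#' no gene flow put most mass off the diagonal (differential fixation);
#' identical groups put all mass on the diagonal.
#'
#' @param g A [genotype_matrix()].
#' @param pm A [population_map()].
#' @param group_a,group_b Group (clade) ids.
#' @return A tibble with `count_a`, `count_b`, `n_loci` (only non-empty
#'   cells), with attributes `n_haplotypes_a/b`.
#' @export
joint_sfs <- function(g, pm, group_a, group_b) {
  pm <- check_popmap(g, pm)
  rows_a <- which(pm$group_id == group_a)
  rows_b <- which(pm$group_id == group_b)
  if (length(rows_a) == 0 || length(rows_b) == 0) {
    abort("both groups must contain at least one individual.")
  }
  ga <- g$genotypes[rows_a, , drop = FALSE]
  gb <- g$genotypes[rows_b, , drop = FALSE]
  complete <- colSums(is.na(ga)) == 0 & colSums(is.na(gb)) == 0
  if (!any(complete)) abort("no loci completely genotyped in both groups.")
  ca <- colSums(ga[, complete, drop = FALSE])
  cb <- colSums(gb[, complete, drop = FALSE])
  out <- tibble(count_a = as.integer(ca), count_b = as.integer(cb)) %>%
    count(.data$count_a, .data$count_b, name = "n_loci")
  attr(out, "n_haplotypes_a") <- 2L * length(rows_a)
  attr(out, "n_haplotypes_b") <- 2L * length(rows_b)
  out
}
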