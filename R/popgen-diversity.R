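#' Nei diversity and differentiation statistics
#'
#' Computes, per locus and overall: observed heterozygosity Ho (proportion of
#' heterozygotes among called individuals, pooled), within-population gene
#' diversity Hs (mean over populations of `2p(1-p)` with the small-sample
#' correction `n/(n-1)`), overall gene diversity Ht (from the unweighted mean
#' of population allele frequencies), Nei's differentiation
#' `Fst = (Ht - Hs)/Ht`, and the inbreeding coefficient `Fis = 1 - Ho/Hs`.
#' Multi-locus Fst and Fis are ratios of averages across loci, not averages
#' of per-locus ratios.
#'
#' @param g A [genotype_matrix()].
#' @param pm A [population_map()]; at least 2 populations, each with at least
#'   2 called individuals at some locus.
#' @return An object of class `diversity_stats`: list with `overall` (a
#'   one-row tibble: `ho`, `hs`, `ht`, `fst`, `fis`) and `per_locus` (a
#'   tibble with the same quantities per locus).
#' @export
diversity <- function(g, pm) {
  st <- pop_allele_stats(g, pm)
  if (length(st$populations) < 2) abort("diversity() needs at least 2 populations.")
  dead <- rowSums(st$n >= 2) == 0
  if (any(dead)) {
    abort(paste0("population(s) with <2 called individuals at every locus: ",
                 paste(st$populations[dead], collapse = ", ")))
  }
  p <- st$p
  n <- st$n

  ho_l <- colSums(st$het) / colSums(n)
  # per-population 2p(1-p) * n/(n-1); populations with <2 calls at a locus
  # cannot contribute an unbiased estimate and are excluded locus-wise
  hs_pop <- 2 * p * (1 - p) * n / (n - 1)
  hs_pop[n < 2] <- NA_real_
  hs_l <- colMeans(hs_pop, na.rm = TRUE)

  p_ok <- p
  p_ok[n == 0] <- NA_real_
  p_bar <- colMeans(p_ok, na.rm = TRUE) # unweighted mean over populations
  ht_l <- 2 * p_bar * (1 - p_bar)

  ho_l <- unname(ho_l); hs_l <- unname(hs_l); ht_l <- unname(ht_l)
  per_locus <- tibble(
    locus_id = g$locus_ids, ho = ho_l, hs = hs_l, ht = ht_l,
    fst = ifelse(ht_l > 0, (ht_l - hs_l) / ht_l, NA_real_),
    fis = ifelse(hs_l > 0, 1 - ho_l / hs_l, NA_real_)
  )
  ho <- mean(ho_l)
  hs <- mean(hs_l)
  ht <- mean(ht_l)
  overall <- tibble(
    ho = ho, hs = hs, ht = ht,
    fst = if (ht > 0) (ht - hs) / ht else NA_real_,
    fis = if (hs > 0) 1 - ho / hs else NA_real_
  )
  structure(list(overall = overall, per_locus = per_locus),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat("<diversity_stats>\n")
  print(x$overall)
  invisible(x)
}

#' @rdname diversity
#' @param x A `diversity_stats` object.
#' @param ... Unused.
#' @method tidy diversity_stats
#' @export
tidy.diversity_stats <- function(x, ...) x$per_locus

#' @rdname diversity
#' @method glance diversity_stats
#' @export
glance.diversity_stats <- function(x, ...) x$overall

#' Pairwise Weir-Cockerham Fst
#'
#' The 1984 variance-components estimator theta for a pair of populations:
#' per-locus theta = a / (a + b + c) from the among-population (a),
#' among-individual (b) and within-individual (c) components, and a
#' multi-locus estimate as the ratio of summed components. Loci monomorphic
#' across the pair are excluded. Per-locus estimates may be negative; they
#' are reported raw.
#'
#' @param g A [genotype_matrix()].
#' @param pm A [population_map()].
#' @param pop_a,pop_b Population ids to compare.
#' @return List with `per_locus` (tibble: `locus_id`, `a`, `b`, `c`,
#'   `theta`) and `theta` (multi-locus estimate).
#' @export
pairwise_wc_fst <- function(g, pm, pop_a, pop_b) {
  pm <- check_popmap(g, pm)
  use <- pm$population_id %in% c(pop_a, pop_b)
  if (!any(pm$population_id == pop_a) || !any(pm$population_id == pop_b)) {
    abort("both populations must be present in the population map.")
  }
  gg <- subset_individuals(g, which(use))
  st <- pop_allele_stats(gg, pm[use, ])

  n <- st$n # 2 x L called diploids
  p <- st$p
  h <- st$het / n # observed heterozygote proportions
  r <- 2
  ok <- colSums(n >= 2) == r
  n_bar <- colMeans(n)
  n_c <- (r * n_bar - colSums(n^2) / (r * n_bar)) / (r - 1)
  p_bar <- colSums(n * p) / (r * n_bar)
  s2 <- colSums(n * sweep(p, 2, p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- colSums(n * h) / (r * n_bar)

  a <- n_bar / n_c *
    (s2 - 1 / (n_bar - 1) * (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2

  poly <- ok & p_bar > 0 & p_bar < 1
  if (!any(poly)) abort("no shared polymorphic loci between the two populations.")
  denom <- a + b + cc
  per_locus <- tibble(
    locus_id = gg$locus_ids[poly],
    a = unname(a[poly]), b = unname(b[poly]), c = unname(cc[poly]),
    theta = unname(ifelse(denom[poly] != 0, a[poly] / denom[poly], NA_real_))
  )
  list(
    per_locus = per_locus,
    theta = sum(per_locus$a) / sum(per_locus$a + per_locus$b + per_locus$c)
  )
}
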