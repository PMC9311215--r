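#' Filter configuration
#'
#' Holds the locus/individual quality filters applied before any analysis:
#' minor allele frequency, per-individual and per-locus missingness caps, and
#' the one-random-SNP-per-tag thinning used to limit linkage disequilibrium.
#'
#' @param maf_min Minimum minor allele frequency; loci below it are dropped
#'   (default 0.05). MAF is computed over all non-missing calls pooled across
#'   populations.
#' @param indiv_missing_max Maximum tolerated proportion of missing calls per
#'   individual (default 0.90).
#' @param locus_missing_max Maximum tolerated proportion of missing calls per
#'   locus (default 0.30).
#' @param one_snp_per_tag Keep a single randomly chosen SNP per tag
#'   (default `TRUE`).
#' @param seed Integer seed driving the random per-tag choice.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(maf_min = 0.05, indiv_missing_max = 0.90,
                          locus_missing_max = 0.30, one_snp_per_tag = TRUE,
                          seed = 1L) {
  stopifnot(
    maf_min >= 0, maf_min <= 1,
    indiv_missing_max >= 0, indiv_missing_max <= 1,
    locus_missing_max >= 0, locus_missing_max <= 1
  )
  structure(
    list(
      maf_min = maf_min, indiv_missing_max = indiv_missing_max,
      locus_missing_max = locus_missing_max,
      one_snp_per_tag = isTRUE(one_snp_per_tag), seed = as.integer(seed)
    ),
    class = "filter_config"
  )
}

#' Apply quality filters to a genotype matrix
#'
#' Filters run in a fixed order: (1) individuals above the missingness cap
#' are dropped, (2) loci above the missingness cap are dropped, (3) one SNP
#' per tag is kept at random (seeded), (4) loci under the MAF cut-off are
#' dropped. Individual-level filtering runs first so that ghost individuals
#' cannot inflate locus missingness, and the MAF is computed on the retained
#' individuals only.
#'
#' @param g A [genotype_matrix()].
#' @param pm A [population_map()] covering `g` (retained for interface
#'   symmetry; filters are global).
#' @param cfg A [filter_config()].
#' @return The filtered `genotype_matrix`, with a `filter_report` attribute:
#'   a tibble of per-step removal counts.
#' @export
apply_filters <- function(g, pm = NULL, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (!is.null(pm)) check_popmap(g, pm)
  n_ind0 <- n_individuals(g)
  n_loc0 <- n_loci(g)

  # (1) individuals
  ind_miss <- rowMeans(is.na(g$genotypes))
  keep_ind <- ind_miss <= cfg$indiv_missing_max
  removed_ind <- sum(!keep_ind)
  if (sum(keep_ind) < 2) abort("filtering step 1 (individual missingness) left <2 individuals.")
  g <- subset_individuals(g, keep_ind)

  # (2) locus missingness
  loc_miss <- colMeans(is.na(g$genotypes))
  keep <- loc_miss <= cfg$locus_missing_max
  removed_miss <- sum(!keep)
  if (!any(keep)) abort("filtering step 2 (locus missingness) removed all loci.")
  g <- subset_loci(g, keep)

  # (3) one SNP per tag, random but reproducible under the seed
  removed_tag <- 0L
  if (cfg$one_snp_per_tag) {
    idx <- seq_len(n_loci(g))
    keep_idx <- with_local_seed(cfg$seed, {
      split(idx, g$tag_ids[idx])[unique(g$tag_ids)] |>
        vapply(function(i) if (length(i) == 1L) i else i[sample.int(length(i), 1L)],
               integer(1))
    })
    keep_idx <- sort(unname(keep_idx))
    removed_tag <- n_loci(g) - length(keep_idx)
    g <- subset_loci(g, keep_idx)
  }

  # (4) minor allele frequency, pooled over all non-missing calls
  p <- colMeans(g$genotypes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= cfg$maf_min
  removed_maf <- sum(!keep)
  if (!any(keep)) abort("filtering step 4 (minor allele frequency) removed all loci.")
  g <- subset_loci(g, keep)

  report <- tibble(
    step = c("individual_missingness", "locus_missingness",
             "one_snp_per_tag", "minor_allele_frequency"),
    removed = c(removed_ind, removed_miss, removed_tag, removed_maf),
    unit = c("individuals", "loci", "loci", "loci")
  )
  attr(g, "filter_report") <- report
  stopifnot(n_loc0 == n_loci(g) + sum(report$removed[report$unit == "loci"]))
  stopifnot(n_ind0 == n_individuals(g) + removed_ind)
  g
}

# evaluate expr with a temporary RNG state so callers' streams are untouched
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Drop loci completely missing in any population
#'
#' Removes every locus with zero non-missing calls in at least one
#' population, a post-hoc cleanup applied to candidate loci whose signal can
#' be driven purely by population-patterned missingness.
#'
#' @param g A [genotype_matrix()].
#' @param pm A [population_map()] (at least 2 populations).
#' @return The pruned `genotype_matrix`, with attribute `missing_report`: a
#'   tibble counting removed loci by the number of populations they were
#'   missing from.
#' @export
drop_population_missing_loci <- function(g, pm) {
  stats <- pop_allele_stats(g, pm)
  if (length(stats$populations) < 2) abort("need at least 2 populations.")
  n_missing_pops <- colSums(stats$n == 0)
  keep <- n_missing_pops == 0
  report <- tibble(n_populations_missing = as.integer(names(table(n_missing_pops[!keep]))),
                   n_loci = as.integer(table(n_missing_pops[!keep])))
  out <- if (all(keep)) g else subset_loci(g, keep)
  attr(out, "missing_report") <- report
  out
}
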