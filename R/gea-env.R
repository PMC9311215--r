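#' Preprocess an environment table
#'
#' Centres every variable to mean 0 and scales to variance 1 across
#' populations, then greedily prunes collinear variables: walking the
#' priority order, a variable is kept iff its squared correlation with every
#' already-kept variable is at most `r2_max` (the threshold is inclusive, so
#' `r^2` exactly equal to `r2_max` is tolerated).
#'
#' @param env Tibble with `population_id` and numeric variables.
#' @param r2_max Collinearity ceiling (default 0.7).
#' @param priority Character vector ordering the variables for the greedy
#'   walk (defaults to column order; variables listed first win ties against
#'   later correlated ones).
#' @return List with `env` (the pruned, standardised table), `kept` and
#'   `dropped` (character vectors).
#' @export
preprocess_env <- function(env, r2_max = 0.7, priority = NULL) {
  vars <- setdiff(names(env), "population_id")
  if (nrow(env) < 2) abort("need at least 2 populations.")
  const <- vars[vapply(env[vars], function(x) var(x) == 0, logical(1))]
  if (length(const) > 0) {
    abort(paste0("constant environment variable(s): ",
                 paste(const, collapse = ", ")))
  }
  scaled <- env
  scaled[vars] <- lapply(env[vars], function(x) as.numeric(scale(x)))
  priority <- priority %||% vars
  if (!setequal(priority, vars)) {
    priority <- c(intersect(priority, vars), setdiff(vars, priority))
  }
  kept <- character(0)
  for (v in priority) {
    r2 <- if (length(kept) == 0) 0 else {
      vapply(kept, function(w) cor(scaled[[v]], scaled[[w]])^2, numeric(1))
    }
    if (all(r2 <= r2_max + 1e-12)) kept <- c(kept, v) # inclusive threshold
  }
  dropped <- setdiff(vars, kept)
  list(
    env = scaled[, c("population_id", kept), drop = FALSE],
    kept = kept, dropped = dropped
  )
}

#' Generate random environmental variables
#'
#' Draws `count` independent standard-normal variables at population level
#' (one value per population, mirroring the resolution of real
#' environmental data). These serve as a negative control in the
#' genotype-environment association stage: loci that associate with many of
#' them are prone to spurious association. Random variables are never
#' subjected to collinearity pruning.
#'
#' @param populations Character vector of population ids.
#' @param count Number of variables (default 100).
#' @param seed Integer seed.
#' @return A tibble: `population_id` plus `ranvar_001 ...`; each column has
#'   provenance "random" recorded in the `provenance` attribute.
#' @export
make_random_env <- function(populations, count = 100, seed = 1L) {
  stopifnot(count >= 1)
  populations <- as.character(populations)
  vals <- with_local_seed(seed, {
    matrix(rnorm(length(populations) * count), nrow = length(populations))
  })
  colnames(vals) <- sprintf("ranvar_%03d", seq_len(count))
  out <- dplyr::bind_cols(tibble(population_id = populations), as_tibble(vals))
  attr(out, "provenance") <- setNames(rep("random", count), colnames(vals))
  out
}

#' Impute missing genotypes with the within-group modal genotype
#'
#' Replaces each missing call with the most common genotype among called
#' individuals of the same group (clade); ties between equally common
#' dosages are broken toward the lower dosage code. Required by ordination
#' methods that cannot tolerate missing data; loci entirely uncalled within
#' a group must be removed beforehand (see
#' [drop_population_missing_loci()]).
#'
#' @param g A [genotype_matrix()].
#' @param pm A [population_map()] supplying the group assignment.
#' @return A complete `genotype_matrix`.
#' @export
impute_modal <- function(g, pm) {
  pm <- check_popmap(g, pm)
  geno <- g$genotypes
  for (grp in unique(pm$group_id)) {
    rows <- which(pm$group_id == grp)
    sub <- geno[rows, , drop = FALSE]
    miss_loci <- which(colSums(is.na(sub)) > 0)
    if (length(miss_loci) == 0) next
    counts <- vapply(0:2, function(d) colSums(sub[, miss_loci, drop = FALSE] == d,
                                              na.rm = TRUE),
                     numeric(length(miss_loci)))
    counts <- matrix(counts, ncol = 3)
    no_calls <- rowSums(counts) == 0
    if (any(no_calls)) {
      abort(paste0(
        "group ", grp, " has zero calls at locus/loci ",
        paste(head(g$locus_ids[miss_loci[no_calls]], 5), collapse = ", "),
        "; run drop_population_missing_loci() first."
      ))
    }
    modal <- max.col(counts, ties.method = "first") - 1L # ties -> lower dosage
    for (jj in seq_along(miss_loci)) {
      j <- miss_loci[jj]
      miss_rows <- rows[is.na(geno[rows, j])]
      geno[miss_rows, j] <- modal[jj]
    }
  }
  genotype_matrix(geno, locus_ids = g$locus_ids, tag_ids = g$tag_ids,
                  individual_ids = g$individual_ids)
}
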