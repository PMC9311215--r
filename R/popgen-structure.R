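#' Principal component analysis of genotypes
#'
#' PCA of the individuals x loci dosage matrix. Missing entries are
#' mean-imputed per locus for this operation only (the genotype matrix is
#' left untouched); columns are centred but not scaled.
#'
#' @param g A [genotype_matrix()].
#' @param n_axes Number of axes to return (default `min(n-1, 10)`).
#' @return An object of class `genotype_pca`: list with `scores` (tibble:
#'   `individual_id`, `PC1` ...), `prop_var` (explained-variance
#'   proportions, non-increasing), `sdev`.
#' @export
pca_genotypes <- function(g, n_axes = NULL) {
  if (n_individuals(g) < 2 || n_loci(g) < 2) {
    abort("PCA needs at least 2 individuals and 2 loci.")
  }
  x <- mean_impute(g$genotypes)
  if (all(apply(x, 2, var) == 0)) abort("constant genotype matrix; PCA undefined.")
  n_axes <- n_axes %||% min(n_individuals(g) - 1L, 10L)
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_axes)
  prop <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x[, seq_len(min(n_axes, ncol(pc$x))), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(individual_id = g$individual_ids), scores)
  structure(
    list(scores = scores, prop_var = prop[seq_len(ncol(pc$x))], sdev = pc$sdev),
    class = "genotype_pca"
  )
}

mean_impute <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx) > 0) x[idx] <- mu[idx[, 2]]
  x
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("<genotype_pca> %d axes; PC1 %.1f%%, PC2 %.1f%%\n",
              length(x$prop_var), 100 * x$prop_var[1],
              100 * ifelse(length(x$prop_var) > 1, x$prop_var[2], NA)))
  invisible(x)
}

#' @rdname pca_genotypes
#' @param x A `genotype_pca`.
#' @param ... Unused.
#' @method tidy genotype_pca
#' @export
tidy.genotype_pca <- function(x, ...) x$scores

#' @rdname pca_genotypes
#' @method glance genotype_pca
#' @export
glance.genotype_pca <- function(x, ...) {
  tibble(n_axes = length(x$prop_var), prop_var_pc1 = x$prop_var[1],
         prop_var_pc2 = if (length(x$prop_var) > 1) x$prop_var[2] else NA_real_)
}

#' Plot PCA scores coloured by population
#'
#' @param pca A [pca_genotypes()] result.
#' @param pm Optional [population_map()] used to colour points.
#' @param axes Which two axes to draw (default 1:2).
#' @return A ggplot object.
#' @export
plot_pca <- function(pca, pm = NULL, axes = c(1, 2)) {
  sc <- pca$scores
  ax <- paste0("PC", axes)
  if (!all(ax %in% names(sc))) abort("requested axes not present in the PCA.")
  if (!is.null(pm)) sc <- left_join(sc, pm, by = "individual_id")
  aes <- if (is.null(pm)) {
    ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]])
  } else {
    ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                 colour = .data$population_id, shape = .data$group_id)
  }
  ggplot2::ggplot(sc, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", ax[1], 100 * pca$prop_var[axes[1]]),
      y = sprintf("%s (%.1f%%)", ax[2], 100 * pca$prop_var[axes[2]])
    ) +
    ggplot2::theme_minimal()
}

#' Directional relative migration (GST method)
#'
#' For each ordered population pair a hypothetical pool population is formed
#' from the pair's unweighted mean allele frequencies; the GST of each member
#' against that pool measures how far the member has drifted from the shared
#' migrant pool, and its inverse transform `((1/GST) - 1)/4` (the island-model
#' relationship between differentiation and Nm) gives a relative migration
#' rate into that member. Rates are divided by the matrix maximum so the
#' best-connected direction equals 1. GST is floored at 1e-6 so that
#' indistinguishable populations yield the maximal rate rather than an
#' indeterminate one.
#'
#' @param g A [genotype_matrix()].
#' @param pm A [population_map()].
#' @param min_rate Entries below this are masked to `NA` (display
#'   convention; default 0 keeps everything).
#' @return A square matrix, `rates[i, j]` = relative migration from
#'   population `i` into population `j`; diagonal `NA`.
#' @export
relative_migration <- function(g, pm, min_rate = 0) {
  st <- pop_allele_stats(g, pm)
  pops <- st$populations
  if (length(pops) < 2) abort("need at least 2 populations.")
  p <- st$p
  p[st$n == 0] <- NA_real_
  p_bar <- colMeans(p, na.rm = TRUE)
  if (all(p_bar %in% c(0, 1), na.rm = TRUE)) {
    abort("monomorphic data; relative migration undefined.")
  }
  k <- length(pops)
  nm <- matrix(NA_real_, k, k, dimnames = list(from = pops, to = pops))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- !is.na(p[i, ]) & !is.na(p[j, ])
      pool <- (p[i, ok] + p[j, ok]) / 2
      g_i <- gst_vs_pool(p[i, ok], pool)
      g_j <- gst_vs_pool(p[j, ok], pool)
      # migration INTO x is high when x sits close to the pool
      nm[j, i] <- ((1 / max(g_i, 1e-6)) - 1) / 4
      nm[i, j] <- ((1 / max(g_j, 1e-6)) - 1) / 4
    }
  }
  rates <- nm / max(nm, na.rm = TRUE)
  if (min_rate > 0) rates[!is.na(rates) & rates < min_rate] <- NA_real_
  rates
}

# multilocus GST between one population and the pooled pair (ratio of
# averages across loci)
gst_vs_pool <- function(p_x, p_pool) {
  hs <- (2 * p_x * (1 - p_x) + 2 * p_pool * (1 - p_pool)) / 2
  p_bar <- (p_x + p_pool) / 2
  ht <- 2 * p_bar * (1 - p_bar)
  ht_m <- mean(ht)
  if (ht_m <= 0) return(0)
  max((ht_m - mean(hs)) / ht_m, 0)
}

#' Correlation between migration rates and geographical distance
#'
#' Pearson correlation over the off-diagonal ordered pairs of a relative
#' migration matrix against a matching distance matrix (km), with the
#' two-tailed t-distribution p-value. Matrix entries are not independent;
#' the plain test is the field's reported convention for this comparison.
#'
#' @param m Migration matrix from [relative_migration()].
#' @param d Square distance matrix with the same population ordering.
#' @return A one-row tibble: `estimate` (r), `p_value`, `n_pairs`.
#' @export
migration_distance_correlation <- function(m, d) {
  if (!all(dim(m) == dim(d))) abort("matrices must share dimensions and ordering.")
  off <- row(m) != col(m)
  use <- off & !is.na(m) & !is.na(d)
  if (sum(use) < 3) abort("need at least 3 off-diagonal pairs.")
  ct <- cor.test(m[use], d[use], method = "pearson")
  tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
         n_pairs = sum(use))
}
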