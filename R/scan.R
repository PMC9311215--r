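# genotype scaling shared by the PCA scan and axis choice:
# centre each locus on its mean and scale by the binomial standard deviation
# sqrt(2 p (1-p)); missing entries become 0 (mean imputation on this scale)
scale_genotypes <- function(g) {
  x <- g$genotypes
  mu <- colMeans(x, na.rm = TRUE)
  p <- mu / 2
  s <- sqrt(2 * p * (1 - p))
  ok <- !is.na(s) & s > 0
  x <- sweep(x, 2, mu)
  x <- sweep(x, 2, ifelse(ok, s, 1), "/")
  x[is.na(x)] <- 0
  list(x = x, polymorphic = ok)
}

#' Choose the number of principal components for the outlier scan
#'
#' Computes the scree (explained-variance proportions) of the scaled
#' genotype matrix and picks `k` at the largest drop between consecutive
#' proportions - an automated stand-in for the usual visual inspection.
#' A flat scree (largest drop below 0.01) indicates no usable axis
#' structure; `k` then defaults to 1 with a warning. The caller may always
#' override `k` in [pcadapt_scan()].
#'
#' @param g A [genotype_matrix()].
#' @param max_k Largest k considered (must be < number of individuals).
#' @return List with `k` and `scree` (tibble: `axis`, `prop_var`, `drop`).
#' @export
choose_k <- function(g, max_k = 10) {
  n <- n_individuals(g)
  if (max_k >= n) abort("max_k must be smaller than the number of individuals.")
  sc <- scale_genotypes(g)
  x <- sc$x[, sc$polymorphic, drop = FALSE]
  if (ncol(x) < 2) abort("degenerate genotype matrix: fewer than 2 polymorphic loci.")
  d <- svd(x, nu = 0, nv = 0)$d
  prop <- d^2 / sum(d^2)
  prop <- prop[seq_len(min(max_k + 1L, length(prop)))]
  drop_ <- -diff(prop)
  scree <- tibble(
    axis = seq_along(prop), prop_var = prop,
    drop = c(drop_, NA_real_)
  )
  k <- which.max(drop_)
  if (drop_[k] < 0.01) {
    warn("choose_k: flat scree (no drop above 0.01); defaulting to k = 1.")
    k <- 1L
  }
  list(k = as.integer(k), scree = scree)
}

#' PCA-based Mahalanobis outlier scan
#'
#' Each locus is regressed on the `k` leading principal components of the
#' scaled genotype matrix; the per-locus vector of regression z-scores is
#' mapped to exact normal scores (the finite-sample t reference) and
#' summarised by a robust Mahalanobis distance D^2. The scatter matrix is
#' Tyler's M-estimator anchored at zero, which resists outlying loci and is
#' exactly invariant to reference/alternate allele flips; the sample
#' covariance is used when fewer than `10 * k` loci are available, and a
#' diagonal covariance when singular. D^2 is calibrated with the genomic
#' inflation factor
#' `lambda = median(D^2) / median(chi^2_k)`; p-values are the upper tail of
#' chi^2_k applied to `D^2 / lambda`, and q-values come from [storey_q()].
#'
#' @param g A [genotype_matrix()] (polymorphic loci; monomorphic columns are
#'   dropped with a message).
#' @param k Number of structure axes to regress out (>= 1, < individuals).
#' @return An object of class `gso_scan`: list with `table` (tibble:
#'   `locus_id`, `statistic`, `p_value`, `q_value`, `method`), `k`,
#'   `lambda`, `pi0`.
#' @export
pcadapt_scan <- function(g, k) {
  n <- n_individuals(g)
  if (k < 1) abort("k must be >= 1.")
  if (k >= n) abort("k must be smaller than the number of individuals.")
  sc <- scale_genotypes(g)
  if (!all(sc$polymorphic)) {
    inform(sprintf("pcadapt_scan: dropping %d monomorphic locus/loci.",
                   sum(!sc$polymorphic)))
  }
  x <- sc$x[, sc$polymorphic, drop = FALSE]
  locus_ids <- g$locus_ids[sc$polymorphic]
  L <- ncol(x)
  if (L < 2) abort("fewer than 2 polymorphic loci; scan undefined.")

  sv <- svd(x, nu = k, nv = 0)
  u <- sv$u # n x k, orthonormal
  beta <- crossprod(u, x) # k x L regression coefficients
  rss <- pmax(colSums(x^2) - colSums(beta^2), 0)
  df <- n - k - 1 # columns are centred, so one further df is spent
  sigma <- sqrt(pmax(rss / df, 1e-12))
  tstat <- t(beta) / sigma # L x k
  # map regression t-scores to exact normal scores so the chi-square
  # reference for D^2 holds at finite sample size (raw t tails are heavier
  # than normal and would inflate the extreme tail of the scan)
  z <- sign(tstat) * abs(qnorm(pt(-abs(tstat), df = df)))
  z[is.na(z) | is.infinite(z)] <- sign(tstat[is.na(z) | is.infinite(z)]) * 38

  cov_est <- robust_cov(z, k)
  d2 <- unname(mahalanobis(z, cov_est$center, cov_est$cov))
  lambda <- median(d2) / qchisq(0.5, df = k)
  p <- pchisq(d2 / lambda, df = k, lower.tail = FALSE)
  q <- storey_q(p)

  structure(
    list(
      table = tibble(locus_id = locus_ids, statistic = d2, p_value = p,
                     q_value = as.numeric(q), method = "pcadapt"),
      k = as.integer(k), lambda = lambda, pi0 = attr(q, "pi0")
    ),
    class = "gso_scan"
  )
}

# Robust scatter of the z-scores. Tyler's M-estimator with the centre fixed
# at the model's null mean (0): the fixed point of
#   S = (k/L) sum_i z_i z_i' / (z_i' S^{-1} z_i)
# It depends on each locus only through z z', so it is exactly invariant to
# reference/alternate allele flips (which negate a locus's z-vector), is
# highly resistant to outlying loci, and is deterministic. Its scale is
# arbitrary, which the genomic-inflation rescaling absorbs. With fewer than
# 10*k loci the sample covariance is used instead; a singular scatter falls
# back to a diagonal one with a warning.
robust_cov <- function(z, k) {
  L <- nrow(z)
  p <- ncol(z)
  if (L >= 10 * k) {
    s <- diag(p)
    ok <- rowSums(z^2) > 0
    zz <- z[ok, , drop = FALSE]
    for (iter in 1:200) {
      d2 <- rowSums((zz %*% solve(s)) * zz)
      d2 <- pmax(d2, 1e-300)
      s_new <- crossprod(zz / sqrt(d2)) * (p / nrow(zz))
      s_new <- s_new / det(s_new)^(1 / p)
      if (max(abs(s_new - s)) < 1e-10) {
        s <- s_new
        break
      }
      s <- s_new
    }
    if (all(is.finite(s)) && det(s) > .Machine$double.xmin) {
      # Tyler's shape has arbitrary scale (det = 1); rescale to the overall
      # second-moment scale (centre 0, hence still flip-invariant) so the
      # genomic inflation factor keeps its usual reading of ~1 at the null
      scale2 <- det(crossprod(zz) / nrow(zz))^(1 / p)
      return(list(center = rep(0, p), cov = s * scale2))
    }
  }
  ctr <- colMeans(z)
  cv <- stats::cov(z)
  if (!is.finite(det(as.matrix(cv))) || det(as.matrix(cv)) <= .Machine$double.xmin) {
    warn("pcadapt_scan: singular z covariance; using diagonal covariance.")
    cv <- diag(pmax(apply(z, 2, var), 1e-12), ncol(z))
  }
  list(center = ctr, cov = cv)
}

#' @export
print.gso_scan <- function(x, ...) {
  cat(sprintf("<gso_scan method=%s> %d loci, k = %d, lambda = %.3f\n",
              x$table$method[1], nrow(x$table), x$k, x$lambda))
  invisible(x)
}

#' @rdname pcadapt_scan
#' @param x A `gso_scan`.
#' @param ... Unused.
#' @method tidy gso_scan
#' @export
tidy.gso_scan <- function(x, ...) x$table

#' @rdname pcadapt_scan
#' @method glance gso_scan
#' @export
glance.gso_scan <- function(x, ...) {
  tibble(method = x$table$method[1], n_loci = nrow(x$table), k = x$k,
         lambda = x$lambda, pi0 = x$pi0 %||% NA_real_,
         n_q_below_0.05 = sum(x$table$q_value < 0.05))
}

#' @rdname pcadapt_scan
#' @param object A `gso_scan`.
#' @method autoplot gso_scan
#' @export
autoplot.gso_scan <- function(object, ...) {
  tab <- mutate(object$table, index = dplyr::row_number())
  ggplot2::ggplot(tab, ggplot2::aes(.data$index, -log10(pmax(.data$q_value, 1e-300)))) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = "locus index", y = expression(-log[10](q))) +
    ggplot2::theme_minimal()
}

#' Ingest an externally computed outlier scan
#'
#' Adapter for q-value tables produced by other genome-scan software (for
#' example a Bayesian differentiation scan). Expects a TSV with header
#' columns `locus_id` and `q_value` (optional `method`). Loci unknown to the
#' active genotype matrix are dropped with a warning; less than 50% overlap
#' is fatal.
#'
#' @param path Path to the TSV.
#' @param g A [genotype_matrix()] defining the locus universe.
#' @param method Method label recorded in the table (default from the file's
#'   `method` column, else `"external"`).
#' @return A `gso_scan` with `p_value` set to `NA`.
#' @export
ingest_external_scan <- function(path, g, method = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("locus_id", "q_value") %in% names(tab))) {
    abort("external scan file needs columns locus_id and q_value.")
  }
  if (anyNA(tab$q_value) || any(tab$q_value < 0 | tab$q_value > 1)) {
    abort("external scan file contains q-values outside [0, 1].")
  }
  method <- method %||% (if ("method" %in% names(tab)) tab$method[1] else "external")
  known <- tab$locus_id %in% g$locus_ids
  if (mean(known) < 0.5) {
    abort("fewer than 50% of external loci match the active genotype matrix.")
  }
  if (!all(known)) {
    warn(sprintf("ingest_external_scan: dropping %d unknown locus/loci.",
                 sum(!known)))
    tab <- tab[known, , drop = FALSE]
  }
  structure(
    list(
      table = tibble(locus_id = as.character(tab$locus_id),
                     statistic = NA_real_, p_value = NA_real_,
                     q_value = tab$q_value, method = method),
      k = NA_integer_, lambda = NA_real_, pi0 = NA_real_
    ),
    class = "gso_scan"
  )
}

#' Flag and prune suspect candidate loci
#'
#' Post-hoc screening of candidate loci: loci whose pooled observed
#' heterozygosity exceeds `ho_max` are flagged (possible paralog collapse),
#' and loci completely missing in at least one population are removed (their
#' apparent signal can be an artefact of population-patterned missingness).
#'
#' @param g A [genotype_matrix()] containing the candidate loci.
#' @param pm A [population_map()].
#' @param candidates A scan table (tibble with `locus_id`) or `gso_scan`.
#' @param ho_max Heterozygosity flag threshold (default 0.5).
#' @return List with `kept` (pruned candidate table, extra column
#'   `ho_flagged`), `flagged_ho` (locus ids), `removed_missing` (locus ids).
#' @export
flag_suspect_outliers <- function(g, pm, candidates, ho_max = 0.5) {
  tab <- if (inherits(candidates, "gso_scan")) candidates$table else candidates
  if (!all(tab$locus_id %in% g$locus_ids)) {
    abort("candidate loci must be present in the genotype matrix.")
  }
  gg <- subset_loci(g, tab$locus_id)
  ho <- colSums(gg$genotypes == 1L, na.rm = TRUE) /
    colSums(!is.na(gg$genotypes))
  st <- pop_allele_stats(gg, pm)
  missing_any <- colSums(st$n == 0) > 0
  flagged <- gg$locus_ids[!is.na(ho) & ho > ho_max]
  removed <- gg$locus_ids[missing_any]
  kept <- tab %>%
    filter(!.data$locus_id %in% removed) %>%
    mutate(ho_flagged = .data$locus_id %in% flagged)
  list(kept = kept, flagged_ho = flagged, removed_missing = removed)
}
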