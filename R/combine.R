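#' Combination and classification configuration
#'
#' @param alpha Significance threshold on (combined) q-values
#'   (default 0.05).
#' @param random_hit_max A significant locus stays high-confidence only if
#'   it associates with fewer than this many random variables (default 5,
#'   i.e. 5% of the default 100 random runs).
#' @param n_random Number of random variables expected per locus
#'   (default 100).
#' @return A list of class `combine_config`.
#' @export
combine_config <- function(alpha = 0.05, random_hit_max = 5L, n_random = 100L) {
  stopifnot(alpha > 0, alpha < 1, random_hit_max >= 0,
            random_hit_max <= n_random)
  structure(list(alpha = alpha, random_hit_max = as.integer(random_hit_max),
                 n_random = as.integer(n_random)),
            class = "combine_config")
}

#' Geometric-mean combination of two q-values
#'
#' `sqrt(q_a * q_b)`: the arithmetic mean on the log scale, sitting between
#' the union rule (`min`) and the intersection rule (`max`) of the two
#' methods. Strong support from one method (a very small q) can pull a locus
#' below the significance threshold even with no support from the other;
#' e.g. `combine_q(0.001, 0.2)` is about 0.0141, significant at alpha 0.05.
#'
#' @param q_a,q_b Numeric vectors of q-values in `[0, 1]` (recycled).
#' @return `sqrt(q_a * q_b)`, elementwise.
#' @export
combine_q <- function(q_a, q_b) {
  if (anyNA(q_a) || anyNA(q_b) ||
      any(q_a < 0 | q_a > 1) || any(q_b < 0 | q_b > 1)) {
    abort("q-values must lie in [0, 1].")
  }
  sqrt(q_a * q_b)
}

scan_table_of <- function(x) {
  if (inherits(x, "gso_scan") || inherits(x, "gea_scan")) x$table else x
}

#' Combine two outlier scans and classify loci
#'
#' Outer-joins the locus sets of two genome scans (a locus absent from one
#' method receives q = 1 there, with a warning, so only strong support from
#' the other method can rescue it), combines q-values by the geometric mean,
#' and reports three nested significant sets at `alpha`: the intersection
#' (significant in both methods), the combination (combined q below alpha)
#' and the union (significant in either) - the combination always sits
#' between the other two.
#'
#' @param scan_a,scan_b `gso_scan` objects or tidy scan tables.
#' @param cfg A [combine_config()].
#' @return A tibble: `locus_id`, `q_a`, `q_b`, `q_combined`, `in_intersection`,
#'   `in_combined`, `in_union`, with a `summary` attribute of set sizes.
#' @export
classify_gso <- function(scan_a, scan_b, cfg = combine_config()) {
  a <- scan_table_of(scan_a) %>% select("locus_id", q_a = "q_value")
  b <- scan_table_of(scan_b) %>% select("locus_id", q_b = "q_value")
  if (length(intersect(a$locus_id, b$locus_id)) == 0) {
    abort("the two scans share no loci.")
  }
  tab <- full_join(a, b, by = "locus_id")
  n_fill <- sum(is.na(tab$q_a)) + sum(is.na(tab$q_b))
  if (n_fill > 0) {
    warn(sprintf("classify_gso: %d locus/method pair(s) missing; assigned q = 1.",
                 n_fill))
    tab$q_a[is.na(tab$q_a)] <- 1
    tab$q_b[is.na(tab$q_b)] <- 1
  }
  tab <- tab %>%
    mutate(
      q_combined = combine_q(.data$q_a, .data$q_b),
      in_intersection = .data$q_a < cfg$alpha & .data$q_b < cfg$alpha,
      in_combined = .data$q_combined < cfg$alpha,
      in_union = .data$q_a < cfg$alpha | .data$q_b < cfg$alpha
    )
  attr(tab, "summary") <- tibble(
    set = c("intersection", "combined", "union"),
    n_loci = c(sum(tab$in_intersection), sum(tab$in_combined),
               sum(tab$in_union))
  )
  tab
}

#' Combine two GEA tables over the locus x variable grid
#'
#' Geometric-mean combination of per locus x variable q-values from two
#' association methods (outer join on the grid; missing cells get q = 1
#' with a warning). With a single method available, pass the same object
#' twice - the geometric mean is idempotent.
#'
#' @param gea_a,gea_b `gea_scan` objects or tidy tables.
#' @return A tibble: `locus_id`, `variable`, `q_a`, `q_b`, `q_combined`.
#' @export
combine_gea <- function(gea_a, gea_b) {
  a <- scan_table_of(gea_a) %>% select("locus_id", "variable", q_a = "q_value")
  b <- scan_table_of(gea_b) %>% select("locus_id", "variable", q_b = "q_value")
  tab <- full_join(a, b, by = c("locus_id", "variable"))
  n_fill <- sum(is.na(tab$q_a)) + sum(is.na(tab$q_b))
  if (n_fill > 0) {
    warn(sprintf("combine_gea: %d grid cell(s) missing; assigned q = 1.", n_fill))
    tab$q_a[is.na(tab$q_a)] <- 1
    tab$q_b[is.na(tab$q_b)] <- 1
  }
  mutate(tab, q_combined = combine_q(.data$q_a, .data$q_b))
}

#' Count associations with random variables per locus
#'
#' @param random_gea Combined (or single-method) GEA table over the random
#'   variables: tibble with `locus_id`, `variable` and `q_combined` (or
#'   `q_value`).
#' @param cfg A [combine_config()]; every locus must be covered by
#'   `cfg$n_random` random variables.
#' @return A tibble: `locus_id`, `n_random_hits` (count of random variables
#'   with q below `cfg$alpha`).
#' @export
random_hit_counts <- function(random_gea, cfg = combine_config()) {
  tab <- scan_table_of(random_gea)
  qcol <- if ("q_combined" %in% names(tab)) "q_combined" else "q_value"
  cover <- tab %>% count(.data$locus_id)
  if (any(cover$n != cfg$n_random)) {
    abort(sprintf("random grid incomplete: expected %d variables per locus.",
                  cfg$n_random))
  }
  tab %>%
    group_by(.data$locus_id) %>%
    summarise(n_random_hits = sum(.data[[qcol]] < cfg$alpha), .groups = "drop")
}

#' Classify GEA candidates with the random-variable null control
#'
#' A locus x variable pair is significant when its combined q-value is below
#' `alpha`. A significant locus is high-confidence when it associates with
#' fewer than `random_hit_max` of the random variables, low-confidence
#' otherwise; the random-hit rule applies per locus.
#'
#' @param real_combined Combined GEA table over the real variables (from
#'   [combine_gea()], or a `gea_scan` table; needs `q_combined` or
#'   `q_value`).
#' @param hits Per-locus random hit counts from [random_hit_counts()].
#' @param cfg A [combine_config()].
#' @return A tibble: `locus_id`, `variable`, `q_combined`, `n_random_hits`,
#'   `significant`, `class` (`not-significant`, `low-confidence`,
#'   `high-confidence`), with a `summary` attribute: per-variable counts of
#'   significant and high-confidence associations.
#' @export
classify_gea <- function(real_combined, hits, cfg = combine_config()) {
  tab <- scan_table_of(real_combined)
  qcol <- if ("q_combined" %in% names(tab)) "q_combined" else "q_value"
  out <- tab %>%
    select("locus_id", "variable", q_combined = !!qcol) %>%
    left_join(hits, by = "locus_id") %>%
    mutate(
      n_random_hits = ifelse(is.na(.data$n_random_hits), 0L, .data$n_random_hits),
      significant = .data$q_combined < cfg$alpha,
      class = dplyr::case_when(
        !significant ~ "not-significant",
        n_random_hits < cfg$random_hit_max ~ "high-confidence",
        TRUE ~ "low-confidence"
      )
    )
  attr(out, "summary") <- out %>%
    group_by(.data$variable) %>%
    summarise(
      n_significant = sum(.data$significant),
      n_high_confidence = sum(.data$class == "high-confidence"),
      .groups = "drop"
    )
  out
}
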