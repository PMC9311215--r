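# broadcast population-level environment values to individuals, in the
# genotype matrix's individual order; returns a numeric matrix n x m
env_design <- function(g, pm, env) {
  pm <- check_popmap(g, pm)
  missing_pops <- setdiff(pm$population_id, env$population_id)
  if (length(missing_pops) > 0) {
    abort(paste0("environment table lacks population(s): ",
                 paste(missing_pops, collapse = ", ")))
  }
  rows <- match(pm$population_id, env$population_id)
  x <- as.matrix(env[rows, setdiff(names(env), "population_id"), drop = FALSE])
  rownames(x) <- g$individual_ids
  x
}

#' Permutation test of the RDA full model
#'
#' Fits a redundancy analysis of the (imputed, complete) genotype matrix on
#' all environmental variables, with population-level values broadcast to
#' individuals, and tests the full model by permutation ANOVA: the pseudo-F
#' statistic `(explained/df_model) / (residual/df_resid)` is compared to its
#' distribution under row permutations of the environment, with
#' `p = (1 + #{F_perm >= F_obs}) / (n_perm + 1)`.
#'
#' @param g A complete [genotype_matrix()] (see [impute_modal()]).
#' @param pm A [population_map()].
#' @param env Preprocessed environment table ([preprocess_env()]).
#' @param n_perm Number of permutations (default 999, giving a minimum
#'   attainable p of 0.001).
#' @param seed Integer seed for the permutations.
#' @return A one-row tibble: `statistic` (pseudo-F), `df_model`, `df_resid`,
#'   `p_value`, `n_perm`.
#' @export
rda_full_model_test <- function(g, pm, env, n_perm = 999, seed = 1L) {
  x <- env_design(g, pm, env)
  if (anyNA(g$genotypes)) abort("genotype matrix has missing data; impute first.")
  n_pops <- length(unique(pm$population_id[pm$individual_id %in% g$individual_ids]))
  if (n_pops < ncol(x) + 2) {
    abort("too few populations for the number of environmental variables.")
  }
  if (qr(cbind(1, x))$rank < ncol(x) + 1) abort("rank-deficient environment design.")
  y <- g$genotypes
  xdf <- as.data.frame(x)
  mod <- vegan::rda(y ~ ., data = xdf)
  an <- with_local_seed(seed, vegan::anova.cca(mod, permutations = n_perm))
  tibble(
    statistic = an$F[1], df_model = an$Df[1], df_resid = an$Df[2],
    p_value = an$`Pr(>F)`[1], n_perm = n_perm
  )
}

# core constrained-ordination decomposition: least-squares fit of centred
# genotypes on the design, SVD of the fitted values, axes with positive
# constrained variance retained
rda_core <- function(y, x) {
  y <- scale(y, center = TRUE, scale = FALSE)
  qx <- qr(cbind(1, x))
  if (qx$rank < ncol(x) + 1) abort("rank-deficient environment design.")
  fitted <- qr.fitted(qx, y)
  sv <- svd(fitted)
  tol <- max(dim(fitted)) * .Machine$double.eps * sv$d[1]
  r <- sum(sv$d > max(tol, 0))
  if (r == 0) abort("zero constrained variance; nothing to associate.")
  list(
    u = sv$u[, seq_len(r), drop = FALSE],
    d = sv$d[seq_len(r)],
    v = sv$v[, seq_len(r), drop = FALSE],
    eig = sv$d[seq_len(r)]^2 / (nrow(y) - 1)
  )
}

#' Per-locus, per-variable association scores from RDA
#'
#' Runs a redundancy analysis of the genotype matrix on the supplied
#' environmental variables and attributes the constrained signal back to
#' each locus x variable pair: the raw score is the sum over retained
#' constrained axes of the locus loading (axis weighted by its singular
#' value) times the correlation between the variable and the axis site
#' scores. Scores are standardised per variable into z-scores, converted to
#' two-tailed normal p-values, and to q-values via [storey_q()]. With a
#' single variable the score reduces to the simple correlation between the
#' locus and that variable.
#'
#' @param g A complete [genotype_matrix()].
#' @param pm A [population_map()].
#' @param env Environment table (any numeric columns; standardised
#'   internally; use [preprocess_env()] upstream for collinearity pruning of
#'   real variables).
#' @param per_variable Fit one univariate RDA per variable instead of a
#'   joint model. Used for the random-variable null runs, where the number
#'   of variables exceeds the rank any joint model could support.
#' @return An object of class `gea_scan`: list with `table` (tibble:
#'   `locus_id`, `variable`, `score`, `z`, `p_value`, `q_value`, `method`),
#'   `eig` (constrained eigenvalues; `NULL` for per-variable fits).
#' @export
rda_associations <- function(g, pm, env, per_variable = FALSE) {
  if (anyNA(g$genotypes)) abort("genotype matrix has missing data; impute first.")
  vars <- setdiff(names(env), "population_id")
  env_std <- env
  env_std[vars] <- lapply(env[vars], function(v) as.numeric(scale(v)))
  x <- env_design(g, pm, env_std)
  y <- g$genotypes

  if (per_variable) {
    tabs <- lapply(vars, function(v) {
      gea_scores(y, x[, v, drop = FALSE], g$locus_ids)
    })
    tab <- bind_rows(tabs)
    eig <- NULL
  } else {
    tab <- gea_scores(y, x, g$locus_ids)
    eig <- attr(tab, "eig")
  }
  structure(list(table = mutate(tab, method = "rda"), eig = eig),
            class = "gea_scan")
}

gea_scores <- function(y, x, locus_ids) {
  dec <- rda_core(y, x)
  # corr of each (standardised) variable with each constrained axis
  cmat <- cor(x, dec$u) # m x r
  loadings <- dec$v %*% diag(dec$d, length(dec$d)) # L x r
  s <- loadings %*% t(cmat) # L x m raw scores
  z <- scale(s)
  p <- 2 * pnorm(-abs(z))
  out <- purrr::map_dfr(seq_len(ncol(x)), function(j) {
    q <- storey_q(p[, j])
    tibble(locus_id = locus_ids, variable = colnames(x)[j],
           score = s[, j], z = as.numeric(z[, j]), p_value = p[, j],
           q_value = as.numeric(q))
  })
  attr(out, "eig") <- dec$eig
  out
}

#' @export
print.gea_scan <- function(x, ...) {
  cat(sprintf("<gea_scan method=%s> %d loci x %d variable(s)\n",
              x$table$method[1], length(unique(x$table$locus_id)),
              length(unique(x$table$variable))))
  invisible(x)
}

#' @rdname rda_associations
#' @param x A `gea_scan`.
#' @param ... Unused.
#' @method tidy gea_scan
#' @export
tidy.gea_scan <- function(x, ...) x$table

#' @rdname rda_associations
#' @method glance gea_scan
#' @export
glance.gea_scan <- function(x, ...) {
  x$table %>%
    group_by(.data$variable) %>%
    summarise(n_loci = n(), n_q_below_0.05 = sum(.data$q_value < 0.05),
              .groups = "drop")
}

#' Ingest an externally computed genotype-environment association table
#'
#' Adapter for per locus x variable q-values from external GEA software
#' (for example a Bayesian environmental-association scan). Expects a TSV
#' with columns `locus_id`, `variable`, `q_value`.
#'
#' @param path Path to the TSV.
#' @param method Method label (default `"external"`).
#' @param env Optional environment table; variables absent from it trigger a
#'   warning.
#' @return A `gea_scan`.
#' @export
ingest_external_gea <- function(path, method = "external", env = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("locus_id", "variable", "q_value")
  if (!all(need %in% names(tab))) {
    abort("external GEA file needs columns locus_id, variable, q_value.")
  }
  if (anyNA(tab$q_value) || any(tab$q_value < 0 | tab$q_value > 1)) {
    abort("external GEA file contains q-values outside [0, 1].")
  }
  if (!is.null(env)) {
    unknown <- setdiff(unique(tab$variable), setdiff(names(env), "population_id"))
    if (length(unknown) > 0) {
      warn(paste0("ingest_external_gea: unknown variable(s): ",
                  paste(unknown, collapse = ", ")))
    }
  }
  grid_n <- length(unique(tab$locus_id)) * length(unique(tab$variable))
  if (nrow(distinct(tab, .data$locus_id, .data$variable)) < grid_n) {
    inform("ingest_external_gea: locus x variable grid is incomplete.")
  }
  structure(
    list(
      table = tibble(locus_id = as.character(tab$locus_id),
                     variable = as.character(tab$variable),
                     score = NA_real_, z = NA_real_, p_value = NA_real_,
                     q_value = tab$q_value, method = method),
      eig = NULL
    ),
    class = "gea_scan"
  )
}

#' Combine q-values across variables correlated with an anchor variable
#'
#' Association tests run on every variable, including those collinear with
#' the anchor (typically latitude). For reporting "anchor in the broad
#' sense", the per-locus q-values of the anchor and of every variable whose
#' squared correlation with it exceeds `r2_min` are combined with the
#' geometric mean.
#'
#' @param gea A `gea_scan` or its tidy table (needs a `q_value` or
#'   `q_combined` column).
#' @param anchor Variable name anchoring the correlated set.
#' @param env Environment table used to measure correlations (must contain
#'   the anchor and the gea table's variables).
#' @param r2_min Variables with `r^2 > r2_min` against the anchor join the
#'   set (default 0.7; the anchor itself is always included).
#' @return A tibble: `locus_id`, `q_broad`, `n_vars`.
#' @export
broad_sense_combine <- function(gea, anchor, env, r2_min = 0.7) {
  tab <- if (inherits(gea, "gea_scan")) gea$table else gea
  qcol <- if ("q_combined" %in% names(tab)) "q_combined" else "q_value"
  vars <- intersect(unique(tab$variable), setdiff(names(env), "population_id"))
  if (!anchor %in% vars) abort(paste0("anchor variable not present: ", anchor))
  r2 <- vapply(vars, function(v) cor(env[[v]], env[[anchor]])^2, numeric(1))
  set <- union(anchor, vars[r2 > r2_min])
  tab %>%
    filter(.data$variable %in% set) %>%
    group_by(.data$locus_id) %>%
    summarise(q_broad = exp(mean(log(pmax(.data[[qcol]], 1e-300)))),
              n_vars = n(), .groups = "drop")
}
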