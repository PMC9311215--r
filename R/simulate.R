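#' Simulation configuration
#'
#' Parameters of the hierarchical Balding-Nichols simulator. The defaults
#' describe the regime the package targets: three strongly diverged clades
#' of several populations each, spread along a latitudinal environmental
#' gradient, with a small minority of loci whose allele frequencies track an
#' environmental variable.
#'
#' @param n_groups Number of groups/clades (default 3).
#' @param pops_per_group Populations per group (default 3).
#' @param inds_per_pop Diploid individuals per population; a single value or
#'   a range `c(min, max)` sampled per population (default 10; field designs
#'   run 5-20).
#' @param n_loci Number of biallelic SNPs (default 2000).
#' @param prop_adaptive Proportion of loci tracking the environment
#'   (default 0.02).
#' @param f_group,f_pop Balding-Nichols drift parameters for the
#'   group-from-ancestral and population-from-group Beta draws. Defaults
#'   0.75 / 0.15 give a composite expected Fst of about 0.79, a
#'   deep-clade regime.
#' @param effect_b Clinal slope of adaptive loci on the logit scale per
#'   standard deviation of the driving variable (default 2).
#' @param n_env Number of real environmental variables, the first being
#'   latitude itself (default 6).
#' @param env_collinearity Correlation of each non-latitude variable with
#'   latitude (default 0.8, so collinearity pruning is exercised).
#' @param missing_rate Proportion of genotype calls set missing
#'   (default 0.02).
#' @param missing_mode `"uniform"` or `"population_biased"` (one random
#'   population receives 10x the missing rate).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 3, pops_per_group = 3, inds_per_pop = 10,
                       n_loci = 2000, prop_adaptive = 0.02, f_group = 0.75,
                       f_pop = 0.15, effect_b = 2, n_env = 6,
                       env_collinearity = 0.8, missing_rate = 0.02,
                       missing_mode = c("uniform", "population_biased"),
                       seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  stopifnot(
    n_groups >= 1, pops_per_group >= 1, all(inds_per_pop >= 1),
    n_loci >= 1, prop_adaptive >= 0, prop_adaptive < 1,
    f_group >= 0, f_group < 1, f_pop >= 0, f_pop < 1,
    n_env >= 1, env_collinearity >= 0, env_collinearity <= 1,
    missing_rate >= 0, missing_rate < 1
  )
  structure(
    list(
      n_groups = n_groups, pops_per_group = pops_per_group,
      inds_per_pop = inds_per_pop, n_loci = n_loci,
      prop_adaptive = prop_adaptive, f_group = f_group, f_pop = f_pop,
      effect_b = effect_b, n_env = n_env,
      env_collinearity = env_collinearity, missing_rate = missing_rate,
      missing_mode = missing_mode, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Beta draw with mean m and Balding-Nichols parameter f; f = 0 returns m
rbeta_bn <- function(n, m, f) {
  m <- pmin(pmax(m, 1e-9), 1 - 1e-9)
  if (f <= 0) return(rep_len(m, n))
  a <- m * (1 - f) / f
  b <- (1 - m) * (1 - f) / f
  rbeta(n, a, b)
}

#' Simulate genotypes under hierarchical drift and an environmental cline
#'
#' Populations are placed evenly on a latitude axis, groups occupying
#' contiguous blocks. Neutral loci drift hierarchically: ancestral frequency
#' `p0 ~ Uniform(0.05, 0.95)`, group frequency Beta-distributed around `p0`
#' with parameter `f_group`, population frequency Beta around the group
#' frequency with `f_pop`. Adaptive loci instead follow a cline,
#' `logit(p_pop) = logit(p0) + effect_b * env(pop)` (driving variable:
#' latitude), plus Beta drift noise with `f_pop`. Genotypes are
#' `Binomial(2, p_pop)` per individual; missingness is applied at
#' `missing_rate`. Environmental variables are standardised
#' collinearity-weighted mixtures of latitude and independent noise.
#'
#' @param cfg A [sim_config()].
#' @return List with `genotypes` ([genotype_matrix()]), `pop_map`
#'   ([population_map()] tibble), `env` (tibble, `population_id` +
#'   variables, first variable `latitude`), `truth` (tibble: `locus_id`,
#'   `adaptive`, `driving_variable`, `effect`).
#' @export
simulate_snp_data <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(cfg$seed, simulate_snp_data_impl(cfg))
}

simulate_snp_data_impl <- function(cfg) {
  n_pops <- cfg$n_groups * cfg$pops_per_group
  pops <- sprintf("pop_%02d", seq_len(n_pops))
  groups <- rep(sprintf("clade_%d", seq_len(cfg$n_groups)),
                each = cfg$pops_per_group)

  # latitude axis: evenly spaced, standardised; groups are contiguous blocks
  lat <- as.numeric(scale(seq_len(n_pops)))

  n_ind <- if (length(cfg$inds_per_pop) == 1) {
    rep(cfg$inds_per_pop, n_pops)
  } else {
    sample(seq(cfg$inds_per_pop[1], cfg$inds_per_pop[2]), n_pops, replace = TRUE)
  }
  pop_of_ind <- rep(pops, times = n_ind)
  group_of_ind <- rep(groups, times = n_ind)
  ind_ids <- sprintf("ind_%04d", seq_along(pop_of_ind))

  # environment: latitude first, then collinear mixtures, all standardised
  rho <- cfg$env_collinearity
  env_mat <- matrix(0, n_pops, cfg$n_env)
  env_mat[, 1] <- lat
  if (cfg$n_env > 1) {
    for (j in 2:cfg$n_env) {
      raw <- rho * lat + sqrt(1 - rho^2) * rnorm(n_pops)
      env_mat[, j] <- as.numeric(scale(raw))
    }
  }
  colnames(env_mat) <- c("latitude",
                         if (cfg$n_env > 1) sprintf("envvar_%02d", 2:cfg$n_env))
  env <- dplyr::bind_cols(tibble(population_id = pops), as_tibble(env_mat))

  # locus truth
  n_adapt <- round(cfg$prop_adaptive * cfg$n_loci)
  locus_ids <- sprintf("locus_%05d", seq_len(cfg$n_loci))
  adaptive <- rep(FALSE, cfg$n_loci)
  if (n_adapt > 0) adaptive[sample.int(cfg$n_loci, n_adapt)] <- TRUE

  p0 <- runif(cfg$n_loci, 0.05, 0.95)
  p_pop <- matrix(0, n_pops, cfg$n_loci)
  for (l in seq_len(cfg$n_loci)) {
    if (adaptive[l]) {
      target <- stats::plogis(stats::qlogis(p0[l]) + cfg$effect_b * lat)
      p_pop[, l] <- rbeta_bn(n_pops, target, cfg$f_pop)
    } else {
      pg <- rbeta_bn(cfg$n_groups, p0[l], cfg$f_group)
      p_pop[, l] <- rbeta_bn(n_pops, pg[match(groups, unique(groups))], cfg$f_pop)
    }
  }

  geno <- matrix(
    rbinom(length(pop_of_ind) * cfg$n_loci, 2,
           p_pop[match(pop_of_ind, pops), ]),
    nrow = length(pop_of_ind)
  )

  if (cfg$missing_rate > 0) {
    rate <- rep(cfg$missing_rate, length(pop_of_ind))
    if (cfg$missing_mode == "population_biased") {
      biased <- sample(pops, 1)
      rate[pop_of_ind == biased] <- min(10 * cfg$missing_rate, 0.95)
    }
    drop_mask <- matrix(runif(length(geno)) < rate, nrow = nrow(geno))
    geno[drop_mask] <- NA_integer_
  }

  list(
    genotypes = genotype_matrix(geno, locus_ids = locus_ids,
                                individual_ids = ind_ids),
    pop_map = population_map(ind_ids, pop_of_ind, group_of_ind),
    env = env,
    truth = tibble(
      locus_id = locus_ids, adaptive = adaptive,
      driving_variable = ifelse(adaptive, "latitude", NA_character_),
      effect = ifelse(adaptive, cfg$effect_b, 0)
    )
  )
}

#' Expected pooled differentiation under the simulator
#'
#' Composite Balding-Nichols expectation for the neutral loci:
#' `1 - (1 - f_group) (1 - f_pop)`; the two drift stages compound
#' multiplicatively on heterozygosity.
#'
#' @param cfg A [sim_config()].
#' @return Expected pooled Fst (numeric scalar).
#' @export
expected_fst <- function(cfg) {
  1 - (1 - cfg$f_group) * (1 - cfg$f_pop)
}
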