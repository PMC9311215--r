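env_toy <- function() {
  tibble::tibble(
    population_id = paste0("p", 1:6),
    latitude = c(-35, -38, -41, -43, -45, -47),
    sst = c(18, 16.5, 14, 12.5, 11, 9.8),     # r^2 with latitude ~ 1
    rain = c(1.2, 0.4, 2.1, 0.8, 1.4, 0.2)    # weakly correlated
  )
}

test_that("environment preprocessing standardises and prunes by the inclusive r2 rule", {
  prep <- preprocess_env(env_toy(), r2_max = 0.7)
  expect_true(all(abs(colMeans(prep$env[-1])) < 1e-12))
  expect_true(all(abs(vapply(prep$env[-1], sd, numeric(1)) - 1) < 1e-12))
  expect_equal(prep$kept, c("latitude", "rain"))
  expect_equal(prep$dropped, "sst")
  # priority order decides which of a correlated pair survives
  prep2 <- preprocess_env(env_toy(), r2_max = 0.7,
                          priority = c("sst", "latitude", "rain"))
  expect_true("sst" %in% prep2$kept)
  expect_false("latitude" %in% prep2$kept)
})

test_that("a pair at exactly r2 = 0.7 is retained (threshold is inclusive)", {
  # construct x, y with cor^2 exactly 0.7 up to floating point
  x <- c(-2, -1, 0, 1, 2)
  e <- c(1, -1, 0, 1, -1); e <- e - mean(e)
  e <- e - x * sum(e * x) / sum(x^2) # orthogonalise
  r <- sqrt(0.7)
  y <- r * x / sd(x) + sqrt(1 - r^2) * e / sd(e)
  env <- tibble::tibble(population_id = paste0("p", 1:5), a = x, b = y)
  expect_equal(cor(x, y)^2, 0.7, tolerance = 1e-12)
  prep <- preprocess_env(env, r2_max = 0.7)
  expect_equal(prep$kept, c("a", "b"))
})

test_that("orthogonal variables are all kept and constant variables are fatal", {
  env <- tibble::tibble(population_id = paste0("p", 1:4),
                        a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  expect_equal(preprocess_env(env)$kept, c("a", "b"))
  env$c <- 5
  expect_error(preprocess_env(env), "constant.*c")
})

test_that("modal imputation fills within-group modes with ties toward lower dosage", {
  toy <- toy_dataset(
    list(
      p1 = rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L), c(NA, 1L)),
      p2 = rbind(c(2L, 2L), c(2L, NA), c(2L, 2L), c(1L, 2L))
    ),
    groups = c(p1 = "gA", p2 = "gB")
  )
  out <- impute_modal(toy$g, toy$pm)
  expect_equal(unname(out$genotypes[4, 1]), 0L)  # mode of {0,0,1}
  expect_equal(unname(out$genotypes[6, 2]), 2L)  # mode of {2,2,2}
  # tie {0,0,1,1} resolves to 0
  toy2 <- toy_dataset(list(p1 = rbind(c(0L), c(0L), c(1L), c(1L), c(NA))))
  expect_equal(unname(impute_modal(toy2$g, toy2$pm)$genotypes[5, 1]), 0L)
  # complete matrices pass through unchanged
  expect_identical(impute_modal(out, toy$pm)$genotypes, out$genotypes)
  # a group with zero calls at a locus is directed to the earlier filter
  toy3 <- toy_dataset(list(p1 = rbind(c(NA_integer_), c(NA_integer_), c(0L))[c(1, 2), , drop = FALSE],
                           p2 = rbind(c(0L), c(1L))),
                      groups = c(p1 = "gA", p2 = "gB"))
  expect_error(impute_modal(toy3$g, toy3$pm), "drop_population_missing_loci")
})

test_that("random environment variables are reproducible, standard normal, and well named", {
  pops <- paste0("p", 1:40)
  r1 <- make_random_env(pops, count = 100, seed = 5)
  r2 <- make_random_env(pops, count = 100, seed = 5)
  r3 <- make_random_env(pops, count = 100, seed = 6)
  expect_identical(r1, r2)
  expect_false(identical(r1$ranvar_001, r3$ranvar_001))
  expect_equal(ncol(r1) - 1, 100)
  expect_equal(names(r1)[2], "ranvar_001")
  mu <- colMeans(as.matrix(r1[-1]))
  s <- apply(as.matrix(r1[-1]), 2, sd)
  expect_lt(abs(mean(mu)), 0.1)
  expect_lt(abs(mean(s) - 1), 0.1)
  expect_equal(unname(attr(r1, "provenance")["ranvar_001"]), "random")
})

test_that("the RDA full-model permutation test matches a direct pseudo-F computation", {
  sim <- simulate_snp_data(sim_config(n_groups = 1, pops_per_group = 8,
                                      inds_per_pop = 6, n_loci = 150,
                                      prop_adaptive = 0.1, f_group = 0,
                                      f_pop = 0.1, effect_b = 3, n_env = 3,
                                      missing_rate = 0, seed = 12))
  prep <- preprocess_env(sim$env)
  res <- rda_full_model_test(sim$genotypes, sim$pop_map, prep$env,
                             n_perm = 99, seed = 2)
  # independent pseudo-F via explicit least squares
  y <- scale(sim$genotypes$genotypes, center = TRUE, scale = FALSE)
  x <- as.matrix(prep$env[-1])[match(sim$pop_map$population_id,
                                     prep$env$population_id), ]
  fit <- lm.fit(cbind(1, x), y)
  ssr <- sum(fit$fitted.values^2)
  sse <- sum(fit$residuals^2)
  m <- ncol(x)
  f_manual <- (ssr / m) / (sse / (nrow(y) - m - 1))
  expect_equal(res$statistic, f_manual, tolerance = 1e-8)
  expect_equal(res$df_model, m)
  # determinism under the seed; p bounded below by 1/(n_perm+1)
  res2 <- rda_full_model_test(sim$genotypes, sim$pop_map, prep$env,
                              n_perm = 99, seed = 2)
  expect_identical(res$p_value, res2$p_value)
  expect_gte(res$p_value, 1 / 100)
  # strong planted signal attains the minimum p
  expect_equal(res$p_value, 1 / 100)
})

test_that("the full-model pseudo-F is null-behaved for exchangeable individuals", {
  # drift-free single population: individuals are iid draws, so the
  # environment is orthogonal to all genotype variation in expectation
  sim <- simulate_snp_data(sim_config(n_groups = 1, pops_per_group = 8,
                                      inds_per_pop = 6, n_loci = 100,
                                      prop_adaptive = 0, f_group = 0,
                                      f_pop = 0, n_env = 2,
                                      missing_rate = 0, seed = 13))
  ps <- vapply(1:5, function(s) {
    env <- sim$env
    set.seed(100 + s)
    env[-1] <- env[sample(nrow(env)), -1]
    rda_full_model_test(sim$genotypes, sim$pop_map, env, n_perm = 99,
                        seed = s)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.2) # no systematic signal
})

test_that("rda associations: constrained decomposition agrees with vegan and planted loci dominate", {
  sim <- simulate_snp_data(sim_config(n_groups = 1, pops_per_group = 9,
                                      inds_per_pop = 8, n_loci = 300,
                                      prop_adaptive = 0.05, f_group = 0,
                                      f_pop = 0.12, effect_b = 3, n_env = 3,
                                      env_collinearity = 0.3,
                                      missing_rate = 0, seed = 19))
  prep <- preprocess_env(sim$env)
  gea <- suppressWarnings(rda_associations(sim$genotypes, sim$pop_map, prep$env))
  # cross-check constrained eigenvalues against vegan's RDA
  y <- sim$genotypes$genotypes
  xdf <- as.data.frame(as.matrix(prep$env[-1])[match(sim$pop_map$population_id,
                                                     prep$env$population_id), ])
  mod <- vegan::rda(y ~ ., data = xdf)
  expect_equal(gea$eig[1:3], unname(mod$CCA$eig[1:3]), tolerance = 1e-6)

  # planted clinal loci take the extreme z for the driving variable
  tab <- gea$table[gea$table$variable == "latitude", ]
  adaptive <- sim$truth$locus_id[sim$truth$adaptive]
  top <- tab$locus_id[order(-abs(tab$z))][seq_along(adaptive)]
  expect_gt(mean(adaptive %in% top), 0.7)
})

test_that("a noiseless linear locus attains the maximal |z| for its variable", {
  pops <- paste0("p", 1:8)
  env <- tibble::tibble(population_id = pops, v = as.numeric(scale(1:8)))
  set.seed(33)
  n_per <- 6
  geno <- matrix(rbinom(8 * n_per * 60, 2, 0.5), nrow = 8 * n_per)
  # plant: dosage proportional to v (exact linear function, no noise)
  lin <- rep(round((env$v - min(env$v)) / diff(range(env$v)) * 2), each = n_per)
  geno <- cbind(geno, as.integer(lin))
  colnames(geno) <- c(sprintf("l%02d", 1:60), "planted")
  ids <- sprintf("i%03d", seq_len(nrow(geno)))
  rownames(geno) <- ids
  g <- genotype_matrix(geno)
  pm <- population_map(ids, rep(pops, each = n_per))
  gea <- suppressWarnings(rda_associations(g, pm, env))
  tab <- gea$table
  expect_equal(tab$locus_id[which.max(abs(tab$z))], "planted")
})

test_that("rda association p-values are near-uniform for pure-noise loci", {
  sim <- simulate_snp_data(sim_config(n_groups = 1, pops_per_group = 10,
                                      inds_per_pop = 8, n_loci = 800,
                                      prop_adaptive = 0, f_group = 0,
                                      f_pop = 0.05, n_env = 2,
                                      env_collinearity = 0,
                                      missing_rate = 0, seed = 27))
  gea <- suppressWarnings(rda_associations(sim$genotypes, sim$pop_map, sim$env))
  for (v in unique(gea$table$variable)) {
    p <- gea$table$p_value[gea$table$variable == v]
    expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
  }
})

test_that("rda associations are equivariant to sign flips of a variable", {
  sim <- simulate_snp_data(sim_config(n_groups = 1, pops_per_group = 6,
                                      inds_per_pop = 5, n_loci = 120,
                                      prop_adaptive = 0, f_pop = 0.1,
                                      n_env = 2, missing_rate = 0, seed = 8))
  env <- sim$env
  gea1 <- suppressWarnings(rda_associations(sim$genotypes, sim$pop_map, env))
  env$latitude <- -env$latitude
  gea2 <- suppressWarnings(rda_associations(sim$genotypes, sim$pop_map, env))
  a <- gea1$table[gea1$table$variable == "latitude", ]
  b <- gea2$table[gea2$table$variable == "latitude", ]
  expect_equal(abs(a$z), abs(b$z), tolerance = 1e-8)
  expect_equal(a$q_value, b$q_value, tolerance = 1e-8)
})

test_that("per-variable fits reduce to the single-variable decomposition", {
  sim <- simulate_snp_data(sim_config(n_groups = 1, pops_per_group = 6,
                                      inds_per_pop = 5, n_loci = 100,
                                      prop_adaptive = 0, f_pop = 0.1,
                                      n_env = 2, missing_rate = 0, seed = 44))
  env1 <- sim$env[, c("population_id", "latitude")]
  joint <- suppressWarnings(rda_associations(sim$genotypes, sim$pop_map, env1))
  per <- suppressWarnings(rda_associations(sim$genotypes, sim$pop_map,
                                           sim$env, per_variable = TRUE))
  a <- joint$table[joint$table$variable == "latitude", ]
  b <- per$table[per$table$variable == "latitude", ]
  expect_equal(a$z, b$z, tolerance = 1e-10)
})

test_that("external GEA ingestion builds the grid and validates input", {
  f <- file.path(tempdir(), "gea.tsv")
  grid <- tidyr::expand_grid(locus_id = paste0("l", 1:4),
                             variable = c("latitude", "sst"))
  grid$q_value <- seq(0.05, 0.4, length.out = 8)
  readr::write_tsv(grid, f)
  gea <- ingest_external_gea(f, method = "bayescenv")
  expect_s3_class(gea, "gea_scan")
  expect_equal(nrow(gea$table), 8)
  expect_equal(gea$table$method[1], "bayescenv")

  env <- tibble::tibble(population_id = "p1", latitude = 1)
  expect_warning(ingest_external_gea(f, env = env), "unknown.*sst")

  grid$q_value[1] <- -0.1
  readr::write_tsv(grid, f)
  expect_error(ingest_external_gea(f), "\\[0, 1\\]")
})

test_that("broad-sense combination pools the anchor-correlated set by geometric mean", {
  env <- env_toy()
  tab <- tidyr::expand_grid(locus_id = c("l1", "l2"),
                            variable = c("latitude", "sst", "rain"))
  tab$q_value <- c(0.001, 0.2, 0.9, 0.04, 0.04, 0.04)
  out <- broad_sense_combine(tab, "latitude", env, r2_min = 0.7)
  # correlated set = {latitude, sst}; rain excluded
  expect_equal(out$n_vars, c(2L, 2L))
  expect_equal(out$q_broad[out$locus_id == "l1"], sqrt(0.001 * 0.2),
               tolerance = 1e-12)
  expect_equal(out$q_broad[out$locus_id == "l2"], 0.04, tolerance = 1e-12)
  # a set of one variable returns that variable's q unchanged
  solo <- broad_sense_combine(tab[tab$variable == "rain", ], "rain", env)
  expect_equal(solo$q_broad, tab$q_value[tab$variable == "rain"],
               tolerance = 1e-12)
})
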