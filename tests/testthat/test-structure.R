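test_that("PCA separates duplicated clusters on PC1 with ~all the variance", {
  a <- rep(c(0L, 2L, 0L, 2L), each = 5)
  b <- rep(c(2L, 0L, 2L, 0L), each = 5)
  geno <- rbind(matrix(a, 5, 4, byrow = FALSE), matrix(b, 5, 4))
  geno <- cbind(geno, geno) # 8 loci, two identical clusters of individuals
  toy <- toy_dataset(list(p1 = geno[1:5, ], p2 = geno[6:10, ]))
  pc <- pca_genotypes(toy$g, n_axes = 3)
  expect_gt(pc$prop_var[1], 0.999)
  s <- tidy(pc)$PC1
  expect_true(all(s[1:5] * s[6:10] < 0)) # opposite sides
})

test_that("PCA scores reproduce an independent eigendecomposition of the centred covariance", {
  sim <- simulate_snp_data(sim_config(n_loci = 80, inds_per_pop = 5,
                                      missing_rate = 0, seed = 17))
  g <- sim$genotypes
  pc <- pca_genotypes(g, n_axes = 4)
  x <- scale(g$genotypes, center = TRUE, scale = FALSE)
  eig <- eigen(tcrossprod(x) / (nrow(x) - 1), symmetric = TRUE)
  # explained variance proportions agree
  expect_equal(pc$prop_var[1:4],
               (eig$values / sum(eig$values))[1:4], tolerance = 1e-8)
  # scores agree up to per-axis sign
  sc <- as.matrix(tidy(pc)[, paste0("PC", 1:4)])
  ref <- eig$vectors[, 1:4] %*% diag(sqrt(eig$values[1:4] * (nrow(x) - 1)))
  for (j in 1:4) {
    expect_equal(abs(cor(sc[, j], ref[, j])), 1, tolerance = 1e-6)
  }
  expect_true(all(diff(pc$prop_var) <= 1e-12))
})

test_that("three simulated clades form three clusters in the first two axes", {
  sim <- simulate_snp_data(sim_config(n_loci = 500, f_group = 0.6, f_pop = 0.05,
                                      missing_rate = 0.02, seed = 23))
  pc <- pca_genotypes(sim$genotypes, n_axes = 2)
  sc <- dplyr::left_join(tidy(pc), sim$pop_map, by = "individual_id")
  cent <- sc %>%
    dplyr::group_by(group_id) %>%
    dplyr::summarise(x = mean(PC1), y = mean(PC2))
  # cluster separation: min between-centroid distance exceeds the max
  # within-clade spread
  dmin <- min(dist(cent[, c("x", "y")]))
  spread <- sc %>%
    dplyr::left_join(cent, by = "group_id") %>%
    dplyr::mutate(r = sqrt((PC1 - x)^2 + (PC2 - y)^2)) %>%
    dplyr::pull(r)
  expect_gt(dmin, 2 * max(spread))
})

test_that("constant genotype matrices are rejected by PCA", {
  toy <- toy_dataset(list(p1 = matrix(1L, 3, 4), p2 = matrix(1L, 3, 4)))
  expect_error(pca_genotypes(toy$g), "constant")
})

test_that("identical populations take the maximal relative migration rate", {
  same <- rbind(c(0L, 1L, 2L), c(1L, 2L, 0L), c(2L, 0L, 1L), c(1L, 1L, 1L))
  toy <- toy_dataset(list(p1 = same, p2 = same))
  m <- relative_migration(toy$g, toy$pm)
  expect_equal(m["p1", "p2"], 1)
  expect_equal(m["p2", "p1"], 1)
  expect_true(is.na(m["p1", "p1"]))
})

test_that("fixed-alternate pairs show negligible migration relative to a connected pair", {
  toy <- toy_dataset(list(
    p1 = rbind(c(0L, 1L), c(1L, 0L), c(0L, 1L)),
    p2 = rbind(c(0L, 1L), c(1L, 1L), c(1L, 0L)), # similar to p1
    p3 = rbind(c(2L, 2L), c(2L, 2L), c(2L, 2L))  # fixed alternate
  ))
  m <- relative_migration(toy$g, toy$pm)
  expect_lt(max(m["p1", "p3"], m["p3", "p1"]), 0.05)
  expect_gt(max(m["p1", "p2"], m["p2", "p1"]), 0.5)
})

test_that("migration is inferred higher into the more diverse member of a pair", {
  # a diverse population sits closer to the pairwise pool than a near-fixed
  # one, so the directional rate into it is larger (migrants homogenise the
  # receiving population)
  set.seed(5)
  n <- 40
  div <- matrix(rbinom(n * 80, 2, 0.5), n)   # high gene diversity
  fixd <- matrix(rbinom(n * 80, 2, 0.95), n) # nearly fixed everywhere
  toy <- toy_dataset(list(div = div, fixd = fixd))
  m <- relative_migration(toy$g, toy$pm)
  expect_gt(m["fixd", "div"], m["div", "fixd"])
})

test_that("relative migration is invariant to global allele relabeling", {
  sim <- simulate_snp_data(sim_config(n_groups = 2, pops_per_group = 2,
                                      inds_per_pop = 6, n_loci = 100,
                                      missing_rate = 0, seed = 31))
  g <- sim$genotypes
  m1 <- relative_migration(g, sim$pop_map)
  flipped <- genotype_matrix(2L - g$genotypes, locus_ids = g$locus_ids,
                             tag_ids = g$tag_ids,
                             individual_ids = g$individual_ids)
  m2 <- relative_migration(flipped, sim$pop_map)
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("monomorphic data are rejected by relative migration", {
  toy <- toy_dataset(list(p1 = matrix(0L, 3, 3), p2 = matrix(0L, 3, 3)))
  expect_error(relative_migration(toy$g, toy$pm), "monomorphic")
})

test_that("migration-distance correlation recovers perfect decay and behaves under the null", {
  d <- as.matrix(dist(c(0, 100, 250, 600)))
  m <- 1 - d / (2 * max(d)) # rates linearly decreasing in distance
  diag(m) <- NA
  ct <- migration_distance_correlation(m, d)
  expect_lt(ct$estimate, -0.999)
  expect_lt(ct$p_value, 0.01)

  # permuted distances: near-zero correlation on average
  set.seed(8)
  r <- replicate(50, {
    perm <- sample(4)
    migration_distance_correlation(m, d[perm, perm])$estimate
  })
  expect_lt(abs(mean(r)), 0.25)

  expect_error(migration_distance_correlation(m[1:2, 1:2], d[1:2, 1:2]), "3")
})
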