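# Independent brute-force oracles, written from first principles with plain
# loops so they share no code path with the package implementations.

# Nei diversity from explicit per-population genotype lists ------------------
# geno_by_pop: named list of integer vectors-of-vectors: each element is a
# matrix (individuals x loci) of dosages for one population, no missing data.
oracle_nei <- function(geno_by_pop) {
  n_loci <- ncol(geno_by_pop[[1]])
  ho_l <- hs_l <- ht_l <- numeric(n_loci)
  for (l in seq_len(n_loci)) {
    het_total <- 0
    n_total <- 0
    hs_terms <- c()
    p_list <- c()
    for (pop in geno_by_pop) {
      gl <- pop[, l]
      n <- length(gl)
      p <- sum(gl) / (2 * n)
      het_total <- het_total + sum(gl == 1)
      n_total <- n_total + n
      hs_terms <- c(hs_terms, 2 * p * (1 - p) * n / (n - 1))
      p_list <- c(p_list, p)
    }
    ho_l[l] <- het_total / n_total
    hs_l[l] <- mean(hs_terms)
    pb <- mean(p_list)
    ht_l[l] <- 2 * pb * (1 - pb)
  }
  ho <- mean(ho_l); hs <- mean(hs_l); ht <- mean(ht_l)
  list(ho = ho, hs = hs, ht = ht, fst = (ht - hs) / ht, fis = 1 - ho / hs,
       per_locus = list(ho = ho_l, hs = hs_l, ht = ht_l))
}

# Weir & Cockerham (1984) variance components for ONE locus, two populations,
# from explicit genotype vectors (no missing data)
oracle_wc_one_locus <- function(g1, g2) {
  r <- 2
  ns <- c(length(g1), length(g2))
  ps <- c(sum(g1) / (2 * ns[1]), sum(g2) / (2 * ns[2]))
  hs <- c(mean(g1 == 1), mean(g2 == 1))
  nbar <- mean(ns)
  nc <- (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ns * ps) / (r * nbar)
  s2 <- sum(ns * (ps - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ns * hs) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# Benjamini-Hochberg step-up by direct definition ---------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    adj[o[i]] <- running
  }
  adj
}

# build a genotype_matrix + population_map from per-population dosage
# matrices (rows = individuals)
toy_dataset <- function(geno_by_pop, groups = NULL) {
  mats <- lapply(geno_by_pop, as.matrix)
  geno <- do.call(rbind, mats)
  pops <- rep(names(geno_by_pop), vapply(mats, nrow, integer(1)))
  ids <- sprintf("t%03d", seq_len(nrow(geno)))
  rownames(geno) <- ids
  list(
    g = genotype_matrix(geno),
    pm = population_map(ids, pops,
                        if (!is.null(groups)) groups[pops] else NULL)
  )
}

# small neutral two-cluster dataset used by several scan tests
neutral_two_clusters <- function(seed = 1, n_loci = 300) {
  simulate_snp_data(sim_config(
    n_groups = 2, pops_per_group = 2, inds_per_pop = 10, n_loci = n_loci,
    prop_adaptive = 0, f_group = 0.2, f_pop = 0, missing_rate = 0,
    seed = seed
  ))
}
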