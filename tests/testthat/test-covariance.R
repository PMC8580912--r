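test_that("genetic covariance matrix matches the printed components", {
  expect_equal(genetic_cov_matrix(scenario_table1("I")$pair),
               matrix(c(1, -0.5, -0.5, 1), 2))
  p0 <- trait_pair(trait_params(2), trait_params(3), 0)
  expect_equal(genetic_cov_matrix(p0), diag(c(2, 3)))
  # yield-protein genetic covariance by direct arithmetic
  expect_equal(genetic_cov_matrix(scenario_wheat(1)$pair)[1, 2],
               -0.270111, tolerance = 1e-5)
})

test_that("phenotypic entry-mean variance dilutes masking components by L, T, LT", {
  pair <- scenario_table1("I")$pair
  expect_equal(phenotypic_cov_matrix(pair, 1, 1)[1, 1], 7.04)
  expect_equal(phenotypic_cov_matrix(pair, 5, 1)[1, 1],
               1 + 0.91 / 5 + 0.33 + 0.52 / 5 + 4.28 / 5)
  # masking vanishes in the limit of many locations and testers
  expect_equal(phenotypic_cov_matrix(pair, 1e9, 1e9),
               genetic_cov_matrix(pair), tolerance = 1e-6)
  expect_error(phenotypic_cov_matrix(pair, 0, 1), ">= 1")
})

test_that("GEBV structure has accuracy r per trait and preserves the genetic correlation", {
  pair <- scenario_table1("I")$pair
  gc <- genomic_cov_structure(pair, c(0.3, 0.5))
  # corr(u_k, g_k) = r_k
  expect_equal(gc$C[1, 1] / sqrt(gc$V[1, 1] * 1), 0.3)
  expect_equal(gc$C[2, 2] / sqrt(gc$V[2, 2] * 1), 0.5)
  # GEBVs of the two traits keep the genetic correlation
  expect_equal(gc$V[1, 2] / sqrt(gc$V[1, 1] * gc$V[2, 2]), -0.5)
  # perfect accuracy: GEBV structure degenerates to the genetic one
  gc1 <- genomic_cov_structure(pair, c(1, 1))
  expect_equal(gc1$V, genetic_cov_matrix(pair))
  expect_equal(gc1$C, genetic_cov_matrix(pair))
  expect_error(genomic_cov_structure(pair, c(1.2, 0.3)), "\\[0, 1\\]")
})

test_that("Smith-Hazel weights solve P b = G a", {
  expect_equal(smith_hazel_weights(2 * diag(2), diag(2), c(1, 1)), c(0.5, 0.5))
  # single-trait reduction for diagonal structure
  P <- diag(c(4, 9)); G <- diag(c(1, 2))
  expect_equal(smith_hazel_weights(P, G, c(1, 0)), c(1 / 4, 0))
  # scenario I, L = 5, T = 1, against an explicit Cramer's-rule oracle
  pair <- scenario_table1("I")$pair
  P <- phenotypic_cov_matrix(pair, 5, 1)
  G <- genetic_cov_matrix(pair)
  v <- G %*% c(1, 1)
  det <- P[1, 1] * P[2, 2] - P[1, 2]^2
  oracle <- c(P[2, 2] * v[1] - P[1, 2] * v[2],
              P[1, 1] * v[2] - P[1, 2] * v[1]) / det
  expect_equal(smith_hazel_weights(P, G, c(1, 1)), oracle, tolerance = 1e-12)
  # scale equivariance in the economic weights
  expect_equal(smith_hazel_weights(P, G, 3 * c(1, 1)),
               3 * smith_hazel_weights(P, G, c(1, 1)))
})

test_that("base index weights are the economic weights", {
  expect_equal(base_weights(economic_weights(c(1, 1))), c(1, 1))
  expect_equal(base_weights(economic_weights(c(2, 0))), c(2, 0))
  expect_equal(base_weights(economic_weights(c(1, 0.12))), c(1, 0.12))
})

test_that("restricted index zeroes the covariance with the restricted trait", {
  set.seed(11)
  for (i in 1:25) {
    A <- matrix(rnorm(4), 2); P <- tcrossprod(A) + diag(2)
    B <- matrix(rnorm(4), 2); G <- tcrossprod(B) + 0.2 * diag(2)
    a <- rnorm(2)
    for (rt in 1:2) {
      b <- restricted_weights(P, G, a, rt)
      expect_lt(abs(sum(b * G[, rt])), 1e-10)
    }
  }
  # diagonal structure decouples: restricting trait 2 leaves pure trait-1 weights
  P <- diag(c(4, 9)); G <- diag(c(1, 2))
  expect_equal(restricted_weights(P, G, c(1, 1), 2), c(1 / 4, 0))
  # degenerate restriction is rejected
  expect_error(restricted_weights(diag(2), diag(c(1, 0)), c(1, 1), 2),
               "degenerate")
})

test_that("criterion structure reproduces closed-form correlations", {
  pair <- scenario_table1("I")$pair
  a <- economic_weights(c(1, 1))
  # single trait, one phenotypic stage, L = T = 1: corr = sqrt(h^2) = 1/sqrt(7.04)
  st <- toy_one_stage()
  al <- allocation(40, 10, locations = 1, testers = 1)
  cs <- build_criterion_structure(st, al, pair, a, "single", single_trait = 1)
  expect_equal(cs$rho_targets[1, "g1"], 1 / sqrt(7.04), tolerance = 1e-12,
               ignore_attr = TRUE)
  # perfect-accuracy genomic stage: SH index correlates perfectly with H
  stg <- gs_rapid(c(1, 1))
  alg <- gsrapid_alloc()
  csg <- build_criterion_structure(stg, alg, pair, a, "sh")
  expect_equal(csg$rho_targets[1, "H"], 1, tolerance = 1e-10, ignore_attr = TRUE)
  # two identical phenotypic stages: cross-stage entry is b'Gb / sigma_I^2
  stp <- ps_standard()
  alp <- psstandard_alloc(2000, 40, L2 = 5, T2 = 2, L3 = 5, T3 = 2)
  csp <- build_criterion_structure(stp, alp, pair, a, "sh")
  b <- csp$weights[[1]]
  G <- genetic_cov_matrix(pair)
  expect_equal(csp$R[1, 2],
               as.numeric(t(b) %*% G %*% b) / csp$sigma_I[1]^2,
               tolerance = 1e-12)
})

test_that("swapping trait labels in a symmetric scenario swaps outcomes exactly", {
  sc <- scenario_table1("I")
  st <- gs_rapid(c(0.3, 0.3))
  al <- gsrapid_alloc()
  r12 <- index_gain(st, al, sc$pair, sc$weights, "sh")
  expect_equal(r12$dg_trait[1], r12$dg_trait[2], tolerance = 1e-12)
  # asymmetric weights: swapping traits and weights swaps per-trait gains
  a <- economic_weights(c(0.7, 1.3))
  g_fwd <- index_gain(st, al, sc$pair, a, "sh")
  pair_swapped <- trait_pair(sc$pair$trait2, sc$pair$trait1, sc$pair$rho_genetic)
  g_swp <- index_gain(st, al, pair_swapped, economic_weights(c(1.3, 0.7)), "sh")
  expect_equal(g_fwd$dg_trait, rev(g_swp$dg_trait), tolerance = 1e-10)
  expect_equal(g_fwd$dg_net, g_swp$dg_net, tolerance = 1e-10)
})

test_that("gains transform consistently under changes of trait units", {
  # rescale trait 2 by c: its variance components scale by c^2, covariances by c
  sc <- scenario_table1("V")
  cc <- 2.5
  t2 <- sc$pair$trait2
  t2s <- trait_params(t2$var_gca * cc^2, t2$var_gca_x_loc * cc^2,
                      t2$var_sca * cc^2, t2$var_sca_x_loc * cc^2,
                      t2$var_error * cc^2)
  pair_s <- trait_pair(sc$pair$trait1, t2s, sc$pair$rho_genetic)
  st <- gs_rapid(c(0.3, 0.3))
  al <- gsrapid_alloc()
  a <- as.numeric(sc$weights)
  g0 <- index_gain(st, al, sc$pair, sc$weights, "sh")
  # counter-scaled weights keep net merit invariant; trait-2 gain scales by c
  g1 <- index_gain(st, al, pair_s, economic_weights(c(a[1], a[2] / cc)), "sh")
  expect_equal(g1$dg_net, g0$dg_net, tolerance = 1e-9)
  expect_equal(g1$dg_trait[2], cc * g0$dg_trait[2], tolerance = 1e-9)
  expect_equal(g1$dg_trait[1], g0$dg_trait[1], tolerance = 1e-9)
})

test_that("SH and base indices coincide when P is proportional to G", {
  G <- matrix(c(1, 0.3, 0.3, 2), 2)
  b_sh <- smith_hazel_weights(3 * G, G, c(1, 0.5))
  expect_equal(b_sh / b_sh[1], c(1, 0.5) / 1, tolerance = 1e-12)
})
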