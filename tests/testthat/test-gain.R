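test_that("single-stage single-trait gain equals the Cochran closed form", {
  sc <- scenario_table1("I")
  st <- toy_one_stage()
  al <- allocation(40, 10, locations = 1, testers = 1)  # alpha = 0.5
  g <- index_gain(st, al, sc$pair, sc$weights, "single", single_trait = 1)
  expect_equal(g$dg_trait[1], sqrt(1 / 7.04) * 2 * dnorm(0), tolerance = 1e-9)
  # correlated response of trait 2 through rho_G
  expect_equal(g$dg_trait[2], -0.5 * g$dg_trait[1], tolerance = 1e-9)
})

test_that("net-merit gain equals the weighted sum of trait gains for every index", {
  st <- gs_rapid(c(0.3, 0.5))
  al <- gsrapid_alloc()
  for (id in c("I", "III", "V", "VI")) {
    sc <- scenario_table1(id)
    a <- as.numeric(sc$weights)
    for (kind in c("sh", "base", "restricted")) {
      g <- index_gain(st, al, sc$pair, sc$weights, kind)
      expect_equal(g$dg_net, sum(a * g$dg_trait),
                   tolerance = 1e-9 * max(1, abs(g$dg_net)))
      expect_equal(g$dg_annual_net, g$dg_net / st$cycle_years)
    }
  }
})

test_that("restricted index yields exactly zero gain in the restricted trait", {
  st <- gs_rapid(c(0.3, 0.3))
  al <- gsrapid_alloc()
  for (id in c("I", "II", "III", "VI", "VII")) {
    sc <- scenario_table1(id)
    g <- index_gain(st, al, sc$pair, sc$weights, "restricted",
                    restricted_trait = 2L)
    expect_lt(abs(g$dg_trait[2]), 1e-9)
    expect_gt(g$dg_trait[1], 0)
  }
})

test_that("weight (2, 0) base index degenerates to single-trait selection", {
  sc <- scenario_table1("IV")  # weights (2, 0)
  st <- gs_rapid(c(0.3, 0.3))
  al <- gsrapid_alloc()
  # base weights (2, 0) are the trait-1 indicator up to scale: same criterion
  g_b <- index_gain(st, al, sc$pair, sc$weights, "base")
  g_st <- index_gain(st, al, sc$pair, sc$weights, "single", single_trait = 1)
  expect_equal(g_b$dg_trait, g_st$dg_trait, tolerance = 1e-9)
  # the SH index still uses the correlated trait 2 as a predictor of g1, so
  # it improves (weakly) on the single-trait criterion for the same target
  g_sh <- index_gain(st, al, sc$pair, sc$weights, "sh")
  expect_gte(g_sh$dg_trait[1], g_st$dg_trait[1] - 1e-9)
})

test_that("annualize divides exactly and rejects non-positive years", {
  sc <- scenario_table1("I")
  g <- index_gain(gs_rapid(), gsrapid_alloc(), sc$pair, sc$weights, "sh")
  g4 <- annualize(g, 4)
  expect_equal(g4$dg_annual_net, g$dg_net / 4)
  expect_equal(annualize(g, 1)$dg_annual_net, g$dg_net)
  expect_equal(annualize(g, 8)$dg_annual_trait, g$dg_trait / 8)
  expect_error(annualize(g, 0), "positive")
})

test_that("single-stage ICL with uncorrelated traits factorizes per trait", {
  # equal components, zero genetic correlation: culling on one trait does not
  # move the other
  pair <- scenario_table1("II")$pair
  st <- toy_one_stage()
  al <- allocation(80, 20, locations = 1, testers = 1)  # stage fraction 0.25
  g <- icl_gain(st, al, pair, economic_weights(c(1, 1)),
                matrix(c(0.5, 0.5), 1))
  h <- 1 / sqrt(7.04)
  expect_equal(g$dg_trait[1], h * 2 * dnorm(0), tolerance = 1e-7)
  expect_equal(g$dg_trait[2], h * 2 * dnorm(0), tolerance = 1e-7)
  expect_equal(g$dg_net, sum(g$dg_trait), tolerance = 1e-12)
})

test_that("single-stage correlated ICL matches the Monte-Carlo oracle", {
  sc <- scenario_table1("I")
  st <- toy_one_stage()
  al <- allocation(80, 20, locations = 2, testers = 1)
  culling <- matrix(c(0.4, 0.625), 1)  # product = 0.25
  g <- icl_gain(st, al, sc$pair, sc$weights, culling)
  cs <- build_criterion_structure(st, al, sc$pair, sc$weights, "icl")
  sch <- indexgain:::icl_truncation_scheme(cs$R, stage_fractions(st, al), culling)
  for (k in 1:2) {
    mc <- mc_oracle(cs$rho_targets[, k + 1], sch, n_draws = 4e5, seed = 40 + k)
    expect_lt(abs(g$dg_trait[k] / cs$sd_targets[k + 1] - mc$mean), 3 * mc$se)
  }
})

test_that("ICL culling fractions must multiply to the stage fractions", {
  sc <- scenario_table1("I")
  st <- toy_one_stage()
  al <- allocation(80, 20, locations = 1, testers = 1)
  expect_error(icl_gain(st, al, sc$pair, sc$weights, matrix(c(0.5, 0.4), 1)),
               "multiply")
  # zero target correlations give zero gains: weights on a trait with no
  # criterion correlation
  g0 <- icl_gain(st, al, sc$pair, sc$weights, matrix(c(0.25, 1), 1))
  expect_true(is.finite(g0$dg_net))
})

test_that("culling-fraction search respects symmetry and degenerate weights", {
  st <- gs_rapid(c(0.3, 0.3))
  al <- gsrapid_alloc(2000, 60)
  # symmetric scenario: optimal split is symmetric (grid contains w = 0.5)
  scI <- scenario_table1("I")
  sI <- icl_search_fractions(st, al, scI$pair, scI$weights, n_combos = 441)
  expect_equal(sI$culling[, 1], sI$culling[, 2], tolerance = 1e-9)
  # all weight on trait 1: no culling pressure left on trait 2
  scIV <- scenario_table1("IV")
  sIV <- icl_search_fractions(st, al, scIV$pair, scIV$weights, n_combos = 441)
  expect_gt(min(sIV$culling[, 2]), 0.95)
  # the search never returns less net merit than the equal split it contains
  eq <- cbind(sqrt(stage_fractions(st, al)), sqrt(stage_fractions(st, al)))
  expect_gte(sI$result$dg_net,
             icl_gain(st, al, scI$pair, scI$weights, eq)$dg_net - 1e-12)
})
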