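# Shared helpers: random valid joint correlation structures, small strategy /
# allocation builders, and a session-level cache so acceptance blocks reuse
# expensive optimizations instead of recomputing them per test.

# random (d+1)-variate correlation structure: first variable is the target
random_target_structure <- function(d) {
  A <- matrix(rnorm((d + 1)^2), d + 1)
  S <- tcrossprod(A) + diag(d + 1) * 0.5
  Dm <- diag(1 / sqrt(diag(S)))
  C <- Dm %*% S %*% Dm
  list(rho = C[1, -1, drop = TRUE], R = C[-1, -1, drop = FALSE])
}

# one nursery + one phenotypic stage, unit cycle; handy for closed-form checks
toy_one_stage <- function(final_count = 5L) {
  strategy("toy", list(stage_nursery(), stage_phenotypic()),
           cycle_years = 1, final_count = final_count)
}

# a feasible mid-sized GSrapid allocation (not optimal, just valid)
gsrapid_alloc <- function(n_ini = 2000, n2 = 100, L = 10, T = 3) {
  allocation(n_ini, c(round(0.25 * n_ini), n2),
             locations = c(NA, L), testers = c(NA, T))
}

psstandard_alloc <- function(n_ini = 2000, n2 = 40, L2 = 5, T2 = 1,
                             L3 = 10, T3 = 6) {
  allocation(n_ini, c(round(0.25 * n_ini), n2),
             locations = c(L2, L3), testers = c(T2, T3))
}

# session-level cache for expensive optimizations shared across test blocks
.opt_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.opt_cache[[key]])) .opt_cache[[key]] <- force(expr)
  .opt_cache[[key]]
}

opt_scenario <- function(id, strategy_name, index_kind, accuracy = 0.3) {
  key <- paste(id, strategy_name, index_kind, accuracy, sep = "_")
  cached(key, {
    sc <- if (grepl("^wheat", id)) {
      scenario_wheat(as.integer(sub("wheat_goal", "", id)))
    } else {
      scenario_table1(id)
    }
    st <- if (strategy_name == "GSrapid") {
      gs_rapid(c(accuracy, accuracy))
    } else {
      ps_standard()
    }
    args <- list(st, sc$pair, sc$weights, index_kind)
    if (index_kind == "single") args$single_trait <- 1L
    do.call(optimize_allocation, args)
  })
}
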