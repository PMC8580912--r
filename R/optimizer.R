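# Budget accounting and exhaustive grid search over allocations maximizing
# annual net-merit gain. The two built-in stage patterns (nursery-genomic-
# phenotypic and nursery-phenotypic-phenotypic) are evaluated with a
# vectorised closed-form kernel: for two truncation criteria the Tallis
# coefficients need only univariate normal quantities once the second
# truncation point is known, and that point is found by a vectorised
# safeguarded Newton iteration on the bivariate survivor probability. The
# selected optimum is re-evaluated (and its cost re-verified) through the
# general matrix path before being returned.

#' Cost of an allocation in field-plot equivalents
#'
#' Sums DH production (and nursery, if a separate nursery charge is
#' configured), genotyping of candidates entering a genomic stage, hybrid
#' seed production per candidate-by-tester combination entering the first
#' phenotypic stage (one production covers `seed_years_covered` phenotyping
#' years, so a later phenotypic stage pays only for testers added beyond the
#' earlier one), and one plot per candidate-location-tester at each
#' phenotypic stage.
#'
#' @inheritParams validate_allocation
#' @param costs a [cost_model()].
#' @return total cost (plot equivalents), with a `breakdown` attribute.
#' @export
allocation_cost <- function(strat, alloc, costs = cost_model()) {
  post <- strat$stages[-1L]
  n <- alloc$n_stages
  parts <- c(dh = alloc$n_ini * costs$cost_dh,
             nursery = alloc$n_ini * costs$cost_nursery_plot)
  prev_T <- NA_real_
  for (j in seq_along(post)) {
    kind <- post[[j]]$kind
    if (kind == "genomic") {
      parts <- c(parts, stats::setNames(n[j] * costs$cost_genotyping,
                                        paste0("genotyping_", j)))
    } else if (kind == "phenotypic") {
      L <- alloc$locations[j]
      T <- alloc$testers[j]
      seed_T <- if (is.na(prev_T) || costs$seed_years_covered < 2L) {
        T
      } else {
        max(0, T - prev_T)
      }
      parts <- c(parts,
                 stats::setNames(costs$cost_hybrid_seed * n[j] * seed_T,
                                 paste0("seed_", j)),
                 stats::setNames(n[j] * L * T, paste0("plots_", j)))
      prev_T <- T
    }
  }
  total <- sum(parts)
  attr(total, "breakdown") <- parts
  total
}

# ---- vectorised two-criterion machinery ------------------------------------

# Solve P(Z1 >= q1, Z2 >= q2) = t for q2, vectorised (safeguarded Newton;
# the derivative is the analytic conditional ordinate).
.solve_q2_vec <- function(q1, r, t, iters = 16L) {
  s <- sqrt(pmax(1 - r^2, 1e-12))
  a1 <- stats::pnorm(q1, lower.tail = FALSE)
  q <- stats::qnorm(pmin(pmax(t / a1, 1e-300), 1 - 1e-16), lower.tail = FALSE)
  for (i in seq_len(iters)) {
    f <- pbv_upper(q1, q, r) - t
    fp <- -stats::dnorm(q) * stats::pnorm((q1 - r * q) / s, lower.tail = FALSE)
    fp <- pmin(fp, -1e-320)
    delta <- pmin(1.5, pmax(-1.5, -f / fp))
    q <- q + delta
    if (max(abs(delta)) < 1e-13) break
  }
  q
}

# Per-cycle gains for two truncation criteria. rho1, rho2: N x 3 matrices of
# correlations of stage-1/stage-2 criteria with (H, g1, g2); sd: length-3.
# alpha2 = 1 (second stage keeps everything) is handled analytically.
.two_stage_kernel <- function(alpha1, alpha2, r12, rho1, rho2, sd) {
  n <- length(alpha1)
  r <- pmin(0.999999, pmax(-0.999999, r12))
  q1 <- stats::qnorm(alpha1, lower.tail = FALSE)
  t <- alpha1 * alpha2
  w1 <- numeric(n)
  w2 <- numeric(n)
  one <- alpha2 >= 1 - 1e-12
  if (any(one)) w1[one] <- stats::dnorm(q1[one]) / t[one]
  act <- !one
  if (any(act)) {
    q2 <- .solve_q2_vec(q1[act], r[act], t[act])
    s <- sqrt(1 - r[act]^2)
    u1 <- (q2 - r[act] * q1[act]) / s
    u2 <- (q1[act] - r[act] * q2) / s
    w1[act] <- stats::dnorm(q1[act]) * stats::pnorm(u1, lower.tail = FALSE) / t[act]
    w2[act] <- stats::dnorm(q2) * stats::pnorm(u2, lower.tail = FALSE) / t[act]
  }
  cbind(net = sd[1L] * (rho1[, 1L] * w1 + rho2[, 1L] * w2),
        g1 = sd[2L] * (rho1[, 2L] * w1 + rho2[, 2L] * w2),
        g2 = sd[3L] * (rho1[, 3L] * w1 + rho2[, 3L] * w2))
}

# Vectorised index weights and criterion summaries for a phenotypic stage.
.phen_stage_vec <- function(pair, a, kind, L, T, restricted_trait, single_trait) {
  G <- genetic_cov_matrix(pair)
  t1 <- pair$trait1
  t2 <- pair$trait2
  P11 <- t1$var_gca + t1$var_gca_x_loc / L + t1$var_sca / T +
    (t1$var_sca_x_loc + t1$var_error) / (L * T)
  P22 <- t2$var_gca + t2$var_gca_x_loc / L + t2$var_sca / T +
    (t2$var_sca_x_loc + t2$var_error) / (L * T)
  P12 <- G[1L, 2L] + pair$cov_gca_x_loc / L + pair$cov_sca / T +
    (pair$cov_sca_x_loc + pair$cov_error) / (L * T)
  v1 <- G[1L, 1L] * a[1L] + G[1L, 2L] * a[2L]
  v2 <- G[2L, 1L] * a[1L] + G[2L, 2L] * a[2L]
  det <- P11 * P22 - P12^2
  if (kind == "sh") {
    b1 <- (P22 * v1 - P12 * v2) / det
    b2 <- (P11 * v2 - P12 * v1) / det
  } else if (kind == "base") {
    b1 <- rep_len(a[1L], length(P11))
    b2 <- rep_len(a[2L], length(P11))
  } else if (kind == "single") {
    b1 <- rep_len(as.numeric(single_trait == 1L), length(P11))
    b2 <- rep_len(as.numeric(single_trait == 2L), length(P11))
  } else if (kind == "restricted") {
    gr <- G[, restricted_trait]
    Pg1 <- (P22 * gr[1L] - P12 * gr[2L]) / det
    Pg2 <- (P11 * gr[2L] - P12 * gr[1L]) / det
    Pv1 <- (P22 * v1 - P12 * v2) / det
    Pv2 <- (P11 * v2 - P12 * v1) / det
    mu <- (gr[1L] * Pv1 + gr[2L] * Pv2) / (gr[1L] * Pg1 + gr[2L] * Pg2)
    b1 <- Pv1 - mu * Pg1
    b2 <- Pv2 - mu * Pg2
  } else {
    stop("unsupported index kind in grid search: ", kind)
  }
  sig <- sqrt(b1^2 * P11 + 2 * b1 * b2 * P12 + b2^2 * P22)
  covg1 <- b1 * G[1L, 1L] + b2 * G[2L, 1L]
  covg2 <- b1 * G[1L, 2L] + b2 * G[2L, 2L]
  covH <- a[1L] * covg1 + a[2L] * covg2
  list(b1 = b1, b2 = b2, sig = sig, covg1 = covg1, covg2 = covg2, covH = covH)
}

# stage pattern of a strategy: post-nursery kinds pasted, e.g. "GP", "PP"
.stage_pattern <- function(strat) {
  paste(vapply(strat$stages[-1L], function(s) {
    switch(s$kind, genomic = "G", phenotypic = "P", "?")
  }, character(1)), collapse = "")
}

# Evaluate a grid of candidate allocations for a two-post-stage strategy.
# grid: data.frame with n2 and L/T columns depending on the pattern.
# Returns the grid augmented with n_ini, n1, cost, feasibility and annual
# gains.
.grid_eval <- function(strat, pair, a, kind, costs, grid,
                       restricted_trait, single_trait) {
  pat <- .stage_pattern(strat)
  frac <- strat$stages[[1L]]$selected_fraction
  fc <- strat$final_count
  B <- costs$budget
  a <- as.numeric(a)
  G <- genetic_cov_matrix(pair)
  sdg <- sqrt(diag(G))
  sdH <- sqrt(as.numeric(t(a) %*% G %*% a))
  sd3 <- c(sdH, sdg)

  if (pat == "GP") {
    gsst <- strat$stages[[2L]]
    gc <- genomic_cov_structure(pair, gsst$accuracy)
    bg <- stage_weights(gc$V, gc$C, a, kind, restricted_trait, single_trait)[[1L]]
    sig1 <- sqrt(as.numeric(t(bg) %*% gc$V %*% bg))
    cg <- as.numeric(t(gc$C) %*% bg)      # cov(I1, g)
    cH <- sum(a * cg)
    rho1 <- cbind(cH / (sig1 * sdH), cg[1L] / (sig1 * sdg[1L]),
                  cg[2L] / (sig1 * sdg[2L]))
    u <- as.numeric(t(bg) %*% gc$C)       # for cov(I1, I2) = u . b_ph
    ph <- .phen_stage_vec(pair, a, kind, grid$L, grid$T,
                          restricted_trait, single_trait)
    r12 <- (u[1L] * ph$b1 + u[2L] * ph$b2) / (sig1 * ph$sig)
    rho2 <- cbind(ph$covH / (ph$sig * sdH), ph$covg1 / (ph$sig * sdg[1L]),
                  ph$covg2 / (ph$sig * sdg[2L]))
    rho1 <- rho1[rep(1L, nrow(grid)), , drop = FALSE]

    coef <- costs$cost_dh + costs$cost_nursery_plot + frac * costs$cost_genotyping
    fixed <- grid$n2 * grid$T * costs$cost_hybrid_seed + grid$n2 * grid$L * grid$T
    n_ini <- floor((B - fixed) / coef)
    cost_of <- function(n_ini) {
      n_ini * (costs$cost_dh + costs$cost_nursery_plot) +
        round(frac * n_ini) * costs$cost_genotyping + fixed
    }
  } else if (pat == "PP") {
    p2 <- .phen_stage_vec(pair, a, kind, grid$L2, grid$T2,
                          restricted_trait, single_trait)
    p3 <- .phen_stage_vec(pair, a, kind, grid$L3, grid$T3,
                          restricted_trait, single_trait)
    cv <- p2$b1 * (G[1L, 1L] * p3$b1 + G[1L, 2L] * p3$b2) +
      p2$b2 * (G[2L, 1L] * p3$b1 + G[2L, 2L] * p3$b2)
    r12 <- cv / (p2$sig * p3$sig)
    rho1 <- cbind(p2$covH / (p2$sig * sdH), p2$covg1 / (p2$sig * sdg[1L]),
                  p2$covg2 / (p2$sig * sdg[2L]))
    rho2 <- cbind(p3$covH / (p3$sig * sdH), p3$covg1 / (p3$sig * sdg[1L]),
                  p3$covg2 / (p3$sig * sdg[2L]))

    extra_T <- if (costs$seed_years_covered >= 2L) {
      pmax(0, grid$T3 - grid$T2)
    } else {
      grid$T3
    }
    coef <- costs$cost_dh + costs$cost_nursery_plot +
      frac * (costs$cost_hybrid_seed * grid$T2 + grid$L2 * grid$T2)
    fixed <- grid$n2 * (costs$cost_hybrid_seed * extra_T + grid$L3 * grid$T3)
    n_ini <- floor((B - fixed) / coef)
    cost_of <- function(n_ini) {
      n_ini * (costs$cost_dh + costs$cost_nursery_plot) +
        round(frac * n_ini) *
          (costs$cost_hybrid_seed * grid$T2 + grid$L2 * grid$T2) + fixed
    }
  } else {
    stop("grid search supports the built-in two-post-stage patterns only")
  }

  n_ini <- pmax(n_ini, 0)
  cost <- cost_of(n_ini)
  for (i in 1:4) {
    over <- cost > B & n_ini > 0
    if (!any(over)) break
    n_ini[over] <- n_ini[over] - 1
    cost <- cost_of(n_ini)
  }
  n1 <- round(frac * n_ini)

  feasible <- n_ini > n1 & n1 > grid$n2 & grid$n2 >= fc & cost <= B
  alpha1 <- ifelse(feasible, grid$n2 / n1, 0.5)
  alpha2 <- ifelse(feasible, fc / grid$n2, 0.5)
  gains <- .two_stage_kernel(alpha1, alpha2, r12, rho1, rho2, sd3)
  gains[!feasible, ] <- NA_real_
  out <- grid
  out$n_ini <- n_ini
  out$n1 <- n1
  out$cost <- cost
  out$feasible <- feasible
  out$dg_net <- gains[, "net"]
  out$dg_g1 <- gains[, "g1"]
  out$dg_g2 <- gains[, "g2"]
  out
}

# default coarse search grids per stage pattern
.default_space <- function(strat, costs) {
  pat <- .stage_pattern(strat)
  fc <- strat$final_count
  B <- costs$budget
  if (pat == "GP") {
    list(n2 = seq(fc + 1L, max(fc + 2L, floor(B / 11)), by = 8L),
         L = 1:20, T = 1:10)
  } else {
    list(n2 = seq(fc + 1L, max(fc + 2L, min(400L, floor(B / 25))), by = 6L),
         L2 = seq(1L, 20L, by = 2L), T2 = 1:8,
         L3 = seq(1L, 20L, by = 2L), T3 = seq(1L, 10L, by = 2L))
  }
}

.clip_seq <- function(center, halfwidth, lo, hi, by = 1L) {
  unique(pmin(hi, pmax(lo, seq(center - halfwidth, center + halfwidth, by = by))))
}

#' Optimum allocation of test resources
#'
#' Exhaustive grid search over candidate allocations maximizing annual gain
#' under the budget. For every grid point of stage sizes, locations and
#' testers, the number of initial DH lines is set to the largest count the
#' remaining budget affords (gain is monotone in the number of initial
#' lines, so this is the per-point optimum). A coarse pass over the whole
#' space is followed by a step-1 refinement pass around the incumbent. The
#' objective is the annual net-merit gain, or the selected trait's annual
#' gain when `index_kind = "single"`. Ties are broken toward smaller
#' `n_ini`, then smaller location counts.
#'
#' @inheritParams build_criterion_structure
#' @param costs a [cost_model()].
#' @param space optional named list overriding the default grid ranges
#'   (`n2`, `L`, `T` for a genomic-phenotypic strategy; `n2`, `L2`, `T2`,
#'   `L3`, `T3` for two-stage phenotypic).
#' @param refine logical: run the step-1 refinement pass.
#' @return object of class `allocation_optimum`: list with `allocation`,
#'   `result` (a `gain_result` recomputed through the general path),
#'   `objective` (annual gain maximized), `cost`, `evaluated` (number of
#'   grid points), `strategy_name`, `index_kind`.
#' @export
optimize_allocation <- function(strat, pair, a,
                                index_kind = c("sh", "base", "restricted", "single"),
                                costs = cost_model(), space = NULL,
                                restricted_trait = 2L, single_trait = 1L,
                                refine = TRUE) {
  index_kind <- match.arg(index_kind)
  pat <- .stage_pattern(strat)
  if (!pat %in% c("GP", "PP")) {
    stop("optimize_allocation supports the built-in two-post-stage strategies")
  }
  sp <- .default_space(strat, costs)
  if (!is.null(space)) sp[names(space)] <- space
  grid <- do.call(expand.grid, sp)
  objective_col <- if (index_kind == "single") {
    paste0("dg_g", single_trait)
  } else {
    "dg_net"
  }

  ev <- .grid_eval(strat, pair, a, index_kind, costs, grid,
                   restricted_trait, single_trait)
  n_eval <- nrow(ev)
  best <- .pick_best(ev, objective_col)
  if (is.null(best)) stop("no feasible allocation: budget too small for the search space")

  if (refine) {
    if (pat == "GP") {
      fine <- expand.grid(
        n2 = .clip_seq(best$n2, 8L, strat$final_count, 10 * best$n2 + 50L),
        L = .clip_seq(best$L, 2L, 1L, max(sp$L) + 2L),
        T = .clip_seq(best$T, 2L, 1L, max(sp$T) + 2L))
    } else {
      fine <- expand.grid(
        n2 = .clip_seq(best$n2, 6L, strat$final_count, 10 * best$n2 + 50L),
        L2 = .clip_seq(best$L2, 2L, 1L, max(sp$L2) + 2L),
        T2 = .clip_seq(best$T2, 1L, 1L, max(sp$T2) + 1L),
        L3 = .clip_seq(best$L3, 2L, 1L, max(sp$L3) + 2L),
        T3 = .clip_seq(best$T3, 2L, 1L, max(sp$T3) + 2L))
    }
    ev2 <- .grid_eval(strat, pair, a, index_kind, costs, fine,
                      restricted_trait, single_trait)
    n_eval <- n_eval + nrow(ev2)
    best2 <- .pick_best(ev2, objective_col)
    if (!is.null(best2) && best2[[objective_col]] > best[[objective_col]]) {
      best <- best2
    }
  }

  if (pat == "GP") {
    alloc <- allocation(best$n_ini, c(best$n1, best$n2),
                        locations = c(NA, best$L), testers = c(NA, best$T))
  } else {
    alloc <- allocation(best$n_ini, c(best$n1, best$n2),
                        locations = c(best$L2, best$L3),
                        testers = c(best$T2, best$T3))
  }
  res <- index_gain(strat, alloc, pair, a, index_kind,
                    restricted_trait = restricted_trait,
                    single_trait = single_trait)
  cost <- allocation_cost(strat, alloc, costs)
  if (cost > costs$budget + 1e-9) stop("internal error: optimum exceeds budget")
  validate_allocation(strat, alloc)
  structure(list(allocation = alloc, result = res,
                 objective = unname(if (index_kind == "single") {
                   res$dg_annual_trait[single_trait]
                 } else {
                   res$dg_annual_net
                 }),
                 cost = as.numeric(cost), evaluated = n_eval,
                 strategy_name = strat$name, index_kind = index_kind),
            class = "allocation_optimum")
}

# first row achieving the feasible maximum, ties toward smaller n_ini then
# smaller location counts
.pick_best <- function(ev, objective_col) {
  obj <- ev[[objective_col]] / 1  # per-cycle and annual argmax coincide
  obj[!ev$feasible] <- NA_real_
  if (all(is.na(obj))) return(NULL)
  m <- max(obj, na.rm = TRUE)
  cand <- which(!is.na(obj) & obj >= m - 1e-12)
  Lcol <- intersect(c("L", "L2"), names(ev))[1L]
  cand <- cand[order(ev$n_ini[cand], ev[[Lcol]][cand])]
  ev[cand[1L], , drop = FALSE]
}

#' @export
print.allocation_optimum <- function(x, ...) {
  al <- x$allocation
  cat(sprintf("Optimum allocation — %s, %s index\n", x$strategy_name, x$index_kind))
  cat(sprintf("  n_ini = %d, stage counts = %s, L = %s, T = %s\n",
              al$n_ini, paste(al$n_stages, collapse = "/"),
              paste(al$locations, collapse = "/"),
              paste(al$testers, collapse = "/")))
  cat(sprintf("  cost = %.0f plot equivalents; %d grid points evaluated\n",
              x$cost, x$evaluated))
  print(x$result)
  invisible(x)
}

#' Optimum allocation across a sweep of prediction accuracies
#'
#' Runs one optimization per accuracy level. In the `unequal_offset` mode
#' the trait-2 accuracy is `r + unequal_offset` (capped at 1). Strategies
#' without a genomic stage are unaffected by the sweep.
#'
#' @inheritParams optimize_allocation
#' @param accuracies trait-1 accuracy levels.
#' @param unequal_offset added to the trait-2 accuracy (0 or 0.2).
#' @return data.frame with one row per accuracy level: accuracies, optimum
#'   allocation summary, cost, and annual gains.
#' @export
sweep_accuracies <- function(strat, pair, a, index_kind = "sh",
                             costs = cost_model(),
                             accuracies = seq(0.1, 0.7, by = 0.1),
                             unequal_offset = 0, ...) {
  rows <- lapply(accuracies, function(r) {
    r2 <- min(1, r + unequal_offset)
    st <- set_accuracy(strat, c(r, r2))
    opt <- optimize_allocation(st, pair, a, index_kind, costs, ...)
    al <- opt$allocation
    data.frame(accuracy_t1 = r, accuracy_t2 = r2,
               n_ini = al$n_ini,
               n_stage1 = al$n_stages[1L], n_stage2 = al$n_stages[2L],
               cost = opt$cost,
               dGa_net = opt$result$dg_annual_net,
               dGa_t1 = opt$result$dg_annual_trait[1L],
               dGa_t2 = opt$result$dg_annual_trait[2L])
  })
  do.call(rbind, rows)
}
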