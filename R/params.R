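# Domain types: testcross variance components, trait pairs, economic weights,
# breeding strategies, allocations and the printed parameter scenarios.

#' Testcross variance components of one trait
#'
#' Variance components of a testcross (hybrid) evaluation on an entry-mean
#' basis: general combining ability (GCA, the selection target), GCA-by-
#' location interaction, specific combining ability (SCA), SCA-by-location
#' interaction, and plot error. All components are in squared trait units.
#'
#' @param var_gca,var_gca_x_loc,var_sca,var_sca_x_loc,var_error non-negative
#'   variances.
#' @return an object of class `trait_params`.
#' @export
trait_params <- function(var_gca, var_gca_x_loc = 0, var_sca = 0,
                         var_sca_x_loc = 0, var_error = 0) {
  v <- c(var_gca = var_gca, var_gca_x_loc = var_gca_x_loc, var_sca = var_sca,
         var_sca_x_loc = var_sca_x_loc, var_error = var_error)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("all variance components must be finite and non-negative")
  }
  if (sum(v) <= 0) stop("phenotypic variance must be strictly positive")
  structure(as.list(v), class = "trait_params")
}

#' Two traits with their genetic correlation
#'
#' Couples the variance components of two traits with the correlation of
#' their GCA effects and optional covariances of the masking components
#' (zero by default, the usual working assumption because SCA and
#' interaction covariances are rarely estimated in practice).
#'
#' @param trait1,trait2 [trait_params()] objects.
#' @param rho_genetic GCA correlation between the traits, in \[-1, 1\].
#' @param cov_sca,cov_gca_x_loc,cov_sca_x_loc,cov_error between-trait
#'   covariances of the corresponding components.
#' @return an object of class `trait_pair`.
#' @export
trait_pair <- function(trait1, trait2, rho_genetic,
                       cov_sca = 0, cov_gca_x_loc = 0, cov_sca_x_loc = 0,
                       cov_error = 0) {
  stopifnot(inherits(trait1, "trait_params"), inherits(trait2, "trait_params"))
  if (abs(rho_genetic) > 1) stop("|rho_genetic| must be <= 1")
  pair <- structure(list(trait1 = trait1, trait2 = trait2,
                         rho_genetic = rho_genetic,
                         cov_sca = cov_sca, cov_gca_x_loc = cov_gca_x_loc,
                         cov_sca_x_loc = cov_sca_x_loc, cov_error = cov_error),
                    class = "trait_pair")
  comps <- list(
    c("var_sca", "cov_sca"),
    c("var_gca_x_loc", "cov_gca_x_loc"),
    c("var_sca_x_loc", "cov_sca_x_loc"),
    c("var_error", "cov_error"))
  for (cp in comps) {
    v1 <- trait1[[cp[1L]]]
    v2 <- trait2[[cp[1L]]]
    cv <- pair[[cp[2L]]]
    if (cv^2 > v1 * v2 + 1e-12) {
      stop(sprintf("component covariance %s = %g implies a correlation > 1",
                   cp[2L], cv))
    }
  }
  pair
}

#' Economic weights of the net merit
#'
#' The net merit is \eqn{H = \sum_l a_l y_l} with `a` the relative economic
#' values of the trait GCA values `y`.
#'
#' @param a numeric vector of two weights, not both zero.
#' @return an object of class `economic_weights` (a plain numeric vector).
#' @export
economic_weights <- function(a) {
  a <- as.numeric(a)
  if (length(a) != 2L || any(!is.finite(a))) stop("a must be 2 finite weights")
  if (all(a == 0)) stop("economic weights must not both be zero")
  structure(a, class = "economic_weights")
}

# --- stages and strategies --------------------------------------------------

#' Stages of a breeding strategy
#'
#' A strategy is an ordered list of stages: one observation `nursery` (a
#' fixed-fraction cut on traits uncorrelated with the net merit), optionally
#' a `genomic` stage selecting on GEBVs with per-trait prediction accuracies,
#' and `phenotypic` stages selecting on testcross means over `locations`
#' locations and `testers` testers with one replication per location.
#' Locations and testers given here are defaults; the allocation being
#' optimized overrides them.
#'
#' @param selected_fraction fraction retained after the nursery.
#' @param accuracy length-2 vector of GEBV prediction accuracies in \[0, 1\].
#' @param locations,testers default test dimensions (may be `NA`).
#' @return an object of class `breeding_stage`.
#' @name stages
NULL

#' @rdname stages
#' @export
stage_nursery <- function(selected_fraction = 0.25) {
  if (selected_fraction <= 0 || selected_fraction > 1) {
    stop("nursery selected fraction must be in (0, 1]")
  }
  structure(list(kind = "nursery", selected_fraction = selected_fraction),
            class = "breeding_stage")
}

#' @rdname stages
#' @export
stage_genomic <- function(accuracy = c(0.3, 0.3)) {
  accuracy <- as.numeric(accuracy)
  if (length(accuracy) != 2L || any(accuracy < 0 | accuracy > 1)) {
    stop("accuracy must be 2 values in [0, 1]")
  }
  structure(list(kind = "genomic", accuracy = accuracy),
            class = "breeding_stage")
}

#' @rdname stages
#' @export
stage_phenotypic <- function(locations = NA_integer_, testers = NA_integer_) {
  if (!is.na(locations) && locations < 1) stop("locations must be >= 1")
  if (!is.na(testers) && testers < 1) stop("testers must be >= 1")
  structure(list(kind = "phenotypic", locations = locations, testers = testers),
            class = "breeding_stage")
}

#' Define a breeding strategy
#'
#' @param name label.
#' @param stages ordered list of [stages]; exactly one nursery, first.
#' @param cycle_years years needed to complete one breeding cycle (used to
#'   annualize gains).
#' @param final_count number of lines selected at the end (default 5).
#' @return an object of class `breeding_strategy`.
#' @export
strategy <- function(name, stages, cycle_years, final_count = 5L) {
  kinds <- vapply(stages, function(s) s$kind, character(1))
  if (sum(kinds == "nursery") != 1L || kinds[1L] != "nursery") {
    stop("a strategy needs exactly one nursery stage, first in order")
  }
  if (length(kinds) < 2L) stop("at least one post-nursery selection stage is required")
  if (cycle_years <= 0) stop("cycle_years must be positive")
  if (final_count < 1) stop("final_count must be >= 1")
  structure(list(name = name, stages = stages, cycle_years = cycle_years,
                 final_count = as.integer(final_count)),
            class = "breeding_strategy")
}

#' Built-in breeding strategies
#'
#' `ps_standard()` is the classical benchmark: nursery followed by two stages
#' of phenotypic testcross selection. `gs_rapid()` replaces the first field
#' stage by genomic selection on GEBVs, which shortens the cycle by two
#' years. `strategy_catalog()` returns both. Default cycle lengths are 7
#' years (PSstandard) and 5 years (GSrapid); see the package vignette for the
#' reasoning.
#'
#' @param accuracy per-trait GEBV prediction accuracies for the genomic
#'   stage.
#' @param cycle_years named vector with elements `PSstandard`, `GSrapid`.
#' @param nursery_fraction fraction kept after the observation nursery.
#' @param final_count lines selected at the end of the cycle.
#' @return `strategy_catalog()`: named list of two `breeding_strategy`
#'   objects.
#' @examples
#' names(strategy_catalog())
#' @export
strategy_catalog <- function(accuracy = c(0.3, 0.3),
                             cycle_years = c(PSstandard = 7, GSrapid = 5),
                             nursery_fraction = 0.25, final_count = 5L) {
  list(PSstandard = ps_standard(cycle_years = cycle_years[["PSstandard"]],
                                nursery_fraction = nursery_fraction,
                                final_count = final_count),
       GSrapid = gs_rapid(accuracy = accuracy,
                          cycle_years = cycle_years[["GSrapid"]],
                          nursery_fraction = nursery_fraction,
                          final_count = final_count))
}

#' @rdname strategy_catalog
#' @export
ps_standard <- function(cycle_years = 7, nursery_fraction = 0.25,
                        final_count = 5L) {
  strategy("PSstandard",
           list(stage_nursery(nursery_fraction), stage_phenotypic(),
                stage_phenotypic()),
           cycle_years = cycle_years, final_count = final_count)
}

#' @rdname strategy_catalog
#' @export
gs_rapid <- function(accuracy = c(0.3, 0.3), cycle_years = 5,
                     nursery_fraction = 0.25, final_count = 5L) {
  strategy("GSrapid",
           list(stage_nursery(nursery_fraction), stage_genomic(accuracy),
                stage_phenotypic()),
           cycle_years = cycle_years, final_count = final_count)
}

#' Replace the genomic-stage prediction accuracies of a strategy
#'
#' Strategies without a genomic stage are returned unchanged.
#'
#' @param strat a `breeding_strategy`.
#' @param accuracy length-2 accuracy vector.
#' @export
set_accuracy <- function(strat, accuracy) {
  for (i in seq_along(strat$stages)) {
    if (strat$stages[[i]]$kind == "genomic") {
      strat$stages[[i]] <- stage_genomic(accuracy)
    }
  }
  strat
}

# --- allocation -------------------------------------------------------------

#' Candidate/location/tester allocation
#'
#' The decision vector of the optimizer: `n_ini` initial DH lines enter the
#' nursery; `n_stages[j]` candidates enter post-nursery stage `j`;
#' `locations`/`testers` give the field dimensions of each post-nursery stage
#' (`NA` at genomic stages). The first post-nursery count must equal
#' `round(fraction * n_ini)` with the nursery's fixed selected fraction.
#'
#' @param n_ini initial number of DH lines.
#' @param n_stages integer counts entering each post-nursery stage.
#' @param locations,testers per post-nursery stage (`NA` where not
#'   applicable).
#' @return object of class `allocation`.
#' @export
allocation <- function(n_ini, n_stages, locations = NA, testers = NA) {
  S <- length(n_stages)
  locations <- rep_len(locations, S)
  testers <- rep_len(testers, S)
  structure(list(n_ini = n_ini, n_stages = as.numeric(n_stages),
                 locations = locations, testers = testers),
            class = "allocation")
}

#' Validate an allocation against a strategy
#'
#' Checks, independently of any gain computation: strictly decreasing counts
#' along the selection path, the nursery ratio, presence of locations and
#' testers (>= 1) at phenotypic stages, and that the last stage retains at
#' least `final_count` candidates.
#'
#' @param strat a `breeding_strategy`.
#' @param alloc an [allocation()].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_allocation <- function(strat, alloc) {
  post <- strat$stages[-1L]
  S <- length(post)
  if (length(alloc$n_stages) != S) {
    stop("allocation must give one candidate count per post-nursery stage")
  }
  frac <- strat$stages[[1L]]$selected_fraction
  n1_expect <- round(frac * alloc$n_ini)
  if (abs(alloc$n_stages[1L] - n1_expect) > 0.5) {
    stop(sprintf("first post-nursery count must be round(%g * n_ini) = %d",
                 frac, n1_expect))
  }
  path <- c(alloc$n_ini, alloc$n_stages)
  if (any(diff(path) >= 0)) stop("candidate counts must be strictly decreasing")
  if (alloc$n_stages[S] < strat$final_count) {
    stop("last stage must retain at least final_count candidates")
  }
  for (j in seq_len(S)) {
    if (post[[j]]$kind == "phenotypic") {
      if (is.na(alloc$locations[j]) || alloc$locations[j] < 1 ||
          is.na(alloc$testers[j]) || alloc$testers[j] < 1) {
        stop(sprintf("phenotypic stage %d needs locations and testers >= 1", j))
      }
    }
  }
  invisible(TRUE)
}

#' Per-stage selected fractions implied by an allocation
#'
#' Stage `j` keeps `n[j+1] / n[j]`; the last stage keeps
#' `final_count / n[S]`.
#'
#' @inheritParams validate_allocation
#' @return numeric vector of fractions in (0, 1].
#' @export
stage_fractions <- function(strat, alloc) {
  n <- alloc$n_stages
  S <- length(n)
  keep <- c(if (S > 1L) n[-1L], strat$final_count)
  f <- keep / n
  if (any(f <= 0 | f > 1)) stop("implied selected fractions outside (0, 1]")
  f
}

# --- printed parameter scenarios -------------------------------------------

#' Standardized two-trait scenarios I-VII
#'
#' The seven hypothetical scenarios of the theoretical comparison. Trait 1
#' always has standardized testcross components (GCA 1, GCAxL 0.91, SCA 0.33,
#' SCAxL 0.52, error 4.28); each scenario modifies exactly one factor of the
#' standard scenario I (genetic correlation -0.5, equal unit weights, equal
#' components):
#' \describe{
#'   \item{I}{standard: rho = -0.5, weights (1, 1).}
#'   \item{II}{rho = 0.}
#'   \item{III}{rho = +0.5.}
#'   \item{IV}{weights (2, 0).}
#'   \item{V}{weights (0.7, 1.3).}
#'   \item{VI}{trait-2 GCA variance tripled.}
#'   \item{VII}{trait-2 masking components tripled.}
#' }
#'
#' @param id scenario label, one of `"I"` ... `"VII"`.
#' @return list of class `gain_scenario` with elements `id`, `pair`
#'   ([trait_pair()]) and `weights` ([economic_weights()]).
#' @export
scenario_table1 <- function(id) {
  ids <- c("I", "II", "III", "IV", "V", "VI", "VII")
  if (!is.character(id) || length(id) != 1L || !(id %in% ids)) {
    stop("unknown scenario id; valid ids: ", paste(ids, collapse = ", "))
  }
  base <- function(gca = 1) trait_params(gca, 0.91, 0.33, 0.52, 4.28)
  t1 <- base()
  t2 <- base()
  rho <- -0.5
  w <- c(1, 1)
  switch(id,
    I = NULL,
    II = { rho <- 0 },
    III = { rho <- 0.5 },
    IV = { w <- c(2, 0) },
    V = { w <- c(0.7, 1.3) },
    VI = { t2 <- base(gca = 3) },
    VII = { t2 <- trait_params(1, 0.91 * 3, 0.33 * 3, 0.52 * 3, 4.28 * 3) })
  structure(list(id = id, pair = trait_pair(t1, t2, rho),
                 weights = economic_weights(w)),
            class = "gain_scenario")
}

#' Hybrid wheat scenarios: yield with a quality trait
#'
#' Empirical testcross variance components for hybrid wheat. Trait 1 is
#' grain yield (dt/ha) in both goals; trait 2 is grain protein content (%)
#' for goal 1 (genetic correlation -0.40) or sedimentation volume (ml) for
#' goal 2 (genetic correlation -0.18). Economic weights are (1, 0.12),
#' expressing the quality premium relative to the base grain price.
#'
#' @param goal 1 (yield + protein) or 2 (yield + sedimentation volume).
#' @return a `gain_scenario` (see [scenario_table1()]).
#' @export
scenario_wheat <- function(goal) {
  if (!(length(goal) == 1L && goal %in% c(1, 2))) stop("goal must be 1 or 2")
  yield <- trait_params(5.7, 5.19, 1.88, 2.94, 24.37)
  if (goal == 1) {
    t2 <- trait_params(0.08, 0.02, 0.01, 0.00, 0.09)
    rho <- -0.40
  } else {
    t2 <- trait_params(23.54, 1.58, 0.64, 0.25, 6.9)
    rho <- -0.18
  }
  structure(list(id = paste0("wheat_goal", goal),
                 pair = trait_pair(yield, t2, rho),
                 weights = economic_weights(c(1, 0.12))),
            class = "gain_scenario")
}

#' Budget and unit costs, in field-plot equivalents
#'
#' One yield-trial plot is the budget unit. `cost_dh` covers producing one
#' DH line including its observation-nursery evaluation; `cost_genotyping`
#' is charged per line entering a genomic stage; `cost_hybrid_seed` per
#' candidate-by-tester hybrid seed production, which delivers enough seed for
#' `seed_years_covered` years of phenotyping (so a second phenotypic stage
#' only pays seed for testers added beyond the first stage). A separate
#' per-line nursery charge can be switched on with `cost_nursery_plot`.
#'
#' @param budget total plot equivalents available per cycle.
#' @param cost_dh,cost_genotyping,cost_hybrid_seed,cost_nursery_plot unit
#'   costs.
#' @param seed_years_covered phenotyping years covered by one seed
#'   production.
#' @return object of class `cost_model`.
#' @export
cost_model <- function(budget = 10000, cost_dh = 1, cost_genotyping = 2,
                       cost_hybrid_seed = 4, cost_nursery_plot = 0,
                       seed_years_covered = 2L) {
  v <- c(cost_dh, cost_genotyping, cost_hybrid_seed, cost_nursery_plot)
  if (any(v < 0)) stop("unit costs must be non-negative")
  if (budget <= 0) stop("budget must be positive")
  structure(list(budget = budget, cost_dh = cost_dh,
                 cost_genotyping = cost_genotyping,
                 cost_hybrid_seed = cost_hybrid_seed,
                 cost_nursery_plot = cost_nursery_plot,
                 seed_years_covered = as.integer(seed_years_covered)),
            class = "cost_model")
}
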