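# Comparison reports: tables of maximum annual gain across scenarios,
# strategies and index kinds, and the percentage contrasts between rows.

round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage contrast between two gains
#'
#' `100 * (numerator / denominator - 1)`, rounded half-up to one decimal —
#' the convention used when comparing strategies or indices ("x% higher").
#'
#' @param numerator,denominator positive gains (denominator > 0).
#' @return percentage, one decimal.
#' @examples
#' contrast(1.45, 1)  # 45
#' @export
contrast <- function(numerator, denominator) {
  if (!is.finite(denominator) || denominator <= 0) {
    stop("contrast denominator must be positive")
  }
  round_half_up(100 * (numerator / denominator - 1), 1L)
}

#' Contrast two rows of a comparison report
#'
#' @param report a [build_report()] result.
#' @param num,den named lists of column filters identifying exactly one row
#'   each, e.g. `list(strategy = "GSrapid", index = "sh")`.
#' @param value column to contrast (default `"dGa_net"`).
#' @export
report_contrast <- function(report, num, den, value = "dGa_net") {
  pick <- function(flt) {
    sel <- rep(TRUE, nrow(report))
    for (nm in names(flt)) sel <- sel & report[[nm]] == flt[[nm]]
    i <- which(sel)
    if (length(i) != 1L) {
      stop("filter must identify exactly one report row (matched ",
           length(i), ")")
    }
    report[[value]][i]
  }
  contrast(pick(num), pick(den))
}

#' Build a comparison report across scenarios, strategies and indices
#'
#' Optimizes every combination of scenario, strategy, index kind and
#' accuracy level and collects the maximum annual gains in a deterministic
#' row order. Index kinds: `"sh"`, `"base"`, `"restricted"` are optimized
#' directly; `"icl"` is evaluated at the Smith-Hazel optimum of the same
#' scenario/strategy/accuracy with a culling-fraction search; `"single"`
#' reports, per trait, the maximum annual gain of a dedicated single-trait
#' optimization (the "No Index" benchmark: the two trait columns come from
#' two separate optimizations and no net merit is reported).
#'
#' @param scenarios list of `gain_scenario` objects (see
#'   [scenario_table1()], [scenario_wheat()]).
#' @param strategies named list of strategies, e.g. [strategy_catalog()].
#' @param indices character vector of index kinds.
#' @param accuracies accuracy levels applied to genomic stages.
#' @param costs a [cost_model()].
#' @param unequal_offset added to the trait-2 accuracy.
#' @param n_icl_combos culling-fraction combinations for ICL.
#' @return data.frame of class `comparison_report`.
#' @export
build_report <- function(scenarios, strategies, indices = c("sh", "base", "restricted"),
                         accuracies = 0.3, costs = cost_model(),
                         unequal_offset = 0, n_icl_combos = 1000L) {
  if (length(indices) == 0L) stop("at least one index kind is required")
  bad <- setdiff(indices, c("sh", "base", "restricted", "icl", "single"))
  if (length(bad)) stop("unknown index kinds: ", paste(bad, collapse = ", "))
  if (inherits(scenarios, "gain_scenario")) scenarios <- list(scenarios)
  rows <- list()
  for (sc in scenarios) {
    for (sn in names(strategies)) {
      for (r in accuracies) {
        st <- set_accuracy(strategies[[sn]], c(r, min(1, r + unequal_offset)))
        sh_opt <- NULL
        for (ix in indices) {
          if (ix == "icl") {
            if (is.null(sh_opt)) {
              sh_opt <- optimize_allocation(st, sc$pair, sc$weights, "sh",
                                            costs = costs)
            }
            icl <- icl_search_fractions(st, sh_opt$allocation, sc$pair,
                                        sc$weights, n_combos = n_icl_combos)
            res <- icl$result
            row <- .report_row(sc$id, sn, ix, r, st, sh_opt$allocation,
                               res$dg_annual_net, res$dg_annual_trait)
          } else if (ix == "single") {
            o1 <- optimize_allocation(st, sc$pair, sc$weights, "single",
                                      costs = costs, single_trait = 1L)
            o2 <- optimize_allocation(st, sc$pair, sc$weights, "single",
                                      costs = costs, single_trait = 2L)
            row <- .report_row(sc$id, sn, ix, r, st, o1$allocation,
                               NA_real_,
                               c(o1$result$dg_annual_trait[1L],
                                 o2$result$dg_annual_trait[2L]))
          } else {
            opt <- optimize_allocation(st, sc$pair, sc$weights, ix,
                                       costs = costs)
            if (ix == "sh") sh_opt <- opt
            row <- .report_row(sc$id, sn, ix, r, st, opt$allocation,
                               opt$result$dg_annual_net,
                               opt$result$dg_annual_trait)
          }
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_report", class(out))
  out
}

.report_row <- function(scenario, strategy_name, index, accuracy, st, al,
                        net, trait) {
  data.frame(scenario = scenario, strategy = strategy_name, index = index,
             accuracy = accuracy,
             n_ini = al$n_ini, n_stage1 = al$n_stages[1L],
             n_stage2 = al$n_stages[2L],
             L1 = al$locations[1L], L2 = al$locations[2L],
             T1 = al$testers[1L], T2 = al$testers[2L],
             dGa_net = net, dGa_t1 = trait[1L], dGa_t2 = trait[2L],
             stringsAsFactors = FALSE)
}

#' Write a comparison report to CSV and/or JSON lines
#'
#' @param report a [build_report()] result.
#' @param csv,json output paths (either may be `NULL`).
#' @export
write_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(report, csv, row.names = FALSE)
  if (!is.null(json)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("the jsonlite package is required for JSON output")
    }
    con <- file(json, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(report))) {
      writeLines(jsonlite::toJSON(as.list(report[i, ]), auto_unbox = TRUE,
                                  digits = NA, na = "null"), con)
    }
  }
  invisible(report)
}
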