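# Reading scenario definitions from YAML files. Bundled fixtures for the
# standardized scenarios I-VII and the two hybrid-wheat goals live under
# inst/extdata/scenarios.

#' Read a scenario from a YAML file
#'
#' The file mirrors the constructor fields: two `trait` blocks with the five
#' variance components, `rho_genetic`, optional component covariances, and
#' `weights`. See the bundled fixtures, e.g.
#' `system.file("extdata", "scenarios", "scenario_I.yaml", package = "indexgain")`.
#'
#' @param path YAML file path.
#' @return a `gain_scenario`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("trait1", "trait2", "rho_genetic", "weights")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("scenario file missing fields: ", paste(miss, collapse = ", "))
  tp <- function(tr) trait_params(tr$var_gca, tr$var_gca_x_loc %||% 0,
                                  tr$var_sca %||% 0, tr$var_sca_x_loc %||% 0,
                                  tr$var_error %||% 0)
  pair <- trait_pair(tp(y$trait1), tp(y$trait2), y$rho_genetic,
                     cov_sca = y$cov_sca %||% 0,
                     cov_gca_x_loc = y$cov_gca_x_loc %||% 0,
                     cov_sca_x_loc = y$cov_sca_x_loc %||% 0,
                     cov_error = y$cov_error %||% 0)
  structure(list(id = y$id %||% basename(path), pair = pair,
                 weights = economic_weights(unlist(y$weights))),
            class = "gain_scenario")
}

#' Directory of bundled scenario fixture files
#'
#' @return path to the installed YAML fixtures.
#' @export
scenario_fixture_dir <- function() {
  system.file("extdata", "scenarios", package = "indexgain")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
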