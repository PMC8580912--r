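# Covariance engine: genetic, phenotypic and GEBV covariance matrices,
# index-weight construction (Smith-Hazel, base, restricted) and assembly of
# the correlation structure among stage selection criteria and the targets
# (net merit H and each trait's GCA).

#' Genetic (GCA) covariance matrix of a trait pair
#'
#' @param pair a [trait_pair()].
#' @return 2x2 matrix `G` with `G[k,k]` the GCA variances and off-diagonal
#'   `rho_genetic * sqrt(G[1,1] * G[2,2])`.
#' @export
genetic_cov_matrix <- function(pair) {
  v1 <- pair$trait1$var_gca
  v2 <- pair$trait2$var_gca
  g12 <- pair$rho_genetic * sqrt(v1 * v2)
  G <- matrix(c(v1, g12, g12, v2), 2L, 2L)
  if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("genetic covariance matrix is not positive semi-definite")
  }
  G
}

#' Phenotypic covariance matrix of testcross means
#'
#' Entry-mean (co)variances for a trial with `L` locations, `T` testers and
#' one replication per location: interaction and error components are diluted
#' by `L`, `T` and `L*T`,
#' \deqn{P_{kk} = \sigma^2_{GCA} + \sigma^2_{GCA \times L}/L +
#'   \sigma^2_{SCA}/T + \sigma^2_{SCA \times L}/(LT) + \sigma^2_e/(LT).}
#' The off-diagonal uses the corresponding component covariances; with the
#' default zero masking covariances it equals the genetic covariance.
#'
#' @param pair a [trait_pair()].
#' @param L number of locations (>= 1).
#' @param T number of testers (>= 1).
#' @return 2x2 matrix `P`.
#' @export
phenotypic_cov_matrix <- function(pair, L, T) {
  if (L < 1 || T < 1) stop("L and T must be >= 1")
  pv <- function(tr) tr$var_gca + tr$var_gca_x_loc / L + tr$var_sca / T +
    tr$var_sca_x_loc / (L * T) + tr$var_error / (L * T)
  G <- genetic_cov_matrix(pair)
  p12 <- G[1L, 2L] + pair$cov_gca_x_loc / L + pair$cov_sca / T +
    pair$cov_sca_x_loc / (L * T) + pair$cov_error / (L * T)
  matrix(c(pv(pair$trait1), p12, p12, pv(pair$trait2)), 2L, 2L)
}

#' GEBV covariance structure of a genomic selection stage
#'
#' Deterministic model for genomic estimated breeding values: the GEBV of
#' trait k is scaled to `var(u_k) = r_k^2 var(g_k)` with
#' `cov(u_k, g_j) = r_k^2 G[k,j]` (hence `corr(u_k, g_k) = r_k` and
#' `corr(u_k, g_j) = r_k rho_G`), and the GEBVs of the two traits preserve
#' the genetic correlation, `cov(u_1, u_2) = r_1 r_2 G[1,2]` so
#' `corr(u_1, u_2) = rho_G`. Under this convention a net-merit index of
#' GEBVs with equal accuracies has accuracy exactly `r` for net merit,
#' whatever the trait correlation; see the methods vignette for the
#' alternatives considered.
#'
#' @param pair a [trait_pair()].
#' @param r length-2 vector of prediction accuracies in \[0, 1\].
#' @return list with `V` (2x2 GEBV covariance matrix) and `C` (2x2
#'   cross-covariance, `C[k, j] = cov(u_k, g_j)`).
#' @export
genomic_cov_structure <- function(pair, r) {
  r <- as.numeric(r)
  if (length(r) != 2L || any(r < 0 | r > 1)) {
    stop("accuracies must be 2 values in [0, 1]")
  }
  G <- genetic_cov_matrix(pair)
  V <- diag(r) %*% G %*% diag(r)
  C <- diag(r^2) %*% G
  list(V = V, C = C)
}

# --- index weights ----------------------------------------------------------

#' Smith-Hazel index weights
#'
#' `b = P^{-1} C a`, where `P` is the covariance matrix of the selection
#' criteria (phenotypic testcross means, or GEBVs at a genomic stage) and
#' `C[k, j] = cov(x_k, g_j)` their cross-covariance with the trait GCA
#' values (`C = G` for phenotypic criteria). With error-free parameters this
#' index maximizes the correlation of the index with net merit.
#'
#' @param P criterion covariance matrix (invertible).
#' @param G cross-covariance of criteria with trait GCA values.
#' @param a [economic_weights()] (or plain numeric vector of length 2).
#' @return numeric weight vector `b`.
#' @export
smith_hazel_weights <- function(P, G, a) {
  if (abs(det(P)) < 1e-300) stop("criterion covariance matrix is singular")
  as.numeric(solve(P, G %*% as.numeric(a)))
}

#' Base index weights
#'
#' The base index applies the economic weights directly to the observed
#' criteria, `b = a`, ignoring all covariances.
#'
#' @inheritParams smith_hazel_weights
#' @export
base_weights <- function(a) {
  as.numeric(a)
}

#' Restricted (Kempthorne-Nordskog) index weights
#'
#' Maximizes `cov(I, H) / sigma_I` subject to a zero expected change of the
#' restricted trait, `cov(I, g_restricted) = 0`. Solved by Lagrange
#' multipliers: with `g_r = C[, restricted_trait]`,
#' `b = P^{-1} (C a - mu g_r)` where
#' `mu = (g_r' P^{-1} C a) / (g_r' P^{-1} g_r)`.
#'
#' @inheritParams smith_hazel_weights
#' @param restricted_trait index (1 or 2) of the trait held constant.
#' @export
restricted_weights <- function(P, G, a, restricted_trait = 2L) {
  if (!restricted_trait %in% c(1L, 2L)) stop("restricted_trait must be 1 or 2")
  if (abs(det(P)) < 1e-300) stop("criterion covariance matrix is singular")
  a <- as.numeric(a)
  gr <- G[, restricted_trait]
  Pinv_gr <- solve(P, gr)
  denom <- sum(gr * Pinv_gr)
  if (denom <= 1e-12 * max(diag(P))) {
    stop("degenerate restriction: restricted trait has (near) zero genetic variance in the criteria")
  }
  v <- G %*% a
  mu <- sum(gr * solve(P, v)) / denom
  b <- as.numeric(solve(P, v - mu * gr))
  if (abs(sum(b * gr)) > 1e-8 * max(1, abs(sum(b * (G %*% a))))) {
    stop("restricted-index constraint not satisfied to tolerance")
  }
  b
}

# internal: stage-level covariance objects (V = Var(criteria),
# C[k, j] = cov(criterion_k, g_j)) for one post-nursery stage
stage_cov <- function(stage, pair, L = NA, T = NA) {
  if (stage$kind == "phenotypic") {
    list(V = phenotypic_cov_matrix(pair, L, T), C = genetic_cov_matrix(pair))
  } else if (stage$kind == "genomic") {
    genomic_cov_structure(pair, stage$accuracy)
  } else {
    stop("nursery stages carry no selection criterion")
  }
}

# internal: weight vectors for a stage, one per criterion
stage_weights <- function(V, C, a, index_kind, restricted_trait, single_trait) {
  switch(index_kind,
    sh = list(smith_hazel_weights(V, C, a)),
    base = list(base_weights(a)),
    restricted = list(restricted_weights(V, C, a, restricted_trait)),
    single = list(as.numeric(diag(2L)[, single_trait])),
    icl = list(c(1, 0), c(0, 1)),
    stop("unknown index_kind: ", index_kind))
}

#' Correlation structure among stage criteria and targets
#'
#' Assembles everything the truncation machinery needs for a strategy at a
#' given allocation: the correlation matrix `R` among all post-nursery
#' selection criteria (one index per stage; two per-trait criteria per stage
#' for independent culling levels), their correlations with the targets (net
#' merit `H = a'g` and each trait's GCA), and the target standard
#' deviations. Criteria of different stages share only their GCA-level
#' (co)variances because each stage uses independent locations and testers.
#'
#' @inheritParams validate_allocation
#' @param pair a [trait_pair()].
#' @param a [economic_weights()].
#' @param index_kind one of `"sh"`, `"base"`, `"restricted"`, `"single"`,
#'   `"icl"`.
#' @param restricted_trait trait held constant by the restricted index.
#' @param single_trait trait selected on when `index_kind = "single"`.
#' @return object of class `criterion_structure`: list with `R`,
#'   `rho_targets` (d x 3 matrix, columns `H`, `g1`, `g2`), `sd_targets`
#'   (named length-3), `weights` (list of per-criterion weight vectors),
#'   `sigma_I`, `stage_of` (stage index of each criterion), `d`.
#' @export
build_criterion_structure <- function(strat, alloc, pair, a,
                                      index_kind = c("sh", "base", "restricted",
                                                     "single", "icl"),
                                      restricted_trait = 2L, single_trait = 1L) {
  index_kind <- match.arg(index_kind)
  validate_allocation(strat, alloc)
  a <- as.numeric(a)
  G <- genetic_cov_matrix(pair)
  post <- strat$stages[-1L]
  S <- length(post)

  covs <- vector("list", S)
  for (s in seq_len(S)) {
    covs[[s]] <- stage_cov(post[[s]], pair, alloc$locations[s], alloc$testers[s])
  }

  crit_b <- list()
  crit_stage <- integer(0)
  for (s in seq_len(S)) {
    bs <- stage_weights(covs[[s]]$V, covs[[s]]$C, a, index_kind,
                        restricted_trait, single_trait)
    crit_b <- c(crit_b, bs)
    crit_stage <- c(crit_stage, rep(s, length(bs)))
  }
  d <- length(crit_b)

  # cross-stage covariance of the underlying criterion vectors: only genetic
  # terms survive. Gamma[k, j] = cov(x_{s,k}, x_{t,j}) for stages s < t.
  cross_gamma <- function(s, t) {
    ks <- post[[s]]$kind
    kt <- post[[t]]$kind
    if (ks == "genomic" && kt == "genomic") return(covs[[s]]$V)
    if (ks == "genomic") return(covs[[s]]$C)          # cov(u_k, g_j)
    if (kt == "genomic") return(t(covs[[t]]$C))       # cov(g_k, u_j)
    G
  }

  sigma_I <- numeric(d)
  cov_g <- matrix(0, d, 2L)
  for (i in seq_len(d)) {
    s <- crit_stage[i]
    b <- crit_b[[i]]
    sigma_I[i] <- sqrt(as.numeric(t(b) %*% covs[[s]]$V %*% b))
    if (sigma_I[i] <= 0) stop("criterion variance must be strictly positive")
    cov_g[i, ] <- as.numeric(t(covs[[s]]$C) %*% b)
  }

  R <- diag(d)
  if (d > 1L) {
    for (i in seq_len(d - 1L)) {
      for (j in seq((i + 1L), d)) {
        s <- crit_stage[i]
        t_ <- crit_stage[j]
        Gam <- if (s == t_) covs[[s]]$V else cross_gamma(s, t_)
        cv <- as.numeric(t(crit_b[[i]]) %*% Gam %*% crit_b[[j]])
        R[i, j] <- R[j, i] <- cv / (sigma_I[i] * sigma_I[j])
      }
    }
  }
  if (any(abs(R) > 1 + 1e-8)) stop("criterion correlation outside [-1, 1]")
  R[] <- pmin(1, pmax(-1, R))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf("assembled criterion correlation matrix is not PSD (eigenvalue %.3e)",
                 min(ev)))
  }

  sd_g <- sqrt(diag(G))
  sd_H <- sqrt(as.numeric(t(a) %*% G %*% a))
  if (sd_H <= 0) stop("net merit has zero variance under these weights")
  cov_H <- as.numeric(cov_g %*% a)
  rho <- cbind(H = cov_H / (sigma_I * sd_H),
               g1 = cov_g[, 1L] / (sigma_I * sd_g[1L]),
               g2 = cov_g[, 2L] / (sigma_I * sd_g[2L]))
  if (any(abs(rho) > 1 + 1e-8)) stop("criterion-target correlation outside [-1, 1]")
  rho[] <- pmin(1, pmax(-1, rho))

  structure(list(R = R, rho_targets = rho,
                 sd_targets = c(H = sd_H, g1 = sd_g[1L], g2 = sd_g[2L]),
                 weights = crit_b, sigma_I = sigma_I,
                 stage_of = crit_stage, d = d, index_kind = index_kind),
            class = "criterion_structure")
}
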