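# Multistage truncation machinery: truncation points from selected fractions
# and Tallis first moments of a correlated target under multi-criterion
# truncation. Everything is on the standard-normal scale; gains are obtained
# by multiplying the truncated mean by the target's standard deviation.

#' Solve truncation points for given per-stage selected fractions
#'
#' Selection acts on `d` jointly normal criteria with correlation matrix `R`;
#' stage `j` retains the fraction `fractions[j]` of the candidates that
#' survived stages `1 .. j-1`. Truncation points are solved sequentially so
#' that the joint survivor probability after stage `j` equals
#' `prod(fractions[1:j])`, mirroring how breeding stages operate (the
#' stage-wise fractions are the decision variables of the allocation
#' optimizer). A fraction of 1 yields the analytic sentinel `q = -Inf`.
#'
#' @param fractions numeric vector of per-stage selected fractions in (0, 1].
#' @param R correlation matrix among the stage criteria.
#' @param tol absolute tolerance of the root solve.
#' @return an object of class `truncation_scheme`: list with elements `q`
#'   (truncation points), `alpha` (per-stage fractions), `alpha_total`
#'   (their product), and `R`.
#' @examples
#' solve_truncation_points(c(0.5, 0.5), diag(2))$q  # c(0, 0)
#' @export
solve_truncation_points <- function(fractions, R, tol = 1e-12) {
  R <- as.matrix(R)
  d <- length(fractions)
  if (d != nrow(R)) stop("length(fractions) must match nrow(R)")
  if (any(fractions <= 0 | fractions > 1)) {
    stop("selected fractions must lie in (0, 1]")
  }
  check_corr_matrix(R)
  q <- numeric(d)
  for (j in seq_len(d)) {
    target <- prod(fractions[seq_len(j)])
    if (fractions[j] == 1) {
      q[j] <- -Inf
      next
    }
    if (j == 1L) {
      q[1L] <- stats::qnorm(fractions[1L], lower.tail = FALSE)
      next
    }
    Rj <- R[seq_len(j), seq_len(j), drop = FALSE]
    f <- function(x) mvn_upper(c(q[seq_len(j - 1L)], x), Rj) - target
    lo <- -12; hi <- 12
    flo <- f(lo); fhi <- f(hi)
    if (flo < 0 || fhi > 0) {
      stop(sprintf(
        "truncation-point solve failed at stage %d: f(%g) = %g, f(%g) = %g",
        j, lo, flo, hi, fhi))
    }
    q[j] <- stats::uniroot(f, c(lo, hi), tol = tol)$root
  }
  realized <- mvn_upper(q, R)
  total <- prod(fractions)
  if (abs(realized - total) > 1e-6) {
    stop(sprintf(
      "realized joint survivor probability %.8f differs from prod(fractions) %.8f",
      realized, total))
  }
  structure(list(q = q, alpha = fractions, alpha_total = total, R = R),
            class = "truncation_scheme")
}

#' Tallis coefficients of a truncation scheme
#'
#' For selection `Z_j >= q_j` (all j) on criteria with correlation matrix `R`,
#' the expected standardized value of any target `Y` among the selected is
#' linear in the target's correlations with the criteria:
#' \deqn{E[Y | sel] = \sum_j \rho_j w_j,\qquad
#'       w_j = \phi(q_j)\,\bar\Phi_{d-1}\big(\tilde q^{(j)}; R^{(j)}\big)/\alpha,}
#' where the (d-1)-dimensional survivor probability uses the conditional
#' limits and partial correlations given \eqn{Z_j = q_j} (Tallis' first
#' moment). The coefficients depend on the scheme only, so several targets
#' (net merit and each trait) can share one evaluation. For `d = 1` the
#' coefficient reduces to \eqn{\phi(q)/\alpha}, the classical selection
#' intensity; for `d = 2` it reproduces the familiar two-criterion ordinate
#' formula with \eqn{Z_1 I_2 + Z_2 I_1} terms.
#'
#' @param scheme a [solve_truncation_points()] result (or a list with
#'   elements `q`, `alpha_total`, `R`).
#' @return numeric vector of coefficients `w`.
#' @export
tallis_coefficients <- function(scheme) {
  q <- scheme$q
  R <- as.matrix(scheme$R)
  a <- scheme$alpha_total
  d <- length(q)
  w <- numeric(d)
  for (j in seq_len(d)) {
    if (!is.finite(q[j])) next   # alpha = 1 stage: no truncation, no ordinate
    if (d == 1L) {
      w[j] <- stats::dnorm(q[j]) / a
      next
    }
    rj <- R[-j, j]
    qi <- q[-j]
    s2 <- 1 - rj^2
    deg <- s2 < 1e-12
    if (any(deg)) {
      # partner criterion perfectly correlated with j: conditional on
      # Z_j = q_j it sits exactly at rj * q_j
      if (any(deg & (qi > rj[deg] * q[j] + 1e-12))) next
    }
    keep <- !deg
    if (!any(keep)) {
      w[j] <- stats::dnorm(q[j]) / a
      next
    }
    s <- sqrt(s2[keep])
    qt <- (qi[keep] - rj[keep] * q[j]) / s
    qt[qi[keep] == -Inf] <- -Inf
    Rsub <- R[-j, -j, drop = FALSE][keep, keep, drop = FALSE]
    Rc <- (Rsub - outer(rj[keep], rj[keep])) / outer(s, s)
    diag(Rc) <- 1
    w[j] <- stats::dnorm(q[j]) * mvn_upper(qt, Rc) / a
  }
  w
}

#' Expected standardized value of a target after multistage truncation
#'
#' @param target_rho correlations of the target with each truncation
#'   criterion (same order as `scheme$q`).
#' @param scheme a [solve_truncation_points()] result.
#' @return the expected standard-normal-scale mean of the target among the
#'   selected candidates.
#' @examples
#' sc <- solve_truncation_points(0.5, diag(1))
#' truncated_mean(1, sc)   # 2 * dnorm(0) = 0.7979
#' @export
truncated_mean <- function(target_rho, scheme) {
  if (length(target_rho) != length(scheme$q)) {
    stop("length(target_rho) must match the number of criteria in the scheme")
  }
  if (any(abs(target_rho) > 1 + 1e-8)) stop("|target_rho| must be <= 1")
  sum(target_rho * tallis_coefficients(scheme))
}

#' Monte-Carlo oracle for the truncated mean
#'
#' Samples the (d+1)-variate normal of (target, criteria), applies the
#' truncation and returns the empirical mean of the target among survivors
#' with its standard error. Used to validate [truncated_mean()] in tests;
#' deterministic given `seed`.
#'
#' @inheritParams truncated_mean
#' @param n_draws number of draws (>= 1e4).
#' @param seed integer seed.
#' @return list with `mean`, `se`, `n_selected`, `n_draws`.
#' @export
mc_oracle <- function(target_rho, scheme, n_draws = 1e5, seed = 1L) {
  if (n_draws < 1e4) stop("n_draws must be at least 1e4")
  d <- length(scheme$q)
  if (length(target_rho) != d) stop("dimension mismatch")
  S <- rbind(c(1, target_rho), cbind(target_rho, scheme$R))
  ch <- tryCatch(chol(S), error = function(e) {
    e2 <- eigen(S, symmetric = TRUE)
    chol(e2$vectors %*% diag(pmax(e2$values, 1e-10)) %*% t(e2$vectors))
  })
  set.seed(seed)
  block <- 200000L
  total <- 0L
  ssum <- 0
  ssq <- 0
  nsel <- 0L
  while (total < n_draws) {
    nb <- min(block, n_draws - total)
    Z <- matrix(stats::rnorm(nb * (d + 1L)), nb, d + 1L) %*% ch
    sel <- rep(TRUE, nb)
    for (j in seq_len(d)) sel <- sel & (Z[, j + 1L] >= scheme$q[j])
    y <- Z[sel, 1L]
    ssum <- ssum + sum(y)
    ssq <- ssq + sum(y^2)
    nsel <- nsel + length(y)
    total <- total + nb
  }
  if (nsel < 100L) {
    stop("fewer than 100 survivors; increase n_draws for this scheme")
  }
  m <- ssum / nsel
  v <- (ssq - nsel * m^2) / (nsel - 1L)
  list(mean = m, se = sqrt(v / nsel), n_selected = nsel, n_draws = n_draws)
}

# internal: validate a correlation matrix (symmetric, unit diagonal, PSD)
check_corr_matrix <- function(R, tol = 1e-8) {
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-10))) {
    stop("correlation matrix is not symmetric")
  }
  if (any(abs(diag(R) - 1) > 1e-10)) stop("correlation matrix diagonal != 1")
  if (any(abs(R) > 1 + 1e-10)) stop("correlation entries outside [-1, 1]")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop(sprintf("correlation matrix is not positive semi-definite (smallest eigenvalue %.3e)",
                 min(ev)))
  }
  invisible(TRUE)
}
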