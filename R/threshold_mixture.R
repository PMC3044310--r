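# Gamma + Normals + Uniform mixture over attempt estimates.
#
# The histogram of attempt estimates T shows a spike near zero (erroneous
# kmers) and peaks near g * c for genomic occurrence g = 1, 2, ... where c
# is the coverage constant N(L - k + 1) / (|G| - k + 1). The mixture
#   pi_0 Gamma(alpha, beta)
#   + sum_{g=1}^G pi_g Normal(mu_g, sigma_g^2)
#   + pi_{G+1} Uniform(min T, max T)
# models this: the gamma captures the error spike, each normal one
# occurrence class, and the uniform the few kmers with occurrence > G.
# Hypothesizing Gamma-distributed Poisson means for the attempt counts
# makes each class Negative Binomial with mean mu_g = g*mu*p/(1-p) and
# variance g*mu*p/(1-p)^2, approximated by normals with matching moments.
# Internally the normal block is parametrized by the unit mean m =
# mu*p/(1-p) and unit variance v = m/(1-p) >= m, for which the weighted-ML
# M step has a closed form; the gamma shape is found by a 1-D root of the
# digamma equation. Fitting is deterministic (moment-based initialization).

.mixture_eps <- 1e-8

#' Mixture density over attempt estimates
#'
#' @param t Evaluation points.
#' @param fit An `attempt_mixture` object from [fit_mixture()].
#' @return Density values; the uniform component contributes 0 outside the
#'   fitted support.
#' @export
mixture_density <- function(t, fit) {
  stopifnot(inherits(fit, "attempt_mixture"))
  rowSums(.component_densities(t, fit) *
            matrix(fit$pi, length(t), fit$G + 2L, byrow = TRUE))
}

# n x (G + 2) matrix of component densities (gamma, normals, uniform)
.component_densities <- function(t, fit) {
  G <- fit$G
  out <- matrix(0, length(t), G + 2L)
  out[, 1] <- stats::dgamma(pmax(t, .mixture_eps), shape = fit$shape, rate = fit$rate)
  for (g in seq_len(G)) {
    out[, g + 1L] <- stats::dnorm(t, mean = g * fit$m, sd = sqrt(g * fit$v))
  }
  out[, G + 2L] <- stats::dunif(t, fit$support[1], fit$support[2])
  out
}

#' Fit the Gamma/Normals/Uniform mixture to attempt estimates by EM
#'
#' @param T_est Attempt estimates (one per observed kmer), e.g. the
#'   `attempts` column of [tidy()] on a [run_em()] fit. Values at or below
#'   `1e-8` are deterministically assigned to the gamma (error) component.
#' @param G Number of occurrence classes modeled by normal components.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param m_init Optional starting value(s) for the occurrence-class unit
#'   mean; by default a deterministic set of candidates (the largest
#'   density peak above the error spike plus upper quantiles of the
#'   estimates) is tried and the fit with the best likelihood kept, since
#'   the error spike can dominate the histogram and trap a single start in
#'   a poor local optimum.
#' @return An object of class `attempt_mixture`: mixing weights `pi`
#'   (gamma, normals, uniform), gamma `shape`/`rate`, negative-binomial
#'   `mu`/`p` with unit mean `m` and unit variance `v` (component `g` has
#'   mean `g*m`, variance `g*v`), `support`, `loglik`, `bic`, trace and
#'   convergence flag.
#' @export
fit_mixture <- function(T_est, G, max_iter = 500, tol = 1e-8, m_init = NULL) {
  T_est <- as.numeric(T_est)
  stopifnot(all(is.finite(T_est)), all(T_est >= 0), G >= 1)
  n <- length(T_est)
  if (n < 10 * (G + 4)) {
    stop("too few kmers to identify a ", G, "-class mixture", call. = FALSE)
  }
  if (is.null(m_init)) m_init <- .unit_mean_candidates(T_est)
  # short-run every start, then iterate the best one to convergence
  fits <- lapply(m_init, function(m0) {
    tryCatch(.fit_mixture_one(T_est, G, min(40L, max_iter), tol, m0),
             error = function(e) NULL)
  })
  lls <- vapply(fits, function(f) if (is.null(f)) -Inf else f$loglik, numeric(1))
  if (all(!is.finite(lls))) stop("mixture fit failed for every start", call. = FALSE)
  best <- fits[[which.max(lls)]]
  if (best$converged) return(best)
  .fit_mixture_one(T_est, G, max_iter, tol, best$m, init = best)
}

.fit_mixture_one <- function(T_est, G, max_iter, tol, m, init = NULL) {
  n <- length(T_est)
  support <- range(T_est)
  if (diff(support) <= 0) stop("degenerate support", call. = FALSE)
  forced <- T_est <= .mixture_eps  # gamma by construction (density limit at 0)

  if (is.null(init)) {
    # deterministic initialization given the unit-mean start
    low <- T_est[T_est <= stats::quantile(T_est, 0.10) & !forced]
    fit <- list(G = as.integer(G), pi = rep(1 / (G + 2L), G + 2L),
                shape = 1, rate = 1 / max(stats::median(low), .mixture_eps),
                m = m, v = 2 * m,  # p = 0.5
                support = support)
    class(fit) <- "attempt_mixture"
  } else {
    fit <- init
  }

  ll_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  pruned <- 0L
  for (iter in seq_len(max_iter)) {
    dens <- .component_densities(T_est, fit)
    wdens <- dens * matrix(fit$pi, n, G + 2L, byrow = TRUE)
    tot <- rowSums(wdens)
    tot[forced] <- 1  # replaced below
    z <- wdens / tot
    z[forced, ] <- 0
    z[forced, 1] <- 1
    ll <- sum(log(pmax(rowSums(wdens)[!forced], 1e-300))) +
      sum(forced) * log(pmax(fit$pi[1], 1e-300))
    trace <- c(trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) <= tol * (abs(ll_prev) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll

    # M step
    Ng <- colSums(z)
    pruned <- max(pruned, sum(Ng < .mixture_eps))
    fit$pi <- Ng / n
    # gamma component (weighted ML over positive T)
    w0 <- z[!forced, 1]
    t0 <- T_est[!forced]
    W0 <- sum(w0)
    if (W0 > .mixture_eps) {
      mT <- sum(w0 * t0) / W0
      mlog <- sum(w0 * log(pmax(t0, .mixture_eps))) / W0
      A <- log(mT) - mlog
      if (is.finite(A) && A > 0) {
        fit$shape <- .solve_gamma_shape(A)
        # identifiability: the gamma models erroneous kmers, whose attempt
        # mass sits below the occurrence-1 class; cap its mean at m/2 so it
        # cannot drift up and mimic a normal component
        fit$rate <- fit$shape / min(mT, fit$m / 2)
      }
    }
    # normal block: closed-form weighted ML in (m, v)
    zg <- z[, 1L + seq_len(G), drop = FALSE]
    gs <- matrix(seq_len(G), n, G, byrow = TRUE)
    Wn <- sum(zg)
    if (Wn > .mixture_eps) {
      m_new <- sum(zg * T_est) / sum(zg * gs)
      v_new <- sum(zg * (T_est - gs * m_new)^2 / gs) / Wn
      fit$m <- max(m_new, .mixture_eps)
      fit$v <- max(v_new, fit$m * (1 + 1e-8))  # NegBin requires v > m
    }
  }
  if (pruned > 0L) {
    warning(pruned, " mixture component(s) emptied during fitting",
            call. = FALSE)
  }
  p <- 1 - fit$m / fit$v
  fit$p <- min(max(p, 1e-6), 1 - 1e-6)
  fit$mu <- fit$m * (1 - fit$p) / fit$p
  fit$loglik <- utils::tail(trace, 1)
  fit$n <- n
  # free parameters: G+1 mixing weights, gamma shape+rate, negbin mu+p
  fit$n_params <- (G + 1L) + 2L + 2L
  fit$bic <- -2 * fit$loglik + fit$n_params * log(n)
  fit$loglik_trace <- trace
  fit$converged <- converged
  fit
}

# deterministic unit-mean starting candidates: the largest density peak
# above the 20th percentile, plus upper quantiles (erroneous kmers can be
# the majority class, in which case the density peak sits in the error
# spike and a higher start is needed)
.unit_mean_candidates <- function(T_est) {
  cands <- numeric(0)
  lo <- stats::quantile(T_est, 0.20)
  upper <- T_est[T_est >= lo]
  if (length(upper) >= 10) {
    d <- stats::density(upper, n = 512)
    cands <- d$x[which.max(d$y)]
  }
  cands <- c(cands, stats::quantile(T_est, c(0.5, 0.7, 0.9, 0.95)))
  cands <- unique(pmax(cands, 10 * .mixture_eps))
  unname(cands)
}

# solve log(a) - digamma(a) = A for the gamma shape
.solve_gamma_shape <- function(A) {
  f <- function(a) log(a) - digamma(a) - A
  lo <- 1e-4; hi <- 1e6
  if (f(lo) < 0) return(lo)
  if (f(hi) > 0) return(hi)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Select the number of occurrence classes by BIC
#'
#' Fits the mixture for each candidate `G` and returns the fit minimizing
#' `BIC = -2 loglik + n_params log(n)`.
#'
#' @inheritParams fit_mixture
#' @param G_range Integer vector of candidate class counts.
#' @return The best `attempt_mixture`, with a `bic_table` attribute listing
#'   the BIC of every candidate (NA where a fit failed).
#' @export
select_G <- function(T_est, G_range = 1:4, max_iter = 500, tol = 1e-8) {
  fits <- lapply(G_range, function(G) {
    tryCatch(fit_mixture(T_est, G, max_iter = max_iter, tol = tol),
             error = function(e) NULL)
  })
  bics <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic, numeric(1))
  if (all(is.na(bics))) stop("all mixture fits failed", call. = FALSE)
  best <- fits[[which.min(bics)]]
  attr(best, "bic_table") <- tibble::tibble(G = G_range, bic = bics)
  best
}

#' Posterior classification of erroneous kmers
#'
#' Flags a kmer as erroneous when its posterior membership in the gamma
#' (error) component exceeds `tau`.
#'
#' @inheritParams fit_mixture
#' @param fit An `attempt_mixture`.
#' @param tau Posterior cutoff (0.5 by default).
#' @return A logical vector aligned with `T_est`.
#' @export
classify_erroneous <- function(T_est, fit, tau = 0.5) {
  stopifnot(inherits(fit, "attempt_mixture"))
  z0 <- posterior_gamma(T_est, fit)
  z0 > tau
}

#' Posterior probability of the gamma (error) component
#'
#' @inheritParams classify_erroneous
#' @return Numeric vector of posterior gamma memberships.
#' @export
posterior_gamma <- function(T_est, fit) {
  dens <- .component_densities(T_est, fit)
  wdens <- dens * matrix(fit$pi, length(T_est), fit$G + 2L, byrow = TRUE)
  z0 <- wdens[, 1] / pmax(rowSums(wdens), 1e-300)
  z0[T_est <= .mixture_eps] <- 1
  z0
}

#' @export
print.attempt_mixture <- function(x, ...) {
  cat("Attempt-histogram mixture: gamma + ", x$G, " normal(s) + uniform\n",
      "  pi: ", paste(signif(x$pi, 3), collapse = " "), "\n",
      "  gamma shape/rate: ", signif(x$shape, 4), " / ", signif(x$rate, 4), "\n",
      "  occurrence-class unit mean m = ", signif(x$m, 4),
      " (mu = ", signif(x$mu, 4), ", p = ", signif(x$p, 4), ")\n",
      "  BIC: ", signif(x$bic, 6), "\n", sep = "")
  invisible(x)
}

#' Tidy mixture components
#'
#' @param x An `attempt_mixture`.
#' @param ... Unused.
#' @return A tibble with one row per component: label, mixing weight, mean
#'   and variance (NA where undefined for the uniform).
#' @export
tidy.attempt_mixture <- function(x, ...) {
  G <- x$G
  tibble::tibble(
    component = c("gamma", paste0("normal_", seq_len(G)), "uniform"),
    occurrence = c(0L, seq_len(G), NA_integer_),
    pi = x$pi,
    mean = c(x$shape / x$rate, seq_len(G) * x$m, mean(x$support)),
    variance = c(x$shape / x$rate^2, seq_len(G) * x$v, diff(x$support)^2 / 12)
  )
}

#' One-row summary of a mixture fit
#'
#' @inheritParams tidy.attempt_mixture
#' @return A one-row tibble with `G`, `loglik`, `bic`, `converged` and the
#'   coverage-constant estimate `m` (the first normal's mean).
#' @export
glance.attempt_mixture <- function(x, ...) {
  tibble::tibble(
    G = x$G, loglik = x$loglik, bic = x$bic,
    converged = x$converged, unit_mean = x$m
  )
}

#' Simulate draws from a fitted (or hand-built) attempt mixture
#'
#' Convenience generator for testing and calibration studies: draws from
#' the gamma/normals/uniform mixture with the given parameters.
#'
#' @param n Number of draws.
#' @param pi Mixing weights (gamma, `G` normals, uniform).
#' @param shape,rate Gamma parameters.
#' @param m,v Unit mean and variance of the occurrence classes.
#' @param support Uniform component support (length 2).
#' @return Numeric draws, truncated below at 0.
#' @export
simulate_mixture <- function(n, pi, shape, rate, m, v, support) {
  G <- length(pi) - 2L
  comp <- sample.int(G + 2L, n, replace = TRUE, prob = pi)
  out <- numeric(n)
  is_g <- comp == 1L
  out[is_g] <- stats::rgamma(sum(is_g), shape = shape, rate = rate)
  for (g in seq_len(G)) {
    sel <- comp == g + 1L
    out[sel] <- stats::rnorm(sum(sel), mean = g * m, sd = sqrt(g * v))
  }
  is_u <- comp == G + 2L
  out[is_u] <- stats::runif(sum(is_u), support[1], support[2])
  pmax(out, 0)
}
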