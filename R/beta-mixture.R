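#' Fit a 3-component beta mixture to methylation levels
#'
#' EM fit of a mixture of three beta distributions to pooled beta-values,
#' the basis for discretizing methylation into unmethylated / semi /
#' methylated states. The E-step computes responsibilities from the
#' weighted beta densities; the M-step starts from weighted
#' moment-matching shape estimates and refines them by maximising the
#' expected complete-data log-likelihood for each component (a 2-parameter
#' optimisation over sufficient statistics, so the refinement is cheap and
#' the observed log-likelihood is non-decreasing across iterations).
#' Components are reordered by mean before return and the two
#' equal-density thresholds are attached.
#'
#' @param values numeric vector of beta-values in [0,1]; clipped to
#'   [1e-6, 1-1e-6] before likelihood evaluation. At least 100 values.
#' @param k number of components; only 3 is supported.
#' @param tol convergence tolerance on the log-likelihood increase.
#' @param max_iter maximum EM iterations; on non-convergence the model is
#'   returned with `converged = FALSE` and a warning.
#' @param max_values cap on the number of values used for fitting; larger
#'   inputs are thinned deterministically (evenly spaced subsequence).
#' @return An object of class `BetaMixtureModel`: `weights`, `shape1`,
#'   `shape2` (component means strictly increasing), `t_low`, `t_high`,
#'   `loglik` (trace), `iterations`, `converged`, `threshold_fallback`.
#' @export
fit_beta_mixture <- function(values, k = 3L, tol = 0.01, max_iter = 200L,
                             max_values = 200000L) {
  if (k != 3L) stop("only k = 3 components are supported", call. = FALSE)
  values <- values[!is.na(values)]
  if (any(values < 0 | values > 1)) {
    stop("beta-values must lie in [0, 1]", call. = FALSE)
  }
  x <- pmin(pmax(values, 1e-6), 1 - 1e-6)
  if (length(x) < 100) {
    stop("need at least 100 values to fit the mixture", call. = FALSE)
  }
  if (length(x) > max_values) {
    ## deterministic thinning: the pooled histogram is massively
    ## redundant and the global fit does not need every value
    x <- x[seq(1L, length(x), length.out = max_values)]
  }
  n <- length(x)
  lx <- log(x)
  l1x <- log1p(-x)

  ## deterministic init: quantile tertiles -> method-of-moments shapes
  qs <- stats::quantile(x, c(1, 2) / 3, names = FALSE)
  grp <- findInterval(x, qs) + 1L
  w <- tabulate(grp, 3L) / n
  shp <- t(vapply(1:3, function(j) {
    moment_shapes(mean(x[grp == j]), stats::var(x[grp == j]))
  }, numeric(2)))
  shp[2, ] <- pmax(shp[2, ], 1)  # middle component starts feasible

  loglik <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ## keep components ordered by mean so the interior-component
    ## constraint below always targets the semi-methylated component
    ord <- order(shp[, 1] / (shp[, 1] + shp[, 2]))
    shp <- shp[ord, , drop = FALSE]
    w <- w[ord]

    ## E-step
    logd <- vapply(1:3, function(j) {
      log(w[j]) + stats::dbeta(x, shp[j, 1], shp[j, 2], log = TRUE)
    }, numeric(n))
    m <- pmax(logd[, 1], logd[, 2], logd[, 3])
    lse <- m + log(exp(logd[, 1] - m) + exp(logd[, 2] - m) +
                     exp(logd[, 3] - m))
    ll <- sum(lse)
    loglik <- c(loglik, ll)
    if (is.finite(ll) && ll - ll_old < tol && iter > 1) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    r <- exp(logd - lse)

    ## M-step: weighted moments, then weighted MLE per component via the
    ## sufficient statistics sum(r log x), sum(r log(1-x)). The middle
    ## component is constrained to shapes >= 1 (unimodal on the
    ## interior): boundary-peaked shapes belong to the outer components,
    ## and an unconstrained middle component can otherwise collapse onto
    ## clipped boundary values.
    nk <- colSums(r)
    w <- nk / n
    for (j in 1:3) {
      mj <- sum(r[, j] * x) / nk[j]
      vj <- sum(r[, j] * (x - mj)^2) / nk[j]
      s1 <- sum(r[, j] * lx)
      s2 <- sum(r[, j] * l1x)
      lower <- if (j == 2) c(0, 0) else c(log(1e-3), log(1e-3))
      init <- pmax(moment_shapes(mj, vj), exp(lower))
      neg_q <- function(lp) {
        a <- exp(lp[1]); b <- exp(lp[2])
        -((a - 1) * s1 + (b - 1) * s2 - nk[j] * lbeta(a, b))
      }
      opt <- try(stats::optim(log(init), neg_q, method = "L-BFGS-B",
                              lower = lower, upper = c(log(1e4), log(1e4)),
                              control = list(maxit = 100)), silent = TRUE)
      ## never decrease Q relative to the current (feasible) shapes:
      ## this is what makes the observed log-likelihood monotone
      cand <- list(pmax(shp[j, ], exp(lower)), init)
      if (!inherits(opt, "try-error")) cand <- c(cand, list(exp(opt$par)))
      qvals <- vapply(cand, function(s) neg_q(log(s)), numeric(1))
      shp[j, ] <- cand[[which.min(qvals)]]
    }
  }
  if (!converged) {
    warning("beta mixture EM did not converge in ", max_iter, " iterations")
  }

  ord <- order(shp[, 1] / (shp[, 1] + shp[, 2]))
  model <- structure(list(weights = w[ord],
                          shape1 = shp[ord, 1],
                          shape2 = shp[ord, 2],
                          t_low = NA_real_, t_high = NA_real_,
                          loglik = loglik,
                          iterations = length(loglik),
                          converged = converged,
                          threshold_fallback = c(low = "none", high = "none")),
                     class = "BetaMixtureModel")
  thr <- equal_density_thresholds(model)
  model$t_low <- thr[["t_low"]]
  model$t_high <- thr[["t_high"]]
  model$threshold_fallback <- attr(thr, "fallback")
  model
}

## method-of-moments shapes for a beta distribution, guarded against
## degenerate variance
moment_shapes <- function(m, v) {
  m <- min(max(m, 1e-4), 1 - 1e-4)
  v <- max(min(v, m * (1 - m) * 0.99), 1e-8)
  common <- m * (1 - m) / v - 1
  pmax(c(m * common, (1 - m) * common), 1e-3)
}

#' @export
print.BetaMixtureModel <- function(x, ...) {
  means <- x$shape1 / (x$shape1 + x$shape2)
  cat("3-component beta mixture\n")
  for (j in 1:3) {
    cat(sprintf("  w=%.3f  Beta(%.2f, %.2f)  mean=%.3f\n",
                x$weights[j], x$shape1[j], x$shape2[j], means[j]))
  }
  cat(sprintf("  thresholds: t_low=%.4f  t_high=%.4f  (converged: %s, %d iter)\n",
              x$t_low, x$t_high, x$converged, x$iterations))
  invisible(x)
}

#' Equal-density thresholds of a fitted beta mixture
#'
#' The discretization cut-offs are the points where the weighted densities
#' of adjacent components are equal: `t_low` solves
#' w1 f1(x) = w2 f2(x) between the first and second component means, and
#' `t_high` solves w2 f2(x) = w3 f3(x) between the second and third. Roots
#' are found to an absolute tolerance well below 1e-6. If the weighted
#' densities do not cross on the search interval (e.g. a vanishing middle
#' component), the crossing of the two outer components is used; failing
#' that, the midpoint of the adjacent means. The fallback used is recorded
#' in the `fallback` attribute.
#'
#' @param model a `BetaMixtureModel` with components ordered by mean.
#' @return Named numeric vector `c(t_low=, t_high=)` with attribute
#'   `fallback`.
#' @export
equal_density_thresholds <- function(model) {
  w <- model$weights; a <- model$shape1; b <- model$shape2
  means <- a / (a + b)
  if (is.unsorted(means, strictly = TRUE)) {
    stop("model components must be ordered by strictly increasing mean",
         call. = FALSE)
  }
  wdens <- function(x, j) w[j] * stats::dbeta(x, a[j], b[j])
  eps <- 1e-9

  crossing <- function(i, j, lo, hi) {
    f <- function(x) wdens(x, i) - wdens(x, j)
    lo <- max(lo, eps); hi <- min(hi, 1 - eps)
    if (hi <= lo) return(NULL)
    flo <- f(lo); fhi <- f(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NULL)
    stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }

  fallback <- c(low = "none", high = "none")
  solve_one <- function(i, j, lo, hi, side) {
    root <- crossing(i, j, lo, hi)
    if (!is.null(root)) return(root)
    ## the middle component may carry ~no weight on this flank: use the
    ## crossing of the flanking outer components
    root <- crossing(1, 3, means[1], means[3])
    if (!is.null(root)) {
      fallback[side] <<- "outer_crossing"
      return(root)
    }
    fallback[side] <<- "midpoint"
    (lo + hi) / 2
  }
  t_low <- solve_one(1, 2, means[1], means[2], "low")
  t_high <- solve_one(2, 3, means[2], means[3], "high")
  if (t_low > t_high) {  # degenerate fits: keep the invariant ordering
    mid <- (t_low + t_high) / 2
    t_low <- t_high <- mid
    fallback[] <- "collapsed"
  }
  structure(c(t_low = t_low, t_high = t_high), fallback = fallback)
}

#' Discretize a beta-value matrix into U / S / M states
#'
#' Values below `t_low` become "U" (unmethylated), above `t_high` become
#' "M" (methylated), everything else — including values exactly at a
#' threshold — becomes "S" (semi-methylated / unknown, the conservative
#' call at the boundary).
#'
#' @param beta a [beta_matrix()].
#' @param model a fitted `BetaMixtureModel` with thresholds.
#' @return An object of class `DiscreteMatrix`: character `states` matrix
#'   with the same dimnames, plus threshold provenance.
#' @export
discretize <- function(beta, model) {
  stopifnot(inherits(beta, "BetaMatrix"), inherits(model, "BetaMixtureModel"))
  if (!is.finite(model$t_low) || !is.finite(model$t_high)) {
    stop("model carries no thresholds", call. = FALSE)
  }
  v <- beta$values
  states <- matrix("S", nrow = nrow(v), ncol = ncol(v), dimnames = dimnames(v))
  states[v < model$t_low] <- "U"
  states[v > model$t_high] <- "M"
  structure(list(states = states,
                 probe_ids = rownames(v),
                 sample_ids = colnames(v),
                 t_low = model$t_low, t_high = model$t_high),
            class = "DiscreteMatrix")
}

#' @export
print.DiscreteMatrix <- function(x, ...) {
  tab <- table(factor(x$states, levels = c("U", "S", "M")))
  cat("DiscreteMatrix:", nrow(x$states), "probes x", ncol(x$states),
      "samples\n  states:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Drop probes without information content
#'
#' Keeps only probes that show a definite state ("U" or "M") in at least
#' `min_definite` samples; the remainder carry no clustering signal. With
#' `require_both = TRUE` a probe must additionally show both definite
#' states at least once (stricter variant).
#'
#' @param d a `DiscreteMatrix`.
#' @param min_definite minimum number of definite calls per probe.
#' @param require_both require both "U" and "M" to occur.
#' @return The filtered `DiscreteMatrix`; the number of removed probes is
#'   in attribute `removed`.
#' @export
filter_informative_probes <- function(d, min_definite = 10L,
                                      require_both = FALSE) {
  stopifnot(inherits(d, "DiscreteMatrix"), min_definite >= 0)
  definite <- d$states != "S"
  keep <- rowSums(definite) >= min_definite
  if (require_both) {
    keep <- keep & rowSums(d$states == "U") > 0 & rowSums(d$states == "M") > 0
  }
  if (!any(keep)) {
    warning("no probe passes the information-content filter")
  }
  out <- d
  out$states <- d$states[keep, , drop = FALSE]
  out$probe_ids <- rownames(out$states)
  attr(out, "removed") <- sum(!keep)
  out
}

#' Numeric encoding of discrete methylation states
#'
#' U = 0, S = 0.5, M = 1; this is the feature matrix fed to the clustering
#' ensemble (samples as rows).
#'
#' @param d a `DiscreteMatrix`.
#' @return Numeric samples-by-probes matrix.
#' @export
discrete_to_numeric <- function(d) {
  stopifnot(inherits(d, "DiscreteMatrix"))
  num <- matrix(0.5, nrow = nrow(d$states), ncol = ncol(d$states),
                dimnames = dimnames(d$states))
  num[d$states == "U"] <- 0
  num[d$states == "M"] <- 1
  t(num)
}
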