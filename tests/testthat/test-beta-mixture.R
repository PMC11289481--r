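rmix3 <- function(n, w, shapes, seed) {
  set.seed(seed)
  z <- sample(1:3, n, replace = TRUE, prob = w)
  vapply(z, function(j) stats::rbeta(1, shapes[j, 1], shapes[j, 2]),
         numeric(1))
}

test_that("EM recovers a known symmetric mixture and its thresholds", {
  truth_w <- c(0.45, 0.10, 0.45)
  shapes <- rbind(c(2, 18), c(10, 10), c(18, 2))
  x <- rmix3(20000, truth_w, shapes, seed = 7)
  m <- fit_beta_mixture(x)
  expect_true(m$converged)
  expect_lt(max(abs(m$weights - truth_w)), 0.03)
  means <- m$shape1 / (m$shape1 + m$shape2)
  expect_lt(max(abs(means - c(0.1, 0.5, 0.9))), 0.02)
  ## mirrored input: thresholds symmetric about 0.5
  expect_lt(abs(m$t_low - (1 - m$t_high)), 0.02)
  ## log-likelihood trace is monotone non-decreasing
  expect_true(all(diff(m$loglik) > -1e-8))
})

test_that("parameter recovery holds across seeds for separated mixtures", {
  shapes <- rbind(c(3, 20), c(12, 12), c(20, 3))
  for (s in 1:3) {
    x <- rmix3(12000, c(0.4, 0.2, 0.4), shapes, seed = 100 + s)
    m <- fit_beta_mixture(x)
    means <- m$shape1 / (m$shape1 + m$shape2)
    true_means <- shapes[, 1] / rowSums(shapes)
    expect_lt(max(abs(means - true_means)), 0.02)
  }
})

test_that("fit rejects invalid input", {
  expect_error(fit_beta_mixture(runif(50)), "at least 100")
  expect_error(fit_beta_mixture(c(runif(200), 1.5)), "0, 1")
  expect_error(fit_beta_mixture(runif(200), k = 2), "k = 3")
})

test_that("equal-density thresholds solve the weighted-density crossings", {
  x <- rmix3(8000, c(0.4, 0.25, 0.35), rbind(c(2, 12), c(9, 9), c(14, 2)),
             seed = 11)
  m <- fit_beta_mixture(x)
  wdens <- function(t, j) m$weights[j] * stats::dbeta(t, m$shape1[j],
                                                      m$shape2[j])
  if (m$threshold_fallback[["low"]] == "none") {
    expect_lt(abs(wdens(m$t_low, 1) - wdens(m$t_low, 2)), 1e-6)
  }
  if (m$threshold_fallback[["high"]] == "none") {
    expect_lt(abs(wdens(m$t_high, 2) - wdens(m$t_high, 3)), 1e-6)
  }
})

test_that("vanishing middle component falls back to the outer crossing", {
  ## equal-weight Beta(1,3) vs Beta(3,1): densities 3(1-x)^2 and 3x^2
  ## cross at exactly 0.5
  model <- structure(list(weights = c(0.5, 1e-14, 0.5),
                          shape1 = c(1, 5, 3), shape2 = c(3, 5, 1),
                          t_low = NA_real_, t_high = NA_real_),
                     class = "BetaMixtureModel")
  thr <- equal_density_thresholds(model)
  expect_equal(unname(thr[["t_low"]]), 0.5, tolerance = 1e-6)
  expect_equal(unname(thr[["t_high"]]), 0.5, tolerance = 1e-6)
  expect_true(all(attr(thr, "fallback") == "outer_crossing"))
})

test_that("discretization maps thresholds conservatively and is monotone", {
  model <- structure(list(weights = c(0.45, 0.1, 0.45),
                          shape1 = c(2, 10, 18), shape2 = c(18, 10, 2),
                          t_low = 0.3, t_high = 0.7,
                          loglik = 0, iterations = 1, converged = TRUE),
                     class = "BetaMixtureModel")
  v <- matrix(c(0.0001, 0.3, 0.5, 0.7, 0.9999, 0.29999, 0.70001, 0.1, 0.5),
              nrow = 3,
              dimnames = list(paste0("p", 1:3), paste0("s", 1:3)))
  d <- discretize(beta_matrix(v), model)
  expect_equal(d$states[1, 1], "U")        # near 0
  expect_equal(d$states[2, 1], "S")        # exactly t_low -> S
  expect_equal(d$states[1, 2], "S")        # exactly t_high -> S
  expect_equal(d$states[2, 2], "M")        # near 1
  ## partition: every value is in exactly one state
  expect_equal(sum(table(d$states)), length(v))
  ## monotone: U < S < M follows the value ordering
  ord <- c(U = 1, S = 2, M = 3)
  vs <- sort(as.vector(v), index.return = TRUE)
  states_sorted <- ord[as.vector(d$states)[vs$ix]]
  expect_true(all(diff(states_sorted) >= 0))
})

test_that("information-content filter applies the 10-definite-sample rule", {
  states <- matrix("S", 3, 12,
                   dimnames = list(paste0("p", 1:3), paste0("s", 1:12)))
  states[1, 1:9] <- "M"    # 9 definite calls -> removed
  states[2, 1:10] <- "U"   # 10 definite calls -> retained
  states[3, 1:5] <- "U"; states[3, 6:11] <- "M"  # 11 pooled -> retained
  d <- structure(list(states = states, probe_ids = rownames(states),
                      sample_ids = colnames(states),
                      t_low = 0.3, t_high = 0.7),
                 class = "DiscreteMatrix")
  f <- filter_informative_probes(d, min_definite = 10)
  expect_setequal(rownames(f$states), c("p2", "p3"))
  expect_equal(attr(f, "removed"), 1L)
  ## min_definite = 0 is the identity filter
  f0 <- filter_informative_probes(d, min_definite = 0)
  expect_equal(nrow(f0$states), 3L)
  ## the stricter variant drops probes showing only one definite state
  fb <- filter_informative_probes(d, min_definite = 10, require_both = TRUE)
  expect_equal(rownames(fb$states), "p3")
  ## all-S input warns and returns nothing
  states[] <- "S"
  d$states <- states
  expect_warning(fa <- filter_informative_probes(d), "no probe")
  expect_equal(nrow(fa$states), 0L)
})
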