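rj_small <- function(seed = 1L, iterations = 2000, thin = 10) {
  tr <- simulate_yule_tree(12, tree_height = 10, seed = 90)
  y <- simulate_bm_trait(tr, 0.05, 0, seed = 91)
  list(tree = tr, trait = y,
       post = run_rjmcmc_trait(y, tr, iterations = iterations, thin = thin,
                               burn_in = 0.3, chains = 2, seed = seed))
}

test_that("every retained sample's logLik matches ou_loglik on the implied painting", {
  # cross-module oracle: rebuild each sampled shift configuration as a regime
  # painting and ask the standalone OU likelihood for its density
  fit <- rj_small()
  post <- fit$post
  tr <- fit$tree; y <- fit$trait
  idx <- unique(round(seq(1, nrow(post$samples), length.out = 12)))
  for (s in idx) {
    sh <- post$shift_samples[[s]]
    row <- post$samples[s, ]
    if (length(sh$edge) == 0) {
      p <- painting_single(tr, "base")
      theta <- c(base = row$theta0)
    } else {
      nm <- paste0("s", seq_along(sh$edge))
      p <- painting_from_shifts(
        tr, data.frame(edge = sh$edge, pos = sh$pos, regime = nm),
        base_regime = "base")
      theta <- c(base = row$theta0, setNames(sh$theta, nm))
    }
    expect_equal(
      ou_loglik(y, tr, p, row$alpha, row$sigma2, theta, root = "stationary"),
      row$logLik, tolerance = 1e-7)
  }
})

test_that("the sampler is bit-for-bit reproducible by seed", {
  a <- rj_small(seed = 7)$post
  b <- rj_small(seed = 7)$post
  expect_identical(a$samples, b$samples)
  expect_identical(a$branch, b$branch)
  c2 <- rj_small(seed = 8)$post
  expect_false(identical(a$samples, c2$samples))
})

test_that("shift_posterior carries coherent summaries", {
  post <- rj_small()$post
  expect_s3_class(post, "shift_posterior")
  tr <- simulate_yule_tree(12, tree_height = 10, seed = 90)
  expect_equal(nrow(post$branch), nrow(tr$edge))
  expect_true(all(post$branch$pp >= 0 & post$branch$pp <= 1))
  expect_equal(sum(post$k_posterior$prob), 1, tolerance = 1e-12)
  expect_true(post$k_hpd[1] <= post$k_median && post$k_median <= post$k_hpd[2])
  expect_setequal(post$diagnostics$parameter,
                  c("alpha", "sigma2", "k", "logLik"))
  expect_true(all(post$diagnostics$rhat >= 1))
  s_all <- summarize_shifts(post, pp_threshold = 0)
  expect_equal(nrow(s_all$branches), nrow(tr$edge))
  s_none <- summarize_shifts(post, pp_threshold = 1.01)
  expect_equal(nrow(s_none$branches), 0)
  expect_equal(s_all$k_summary$k_mode, post$k_mode)
})

test_that("input validation rejects unusable sampler settings", {
  tr <- simulate_yule_tree(8, tree_height = 5, seed = 92)
  y <- simulate_bm_trait(tr, 0.1, 0, seed = 93)
  expect_error(run_rjmcmc_trait(y, tr, iterations = 1000, thin = 10,
                                chains = 1), "at least 2 chains")
  expect_error(run_rjmcmc_trait(y, tr, iterations = 50, thin = 10,
                                chains = 2), "10 \\* thin")
})

test_that("prior-only sampling reproduces the conditional Poisson shift prior", {
  tr <- simulate_yule_tree(15, tree_height = 10, seed = 94)
  y <- simulate_bm_trait(tr, 0.05, 0, seed = 95)
  post <- run_rjmcmc_trait(y, tr, iterations = 30000, thin = 5,
                           burn_in = 0.2, chains = 2, seed = 3,
                           likelihood = FALSE)
  kmax <- post$prior$k_max
  target <- dpois(0:kmax, 1); target <- target / sum(target)
  emp <- rep(0, kmax + 1)
  emp[post$k_posterior$k + 1] <- post$k_posterior$prob
  # Poisson(1) truncated: P(0) = P(1) ~ 0.368
  expect_equal(emp[1], target[1], tolerance = 0.25)
  expect_equal(emp[2], target[2], tolerance = 0.25)
  expect_equal(emp[3], target[3], tolerance = 0.35)
})

test_that("prior placement favours long edges in proportion to length", {
  tr <- simulate_yule_tree(15, tree_height = 10, seed = 94)
  y <- simulate_bm_trait(tr, 0.05, 0, seed = 95)
  post <- run_rjmcmc_trait(y, tr, iterations = 30000, thin = 5,
                           burn_in = 0.2, chains = 2, seed = 4,
                           likelihood = FALSE)
  pp <- post$branch$pp
  len <- tr$edge.length
  # conditional on a shift, an edge is hit roughly in proportion to length
  expect_gt(cor(pp, len), 0.7)
})

test_that("the allometry flavour tracks per-edge slopes", {
  tr <- simulate_yule_tree(12, tree_height = 10, seed = 96)
  x <- simulate_bm_trait(tr, 0.02, 0, seed = 97)
  y <- setNames(0.2 + 0.7 * unname(x), names(x)) +
    simulate_bm_trait(tr, 0.005, 0, seed = 98)
  post <- run_rjmcmc_allometry(y, x, tr, iterations = 2000, thin = 10,
                               burn_in = 0.3, chains = 2, seed = 5)
  expect_equal(post$flavour, "allometry")
  expect_true("mean_beta" %in% names(post$branch))
  expect_true(is.numeric(post$root_beta))
  expect_true("beta0" %in% names(post$samples))
})

test_that("convergence diagnostics behave at the calibration points", {
  set.seed(10)
  x <- rnorm(500)
  same <- list(tibble::tibble(p = x), tibble::tibble(p = x))
  d_same <- convergence_diagnostics(same)
  expect_equal(d_same$rhat, 1)
  apart <- list(tibble::tibble(p = x), tibble::tibble(p = x + 5))
  expect_gt(convergence_diagnostics(apart)$rhat, 1.1)
  iid <- list(tibble::tibble(p = rnorm(500)), tibble::tibble(p = rnorm(500)))
  d_iid <- convergence_diagnostics(iid)
  expect_lt(d_iid$rhat, 1.05)
  expect_gt(d_iid$ess, 300)
  expect_error(convergence_diagnostics(list(tibble::tibble(p = x))),
               "at least 2")
  expect_error(convergence_diagnostics(
    list(tibble::tibble(p = x), tibble::tibble(p = x[1:10]))),
    "unequal")
})

test_that("discrete_hpd accumulates highest-mass values first", {
  expect_equal(allomacro:::discrete_hpd(0:3, c(0.5, 0.3, 0.15, 0.05), 0.95),
               c(0, 2))
  expect_equal(allomacro:::discrete_hpd(0:2, c(0.96, 0.03, 0.01), 0.95),
               c(0, 0))
  # ties break toward smaller k
  expect_equal(allomacro:::discrete_hpd(0:1, c(0.5, 0.5), 0.4), c(0, 0))
})
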