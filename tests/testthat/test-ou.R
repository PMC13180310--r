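test_that("fit_bm matches the closed-form GLS root, rate and likelihood", {
  tr <- rand_tree(20, 2, height = 3)
  y <- simulate_bm_trait(tr, 1.3, 0.5, seed = 7)
  fit <- fit_bm(y, tr)
  V <- phylo_vcv(tr)
  ones <- matrix(1, 20, 1)
  root_hat <- gls_oracle(ones, unname(y), V)
  r <- unname(y) - root_hat
  s2_hat <- drop(t(r) %*% solve(V, r)) / 20
  expect_equal(fit$root, root_hat, tolerance = 1e-9)
  expect_equal(unname(fit$sigma2), s2_hat, tolerance = 1e-9)
  expect_equal(fit$logLik,
               mvn_logdens(unname(y), rep(root_hat, 20), s2_hat * V),
               tolerance = 1e-9)
  expect_equal(fit$k, 2)
})

test_that("multi-rate BM with one regime equals the single-rate fit", {
  tr <- rand_tree(15, 3, height = 2)
  y <- simulate_bm_trait(tr, 0.8, 0, seed = 9)
  f1 <- fit_bm(y, tr)
  f2 <- fit_bm(y, tr, painting = painting_single(tr, "base"))
  expect_equal(f2$logLik, f1$logLik, tolerance = 1e-8)
  expect_equal(unname(f2$sigma2), unname(f1$sigma2), tolerance = 1e-8)
  expect_equal(f2$k, 2)
})

test_that("multi-rate BM recovers a strong rate contrast", {
  tr <- simulate_yule_tree(80, tree_height = 10, seed = 4)
  sim <- simulate_discrete_regimes(tr, c(a_to_b = 0.08, b_to_a = 0.08), "a",
                                   seed = 5)
  y <- simulate_bm_trait(tr, c(a = 0.1, b = 3), 0, seed = 6,
                         painting = sim$painting)
  fit <- fit_bm(y, tr, painting = sim$painting)
  expect_gt(fit$sigma2[["b"]] / fit$sigma2[["a"]], 5)
  single <- fit_bm(y, tr)
  expect_gt(fit$logLik, single$logLik)
})

test_that("ou_loglik equals a brute-force MVN density under both root models", {
  tr <- read_newick("(((A:1,B:1):1,C:2):1,D:3);")
  ab <- ape::getMRCA(tr, c("A", "B"))
  e_ab <- which(tr$edge[, 2] == ab)
  p <- painting_from_shifts(tr, data.frame(edge = e_ab, pos = 0.4,
                                           regime = "hot"),
                            base_regime = "base")
  y <- setNames(c(0.3, -0.2, 1.1, 0.6), c("A", "B", "C", "D"))
  alpha <- 0.7; sigma2 <- 0.9
  theta <- c(base = 0.2, hot = 1.5)
  for (root in c("stationary", "fixed")) {
    mu <- ou_mean_oracle(tr, p, alpha, theta,
                         root_mean = theta[["base"]])
    C <- ou_cov_oracle(tr, alpha, sigma2, root = root)
    expect_equal(ou_loglik(y, tr, p, alpha, sigma2, theta, root = root),
                 mvn_logdens(unname(y[tr$tip.label]),
                             mu, C[tr$tip.label, tr$tip.label]),
                 tolerance = 1e-9)
  }
})

test_that("fit_ou maximises its own likelihood (ou_loglik cross-check)", {
  tr <- simulate_yule_tree(40, tree_height = 8, seed = 11)
  sim <- simulate_discrete_regimes(tr, c(a_to_b = 0.15, b_to_a = 0.15), "a",
                                   seed = 12)
  y <- simulate_ou_trait(tr, 0.5, 1, c(a = 0, b = 2), seed = 13,
                         painting = sim$painting)
  fit <- fit_ou(y, tr, painting = sim$painting)
  lmax <- ou_loglik(y, tr, sim$painting, fit$alpha, fit$sigma2, fit$theta)
  expect_equal(fit$logLik, lmax, tolerance = 1e-8)
  # perturbing any parameter cannot improve the likelihood
  expect_lt(ou_loglik(y, tr, sim$painting, fit$alpha * 1.3, fit$sigma2,
                      fit$theta), lmax + 1e-8)
  expect_lt(ou_loglik(y, tr, sim$painting, fit$alpha, fit$sigma2 * 1.2,
                      fit$theta), lmax + 1e-8)
  expect_lt(ou_loglik(y, tr, sim$painting, fit$alpha, fit$sigma2,
                      fit$theta + c(0.1, 0)), lmax + 1e-8)
  expect_equal(fit$half_life, log(2) / fit$alpha)
  expect_equal(fit$stationary_variance, fit$sigma2 / (2 * fit$alpha))
})

test_that("fit_ou recovers generating optima on a well-powered design", {
  tr <- simulate_yule_tree(120, tree_height = 10, seed = 21)
  sim <- simulate_discrete_regimes(tr, c(a_to_b = 0.1, b_to_a = 0.1), "a",
                                   seed = 22)
  y <- simulate_ou_trait(tr, 1, 0.5, c(a = -1, b = 1), seed = 23,
                         painting = sim$painting)
  fit <- fit_ou(y, tr, painting = sim$painting)
  expect_equal(unname(fit$theta["a"]), -1, tolerance = 0.35)
  expect_equal(unname(fit$theta["b"]), 1, tolerance = 0.35)
  expect_gt(fit$alpha, 0.3)
  expect_lt(fit$alpha, 3 * 1) # allow generous ML spread around alpha = 1
})

test_that("fixed-root OU at tiny alpha approaches the BM likelihood", {
  tr <- rand_tree(15, 6, height = 2)
  y <- simulate_bm_trait(tr, 1, 0, seed = 31)
  bm <- fit_bm(y, tr)
  ll_tiny <- ou_loglik(y, tr, painting_single(tr), alpha = 1e-7,
                       sigma2 = unname(bm$sigma2),
                       theta = c(base = bm$root), root = "fixed")
  expect_equal(ll_tiny, bm$logLik, tolerance = 1e-4)
})

test_that("compare_models builds a coherent AICc table and guards inputs", {
  tr <- simulate_yule_tree(50, tree_height = 8, seed = 41)
  y <- simulate_bm_trait(tr, 1, 0, seed = 42)
  bm <- fit_bm(y, tr)
  ou <- fit_ou(y, tr)
  tab <- compare_models(bm, ou)
  expect_s3_class(tab, "model_table")
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_equal(tab$delta_AICc[1], 0)
  expect_true(all(diff(tab$AICc) >= 0))
  expect_equal(tab$AICc,
               -2 * tab$logLik + 2 * tab$k +
                 2 * tab$k * (tab$k + 1) / (50 - tab$k - 1))
  y2 <- y; y2[1] <- y2[1] + 1
  bm2 <- fit_bm(y2, tr)
  expect_error(compare_models(bm, bm2, ou), "identical data")
})

test_that("ancestral_continuous matches ape::ace ML reconstruction", {
  tr <- rand_tree(25, 51, height = 1)
  y <- simulate_bm_trait(tr, 1, 0, seed = 52)
  anc <- ancestral_continuous(y, tr)
  ref <- phytools::fastAnc(tr, y) # exact re-rooted GLS root estimates
  expect_equal(anc$estimate, unname(as.numeric(ref)), tolerance = 1e-6)
  expect_true(all(anc$var >= 0))
  # the root estimate equals the GLS/ML root
  expect_equal(anc$estimate[anc$node == 26], fit_bm(y, tr)$root,
               tolerance = 1e-6)
})

test_that("half_life warns on non-positive alpha", {
  expect_equal(half_life(0.1), log(2) / 0.1)
  expect_warning(h <- half_life(0), "infinite")
  expect_identical(h, Inf)
})
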