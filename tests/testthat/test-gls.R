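test_that("summarize_species computes means, variances and imputation", {
  df <- tibble::tibble(
    species = c("a", "a", "b", "b", "b", "c"),
    body_mass_g = c(10, 1000, 10, 100, 1000, 100),
    smr = c(1, 1, 2, 2, 2, 4),
    family = c("f1", "f1", "f1", "f1", "f1", "f2")
  )
  s <- summarize_species(df)
  expect_s3_class(s, "species_summary")
  expect_equal(s$n, c(2L, 3L, 1L))
  expect_equal(s$mean_x[s$species == "a"], mean(log10(c(10, 1000))))
  expect_equal(s$var_x[s$species == "a"], var(log10(c(10, 1000))) / 2)
  # singleton 'c' gets the pooled within-species variance over its n of 1
  pooled <- (var(log10(c(10, 1000))) * 1 + var(log10(c(10, 100, 1000))) * 2) / 3
  expect_equal(s$var_x[s$species == "c"], pooled)
  expect_equal(s$var_imputed, c(FALSE, FALSE, TRUE))
  expect_equal(s$family, c("f1", "f1", "f2"))
  expect_error(summarize_species(dplyr::mutate(df, smr = smr - 1)),
               "nonpositive")
})

test_that("fit_ols agrees with lm to machine precision", {
  set.seed(1)
  d <- tibble::tibble(species = paste0("s", 1:20),
                      mean_x = rnorm(20), mean_y = rnorm(20))
  fit <- fit_ols(d)
  ref <- lm(mean_y ~ mean_x, data = d)
  expect_equal(unname(fit$coefficients$estimate), unname(coef(ref)),
               tolerance = 1e-12)
  expect_equal(unname(fit$coefficients$std_error),
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-12)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-12)
})

test_that("fit_pgls at lambda = 0 reduces to OLS", {
  tr <- rand_tree(15, 3, height = 2)
  set.seed(4)
  d <- tibble::tibble(species = tr$tip.label, mean_x = rnorm(15),
                      mean_y = rnorm(15))
  p0 <- fit_pgls(d, tr, lambda = 0)
  ols <- fit_ols(d)
  expect_equal(unname(p0$coefficients$estimate),
               unname(ols$coefficients$estimate), tolerance = 1e-9)
})

test_that("fit_pgls equals the closed-form GLS solution at its own lambda", {
  for (s in 1:10) {
    n <- sample(8:14, 1)
    tr <- if (s %% 2) rand_tree(n, s) else rand_tree_nonultra(n, s)
    set.seed(100 + s)
    d <- tibble::tibble(species = tr$tip.label, mean_x = rnorm(n),
                        mean_y = rnorm(n))
    fit <- fit_pgls(d, tr)
    V <- apply_lambda(phylo_vcv(tr), fit$lambda)
    X <- cbind(1, d$mean_x[match(tr$tip.label, d$species)])
    y <- d$mean_y[match(tr$tip.label, d$species)]
    expect_equal(unname(fit$coefficients$estimate), gls_oracle(X, y, V),
                 tolerance = 1e-9)
  }
})

test_that("PGLS residuals are V(lambda)-orthogonal to the design", {
  tr <- rand_tree(30, 8, height = 1)
  y <- simulate_bm_trait(tr, 1, 0, seed = 2)
  x <- simulate_bm_trait(tr, 1, 0, seed = 3)
  d <- tibble::tibble(species = tr$tip.label, mean_x = unname(x),
                      mean_y = unname(y))
  fit <- fit_pgls(d, tr)
  V <- apply_lambda(phylo_vcv(tr), fit$lambda)
  X <- cbind(1, d$mean_x)
  g <- t(X) %*% solve(V, unname(fit$residuals[tr$tip.label]))
  expect_equal(as.numeric(g), c(0, 0), tolerance = 1e-7)
})

test_that("phylo_correlation at lambda 0 on an ultrametric tree is Pearson", {
  tr <- rand_tree(12, 5, height = 1)
  set.seed(9)
  d <- tibble::tibble(species = tr$tip.label, mean_x = rnorm(12),
                      mean_y = rnorm(12))
  expect_equal(phylo_correlation(d, tr, lambda = 0),
               cor(d$mean_x, d$mean_y), tolerance = 1e-9)
  r1 <- phylo_correlation(d, tr, lambda = 1)
  expect_true(abs(r1) <= 1)
})

test_that("fit_pgls profile lambda matches phytools phylosig on BM data", {
  tr <- rand_tree(60, 13, height = 1)
  y <- simulate_bm_trait(tr, 1, 0, seed = 21)
  sig <- pagel_lambda_signal(y, tree = tr)
  ps <- phytools::phylosig(tr, y, method = "lambda")
  # phylosig's lambda search allows values slightly above 1 and uses a coarser
  # optimizer, so agreement is close but not exact
  expect_equal(sig$lambda, ps$lambda, tolerance = 0.01)
  expect_equal(sig$logLik, ps$logL, tolerance = 0.02)
})

test_that("lambda signal is high for BM data and low after shuffling", {
  tr <- rand_tree(60, 14, height = 1)
  y <- simulate_bm_trait(tr, 1, 0, seed = 22)
  strong <- pagel_lambda_signal(y, tree = tr)
  expect_gt(strong$lambda, 0.8)
  expect_lt(strong$p_value, 0.01)
  set.seed(1)
  y_shuf <- setNames(sample(unname(y)), names(y))
  weak <- pagel_lambda_signal(y_shuf, tree = tr)
  expect_lt(weak$lambda, 0.4)
})

test_that("repeatability_icc matches the hand-worked balanced ANOVA", {
  d <- tibble::tibble(species = rep(c("a", "b", "c"), each = 2),
                      y = c(1, 2, 4, 5, 9, 10))
  r <- repeatability_icc(d, y)
  a <- anova(lm(y ~ species, data = d))
  ms_a <- a$`Mean Sq`[1]; ms_w <- a$`Mean Sq`[2]
  s2a <- (ms_a - ms_w) / 2
  expect_equal(r$n0, 2)
  expect_equal(r$R, s2a / (s2a + ms_w), tolerance = 1e-12)
  expect_equal(r$var_within, ms_w, tolerance = 1e-12)
})

test_that("repeatability_icc hits the boundaries and errors correctly", {
  perfect <- tibble::tibble(species = rep(c("a", "b"), each = 3),
                            y = rep(c(1, 5), each = 3))
  expect_equal(repeatability_icc(perfect, y)$R, 1)
  set.seed(2)
  none <- tibble::tibble(species = rep(paste0("s", 1:20), each = 5),
                         y = rnorm(100))
  # among-species variance indistinguishable from zero
  expect_lt(repeatability_icc(none, y)$R, 0.1)
  expect_error(repeatability_icc(tibble::tibble(species = "a", y = 1), y),
               "at least 2 groups")
  singles <- tibble::tibble(species = c("a", "b"), y = c(1, 2))
  expect_error(repeatability_icc(singles, y), "single observation")
})

test_that("repeatability_icc is consistent: equal variance components give 0.5", {
  set.seed(5)
  k <- 300
  d <- tibble::tibble(
    species = rep(paste0("s", 1:k), each = 4),
    y = rep(rnorm(k, 0, 1), each = 4) + rnorm(4 * k, 0, 1)
  )
  expect_equal(repeatability_icc(d, y)$R, 0.5, tolerance = 0.1)
})

test_that("attenuation_correct validates and computes", {
  expect_equal(attenuation_correct(0.85, 0.85), 1)
  expect_error(attenuation_correct(1, 0), "positive")
  expect_error(attenuation_correct(1, 1.2), "exceed 1")
})

test_that("Ives fit with zero sampling variance equals plain PGLS", {
  tr <- rand_tree(25, 17, height = 1)
  y <- simulate_bm_trait(tr, 1, 0, seed = 30)
  x <- simulate_bm_trait(tr, 1, 0, seed = 31)
  s <- tibble::tibble(species = tr$tip.label, n = 5L,
                      mean_x = unname(x), mean_y = unname(y),
                      var_x = 0, var_y = 0, var_imputed = FALSE)
  ives <- fit_pgls_ives(s, tr, nboot = 0)
  pgls <- fit_pgls(s, tr)
  expect_equal(unname(ives$coefficients$estimate[2]),
               unname(pgls$coefficients$estimate[2]), tolerance = 1e-4)
  expect_true(ives$converged)
})

test_that("mass_independent_residuals equal y minus the PGLS fit", {
  tr <- rand_tree(20, 19, height = 1)
  set.seed(40)
  s <- tibble::tibble(species = tr$tip.label, mean_x = rnorm(20),
                      mean_y = rnorm(20))
  res <- mass_independent_residuals(s, tr)
  fit <- fit_pgls(s, tr)
  expect_equal(setNames(res$residual, res$species), fit$residuals)
  expect_equal(sort(res$species), sort(s$species))
})

test_that("family_outlier_scan flags a planted deviant family", {
  tr <- simulate_yule_tree(40, tree_height = 237, seed = 3)
  study <- simulate_allometry_study(
    simulation_config(n_species = 40, seed = 3), tree = tr)
  s <- summarize_species(study$data)
  fams <- table(s$family)
  target <- names(fams)[fams >= 4][1]
  s$mean_y[s$family == target] <- s$mean_y[s$family == target] + 1.5
  scan <- family_outlier_scan(s, tr, nboot = 0)
  expect_true(target %in% scan$flagged)
  expect_true(all(c("family", "contrast", "p_value", "p_holm") %in%
                    names(scan$table)))
  expect_s3_class(scan$refit_ives, "gls_fit")
  expect_false(any(scan$refit_ives$species %in% s$species[s$family == target]))
})

test_that("loo_prediction reports sane accuracy and beats the mean on BM data", {
  tr <- rand_tree(30, 23, height = 1)
  x <- simulate_bm_trait(tr, 1, 0, seed = 50)
  y <- setNames(unname(x) + simulate_bm_trait(tr, 0.3, 0, seed = 51),
                names(x))
  s <- tibble::tibble(species = tr$tip.label, mean_x = unname(x),
                      mean_y = unname(y))
  loo <- loo_prediction(s, tr)
  expect_equal(nrow(loo), 30)
  expect_lte(attr(loo, "r2_loo"), 1)
  expect_gt(attr(loo, "r2_loo"), attr(loo, "r2_loo_mean"))
  expect_lt(attr(loo, "mae_loo"), attr(loo, "mae_loo_mean"))
})

test_that("grouped PGLS reports intercept and slope contrasts", {
  tr <- rand_tree(24, 29, height = 1)
  set.seed(60)
  s <- tibble::tibble(species = tr$tip.label, mean_x = rnorm(24),
                      mean_y = rnorm(24),
                      behaviour = rep(c("p", "f"), each = 12))
  fit <- fit_pgls(s, tr, grouping = "behaviour")
  expect_false(is.null(fit$contrasts))
  expect_setequal(fit$contrasts$contrast, c("intercept", "slope"))
  quad <- fit_pgls(s, tr, quadratic = TRUE)
  expect_true("x2" %in% quad$coefficients$term)
})
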