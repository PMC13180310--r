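test_that("causal_dag parses edges and validates acyclicity", {
  dag <- causal_dag(c("A -> B", "B -> C"))
  expect_setequal(dag$nodes, c("A", "B", "C"))
  expect_equal(nrow(dag$edges), 2)
  expect_error(causal_dag(c("A -> B", "B -> A")), "cyclic")
  expect_error(causal_dag("A - B"), "cannot parse")
  iso <- causal_dag("A -> B", nodes = c("A", "B", "Z"))
  expect_true("Z" %in% iso$nodes)
  expect_equal(allomacro:::topological_order(dag), c("A", "B", "C"))
})

test_that("basis_set enumerates one claim per non-adjacent pair", {
  chain <- causal_dag(c("A -> B", "B -> C"))
  bs <- basis_set(chain)
  expect_equal(nrow(bs), 1) # only the (A, C) pair is non-adjacent
  expect_equal(bs$predictor, "A")
  expect_equal(bs$response, "C")
  expect_equal(bs$conditioning[[1]], "B")

  complete <- causal_dag(c("A -> B", "A -> C", "B -> C"))
  expect_equal(nrow(basis_set(complete)), 0)

  collider <- causal_dag(c("A -> C", "B -> C"))
  bsc <- basis_set(collider)
  expect_equal(nrow(bsc), 1)
  # A and B are marginally independent; their parent sets are empty
  expect_equal(bsc$conditioning[[1]], character(0))

  diamond <- causal_dag(c("A -> B", "A -> C", "B -> D", "C -> D"))
  bsd <- basis_set(diamond)
  # pairs: (B, C) and (A, D) -> C(4,2) - 4 edges = 2 claims
  expect_equal(nrow(bsd), choose(4, 2) - 4)
})

test_that("fisher_c computes the chi-squared combination and guards inputs", {
  p <- c(0.2, 0.5, 0.9)
  fc <- fisher_c(p)
  expect_equal(fc$C, -2 * sum(log(p)))
  expect_equal(fc$df, 6)
  expect_equal(fc$p_value, pchisq(-2 * sum(log(p)), 6, lower.tail = FALSE))
  expect_error(fisher_c(c(0.5, 0)), "p-value of 0")
  expect_error(fisher_c(c(0.5, 1.2)), "in \\(0, 1\\]")
})

test_that("cicc computes the small-sample criterion and guards n", {
  expect_equal(cicc(4, 3, 50), 4 + 2 * 3 * 50 / (50 - 1 - 3))
  expect_error(cicc(4, 10, 11), "undefined")
})

test_that("d-sep tests accept a true chain and reject a false independence", {
  tr <- simulate_yule_tree(60, tree_height = 1, seed = 101)
  dag_true <- causal_dag(c("A -> B", "B -> C"))
  df <- simulate_dag_traits(tr, dag_true, c("A->B" = 1, "B->C" = 1),
                            c(A = 1, B = 0.5, C = 0.5), seed = 102)
  fit_true <- fit_path_model(dag_true, df, tr)
  expect_gt(fit_true$model_p, 0.05)
  expect_equal(fit_true$q, 2 + 3)
  expect_equal(fit_true$n, 60)
  # a model claiming B independent of C given A is contradicted by the data
  dag_false <- causal_dag(c("A -> B", "A -> C"))
  fit_false <- fit_path_model(dag_false, df, tr)
  expect_lt(fit_false$model_p, 0.01)
  expect_gt(fit_false$CICc, fit_true$CICc)
})

test_that("standardized path coefficients recover signs and magnitudes", {
  tr <- simulate_yule_tree(80, tree_height = 1, seed = 103)
  dag <- causal_dag(c("A -> B", "B -> C"))
  df <- simulate_dag_traits(tr, dag, c("A->B" = 1, "B->C" = -1),
                            c(A = 1, B = 0.3, C = 0.3), seed = 104)
  fit <- fit_path_model(dag, df, tr)
  cf <- fit$coefficients
  ab <- cf[cf$from == "A" & cf$to == "B", ]
  bc <- cf[cf$from == "B" & cf$to == "C", ]
  expect_gt(ab$coefficient, 0.5)
  expect_lt(bc$coefficient, -0.5)
  expect_true(all(cf$conf_low < cf$coefficient & cf$coefficient < cf$conf_high))
})

test_that("rank_and_average weights, supports and averages coherently", {
  tr <- simulate_yule_tree(60, tree_height = 1, seed = 105)
  gen <- causal_dag(c("A -> B", "B -> C"))
  df <- simulate_dag_traits(tr, gen, c("A->B" = 1, "B->C" = 1),
                            c(A = 1, B = 0.4, C = 0.4), seed = 106)
  models <- list(
    chain = causal_dag(c("A -> B", "B -> C")),
    fork = causal_dag(c("B -> A", "B -> C")),
    indep = causal_dag(c("A -> C"), nodes = c("A", "B", "C"))
  )
  res <- rank_and_average(models, df, tr)
  expect_s3_class(res, "path_model_set")
  expect_equal(sum(res$table$weight), 1, tolerance = 1e-12)
  expect_equal(res$table$delta_CICc[1], 0)
  expect_true(all(diff(res$table$CICc) >= 0))
  expect_true(all(res$table$delta_CICc[res$table$supported] <= 2))
  expect_true(res$table$model[1] %in% res$supported)
  # every averaged edge comes from a supported model and is a convex average
  for (i in seq_len(nrow(res$average))) {
    e <- res$average[i, ]
    vals <- vapply(res$supported, function(m) {
      cf <- res$fits[[m]]$coefficients
      hit <- cf$from == e$from & cf$to == e$to
      if (any(hit)) cf$coefficient[hit] else NA_real_
    }, numeric(1))
    vals <- vals[!is.na(vals)]
    expect_gte(e$coefficient, min(vals) - 1e-12)
    expect_lte(e$coefficient, max(vals) + 1e-12)
  }
})

test_that("a single candidate model averages to itself", {
  tr <- simulate_yule_tree(40, tree_height = 1, seed = 107)
  dag <- causal_dag(c("A -> B", "B -> C"))
  df <- simulate_dag_traits(tr, dag, c("A->B" = 1, "B->C" = 1),
                            c(A = 1, B = 0.5, C = 0.5), seed = 108)
  res <- rank_and_average(list(only = dag), df, tr)
  fit <- fit_path_model(dag, df, tr)
  expect_equal(res$average$coefficient, fit$coefficients$coefficient)
  expect_equal(res$table$weight, 1)
  expect_equal(res$supported, "only")
})

test_that("claim order does not depend on the order edges are written", {
  dag1 <- causal_dag(c("A -> B", "B -> C", "A -> D"))
  dag2 <- causal_dag(c("A -> D", "B -> C", "A -> B"))
  b1 <- basis_set(dag1)
  b2 <- basis_set(dag2)
  key <- function(b) paste(b$predictor, b$response,
                           vapply(b$conditioning, paste, "", collapse = ","))
  expect_setequal(key(b1), key(b2))
})

test_that("test_dsep_claims drops incomplete rows and reports n", {
  tr <- simulate_yule_tree(30, tree_height = 1, seed = 109)
  dag <- causal_dag(c("A -> B", "B -> C"))
  df <- simulate_dag_traits(tr, dag, c("A->B" = 1, "B->C" = 1),
                            c(A = 1, B = 0.5, C = 0.5), seed = 110)
  df$C[1:3] <- NA
  claims <- test_dsep_claims(dag, df, tr)
  expect_equal(attr(claims, "n"), 27)
  expect_error(test_dsep_claims(dag, df[, c("species", "A", "B")], tr),
               "missing trait columns")
})
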