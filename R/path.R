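#' Define a causal DAG over trait names
#'
#' @param edges Character vector of `"parent -> child"` strings, or a data
#'   frame with `from`/`to` columns.
#' @param nodes Optional node set (inferred from the edges otherwise); include
#'   isolated traits here.
#' @param id Optional model label.
#' @return A `causal_dag`.
#' @export
causal_dag <- function(edges, nodes = NULL, id = NULL) {
  if (is.character(edges)) {
    parts <- strsplit(gsub("\\s", "", edges), "->")
    bad <- lengths(parts) != 2
    if (any(bad)) abort(paste0("cannot parse edge: ", edges[bad][1]))
    edges <- tibble::tibble(from = vapply(parts, `[`, "", 1),
                            to = vapply(parts, `[`, "", 2))
  } else {
    edges <- tibble::as_tibble(edges)[, c("from", "to")]
  }
  nodes <- union(nodes %||% character(0), union(edges$from, edges$to))
  dag <- structure(list(nodes = nodes, edges = edges, id = id),
                   class = "causal_dag")
  topological_order(dag) # errors on cycles
  dag
}

# Kahn's algorithm; errors if the graph is cyclic.
topological_order <- function(dag) {
  nodes <- dag$nodes
  edges <- dag$edges
  indeg <- setNames(numeric(length(nodes)), nodes)
  for (v in edges$to) indeg[v] <- indeg[v] + 1
  out <- character(0)
  avail <- sort(names(indeg)[indeg == 0])
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    out <- c(out, v)
    ch <- edges$to[edges$from == v]
    for (w in ch) {
      indeg[w] <- indeg[w] - 1
      if (indeg[w] == 0) avail <- sort(c(avail, w))
    }
  }
  if (length(out) != length(nodes)) abort("graph is cyclic")
  out
}

dag_parents <- function(dag, v) dag$edges$from[dag$edges$to == v]

# is there a directed path from a to b?
dag_reaches <- function(dag, a, b) {
  frontier <- a
  seen <- character(0)
  while (length(frontier)) {
    v <- frontier[1]; frontier <- frontier[-1]
    if (v == b) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    frontier <- c(frontier, dag$edges$to[dag$edges$from == v])
  }
  FALSE
}

#' Basis set of d-separation claims implied by a DAG
#'
#' One conditional-independence claim per non-adjacent pair of nodes,
#' conditioning on the union of both nodes' parents. The regression response
#' is the non-ancestor of the pair (the later node in topological order when
#' neither is an ancestor of the other), so the tested coefficient is causally
#' interpretable.
#'
#' @param dag A [causal_dag()].
#' @return Tibble: `predictor`, `response`, `conditioning` (list column).
#' @export
basis_set <- function(dag) {
  ord <- topological_order(dag)
  nodes <- ord
  adj <- paste(dag$edges$from, dag$edges$to)
  claims <- list()
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (j <= i) next
      a <- nodes[i]; b <- nodes[j] # a precedes b in topological order
      if (paste(a, b) %in% adj || paste(b, a) %in% adj) next
      cond <- setdiff(union(dag_parents(dag, a), dag_parents(dag, b)), c(a, b))
      claims[[length(claims) + 1]] <- tibble::tibble(
        predictor = a, response = b, conditioning = list(sort(cond))
      )
    }
  }
  if (!length(claims)) {
    return(tibble::tibble(predictor = character(0), response = character(0),
                          conditioning = list()))
  }
  dplyr::bind_rows(claims)
}

#' Test a DAG's d-separation claims by PGLS
#'
#' Each independence claim is tested as the p-value of the predictor's
#' coefficient in a profile-lambda PGLS of the response on the conditioning
#' set plus the predictor.
#'
#' @param dag A [causal_dag()].
#' @param data Species-level trait table (`species` column plus one column per
#'   DAG node). Rows with missing values in the DAG's traits are dropped
#'   listwise.
#' @param tree A `phylo` object.
#' @return The basis-set tibble with a `p_value` column (and `n` attribute).
#' @export
test_dsep_claims <- function(dag, data, tree) {
  miss <- setdiff(dag$nodes, names(data))
  if (length(miss)) abort(paste0("missing trait columns: ", paste(miss, collapse = ", ")))
  df <- data[complete.cases(data[, dag$nodes, drop = FALSE]), ]
  al <- align_summary_tree(df, tree)
  df <- al$summary; tree <- al$tree
  V <- phylo_vcv(tree)
  claims <- basis_set(dag)
  if (!nrow(claims)) {
    attr(claims, "n") <- nrow(df)
    claims$p_value <- numeric(0)
    return(claims)
  }
  claims$p_value <- vapply(seq_len(nrow(claims)), function(i) {
    cond <- claims$conditioning[[i]]
    X <- cbind(1, as.matrix(df[, c(cond, claims$predictor[i]), drop = FALSE]))
    fit <- gls_profile_fit(X, df[[claims$response[i]]], V, "lambda")
    j <- ncol(X)
    tstat <- fit$beta[j] / fit$se[j]
    2 * pt(-abs(tstat), df = fit$n - fit$p)
  }, numeric(1))
  attr(claims, "n") <- nrow(df)
  claims
}

#' Fisher's C statistic
#'
#' `C = -2 sum(log p)` over the independence-claim p-values; under the causal
#' model C is chi-squared with `2 * length(p)` degrees of freedom.
#'
#' @param p_values Claim p-values in `(0, 1]`.
#' @return Tibble: `C`, `df`, `p_value`.
#' @export
fisher_c <- function(p_values) {
  if (any(p_values <= 0)) {
    abort("a claim p-value of 0 indicates a perfect violation; inspect the claim")
  }
  if (any(p_values > 1)) abort("p-values must lie in (0, 1]")
  C <- -2 * sum(log(p_values))
  df <- 2 * length(p_values)
  tibble::tibble(C = C, df = df,
                 p_value = pchisq(C, df, lower.tail = FALSE))
}

#' Small-sample C-statistic information criterion
#'
#' `CICc = C + 2 q n / (n - 1 - q)` with `q` the parameter count of the path
#' model (edges plus nodes).
#'
#' @param C Fisher's C.
#' @param q Parameter count.
#' @param n Sample size (species).
#' @return CICc (numeric).
#' @export
cicc <- function(C, q, n) {
  if (n <= q + 1) abort("CICc undefined: n <= q + 1")
  C + 2 * q * n / (n - 1 - q)
}

# standardized path coefficients: z-score traits by their raw SD, then PGLS
# of each child on its parents
path_coefficients <- function(dag, df, V) {
  zs <- df
  for (v in dag$nodes) zs[[v]] <- (df[[v]] - mean(df[[v]])) / sd(df[[v]])
  out <- list()
  for (v in unique(dag$edges$to)) {
    pa <- dag_parents(dag, v)
    X <- cbind(1, as.matrix(zs[, pa, drop = FALSE]))
    fit <- gls_profile_fit(X, zs[[v]], V, "lambda")
    for (j in seq_along(pa)) {
      out[[length(out) + 1]] <- tibble::tibble(
        from = pa[j], to = v,
        coefficient = fit$beta[j + 1], std_error = fit$se[j + 1],
        conf_low = fit$beta[j + 1] - 1.96 * fit$se[j + 1],
        conf_high = fit$beta[j + 1] + 1.96 * fit$se[j + 1]
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Fit one phylogenetic path model
#'
#' d-separation tests, Fisher's C, CICc and standardized path coefficients
#' for a single candidate DAG.
#'
#' @inheritParams test_dsep_claims
#' @return A `path_model_fit`.
#' @export
fit_path_model <- function(dag, data, tree) {
  claims <- test_dsep_claims(dag, data, tree)
  n <- attr(claims, "n")
  fc <- if (nrow(claims)) fisher_c(claims$p_value) else
    tibble::tibble(C = 0, df = 0, p_value = 1)
  q <- nrow(dag$edges) + length(dag$nodes)
  df2 <- data[complete.cases(data[, dag$nodes, drop = FALSE]), ]
  al <- align_summary_tree(df2, tree)
  coefs <- path_coefficients(dag, al$summary, phylo_vcv(al$tree))
  structure(list(
    dag = dag, claims = claims, C = fc$C, df = fc$df, model_p = fc$p_value,
    q = q, n = n, CICc = cicc(fc$C, q, n), coefficients = coefs,
    id = dag$id
  ), class = "path_model_fit")
}

#' Rank candidate path models and average the supported set
#'
#' Fits every candidate DAG, ranks them by CICc, computes CICc weights, and
#' conditionally averages the standardized coefficients over the supported
#' models (`delta CICc <= cutoff`, inclusive): for each edge, the average is
#' taken over the supported models containing that edge with their weights
#' renormalised, and the CI bounds are averaged with the same weights.
#' Opposite arrow directions are reported as two directed coefficients.
#'
#' @param models Named list of [causal_dag()]s (all over the same traits).
#' @param data Species-level trait table.
#' @param tree A `phylo` object.
#' @param cutoff Support threshold on delta CICc (default 2, inclusive).
#' @return A `path_model_set`: `table` (ranked tibble), `fits`, `supported`,
#'   `average` (tibble of averaged edges).
#' @export
rank_and_average <- function(models, data, tree, cutoff = 2) {
  if (length(models) < 2) {
    if (length(models) == 1) {
      fit <- fit_path_model(models[[1]], data, tree)
      avg <- fit$coefficients
      avg$weight_sum <- 1
      tab <- tibble::tibble(model = names(models) %||% "m1", C = fit$C,
                            q = fit$q, n = fit$n, model_p = fit$model_p,
                            CICc = fit$CICc, delta_CICc = 0, weight = 1,
                            supported = TRUE)
      return(structure(list(table = tab, fits = setNames(list(fit), tab$model),
                            supported = tab$model, average = avg),
                       class = "path_model_set"))
    }
    abort("supply at least one model")
  }
  if (is.null(names(models))) names(models) <- paste0("m", seq_along(models))
  fits <- lapply(models, fit_path_model, data = data, tree = tree)
  ns <- unique(vapply(fits, `[[`, numeric(1), "n"))
  if (length(ns) != 1) abort("models evaluated on different species sets")
  tab <- tibble::tibble(
    model = names(models),
    C = unname(vapply(fits, `[[`, numeric(1), "C")),
    q = unname(vapply(fits, `[[`, numeric(1), "q")),
    n = ns,
    model_p = unname(vapply(fits, `[[`, numeric(1), "model_p")),
    CICc = unname(vapply(fits, `[[`, numeric(1), "CICc"))
  )
  tab$delta_CICc <- tab$CICc - min(tab$CICc)
  w <- exp(-0.5 * tab$delta_CICc)
  tab$weight <- w / sum(w)
  tab$supported <- tab$delta_CICc <= cutoff
  tab <- dplyr::arrange(tab, .data$CICc)
  supported <- tab$model[tab$supported]
  edges <- dplyr::bind_rows(lapply(supported, function(m) {
    cf <- fits[[m]]$coefficients
    cf$model <- m
    cf$weight <- tab$weight[tab$model == m]
    cf
  }))
  average <- edges |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(
      coefficient = sum(.data$coefficient * .data$weight) / sum(.data$weight),
      conf_low = sum(.data$conf_low * .data$weight) / sum(.data$weight),
      conf_high = sum(.data$conf_high * .data$weight) / sum(.data$weight),
      weight_sum = sum(.data$weight),
      n_models = dplyr::n(),
      .groups = "drop"
    )
  structure(list(table = tab, fits = fits, supported = supported,
                 average = average),
            class = "path_model_set")
}
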