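# trait input: named numeric vector, or a two-column data frame (species, value)
as_trait_vector <- function(trait, tree) {
  if (is.data.frame(trait)) {
    stopifnot("species" %in% names(trait))
    vcol <- setdiff(names(trait), "species")[1]
    trait <- setNames(as.numeric(trait[[vcol]]), as.character(trait$species))
  }
  if (is.null(names(trait))) abort("trait must be named by species")
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing)) {
    abort(paste0("trait missing for tips: ", paste(missing, collapse = ", ")))
  }
  trait[tree$tip.label]
}

#' Brownian-motion fit (single- or multi-rate)
#'
#' Maximum-likelihood BM fit of a continuous trait. With a regime painting the
#' diffusion rate differs among regimes (branch-length scaling): the trait
#' covariance is `sum_r sigma2_r V_r` with `V_r` the shared path time spent in
#' regime r. The root state is profiled analytically (GLS mean); the overall
#' scale is profiled too, so only rate ratios are optimised numerically.
#'
#' @param trait Named numeric vector (or `species`/value data frame).
#' @param tree A `phylo` object.
#' @param painting Optional `regime_painting` for a multi-rate fit.
#' @return A `bm_fit`: `sigma2` (named per regime), `root`, `logLik`, `AICc`,
#'   `k`, `n`.
#' @export
fit_bm <- function(trait, tree, painting = NULL) {
  tree <- validate_tree(tree)
  y <- as_trait_vector(trait, tree)
  n <- length(y)
  if (is.null(painting)) {
    V <- phylo_vcv(tree)
    L <- chol(V)
    ys <- backsolve(L, y, transpose = TRUE)
    os <- backsolve(L, rep(1, n), transpose = TRUE)
    root <- sum(os * ys) / sum(os^2)
    r <- ys - root * os
    s2 <- sum(r^2) / n
    lnl <- -0.5 * n * (log(2 * pi * s2) + 1) - sum(log(diag(L)))
    k <- 2
    fit <- list(sigma2 = c(base = s2), root = root, logLik = lnl)
  } else {
    Vr <- regime_vcv(tree, painting)
    regimes <- names(Vr)
    tot <- vapply(Vr, function(v) sum(diag(v)), numeric(1))
    if (any(tot <= 0)) {
      abort(paste0("regime(s) with zero branch-time coverage: ",
                   paste(regimes[tot <= 0], collapse = ", ")))
    }
    R <- length(regimes)
    prof <- function(logc) {
      cvec <- c(1, exp(logc))
      C <- Reduce(`+`, Map(`*`, Vr, cvec))
      L <- tryCatch(chol(C), error = function(e) NULL)
      if (is.null(L)) return(list(nll = 1e10))
      ys <- backsolve(L, y, transpose = TRUE)
      os <- backsolve(L, rep(1, n), transpose = TRUE)
      root <- sum(os * ys) / sum(os^2)
      s <- sum((ys - root * os)^2) / n
      lnl <- -0.5 * n * (log(2 * pi * s) + 1) - sum(log(diag(L)))
      list(nll = -lnl, s = s, root = root)
    }
    if (R == 1) {
      opt <- list(par = numeric(0))
    } else {
      opt <- optim(rep(0, R - 1), function(p) prof(p)$nll,
                   method = if (R == 2) "Brent" else "Nelder-Mead",
                   lower = if (R == 2) -15 else -Inf,
                   upper = if (R == 2) 15 else Inf)
    }
    best <- prof(opt$par)
    cvec <- c(1, exp(opt$par))
    sigma2 <- setNames(best$s * cvec, regimes)
    k <- R + 1
    fit <- list(sigma2 = sigma2, root = best$root, logLik = -best$nll)
  }
  structure(c(fit, list(k = k, n = n, AICc = aicc(fit$logLik, k, n),
                        model = if (is.null(painting)) "BM" else "mrBM",
                        data_id = unname(sum(y)))),
            class = "bm_fit")
}

#' Multi-optimum Ornstein-Uhlenbeck fit (Hansen model)
#'
#' ML fit of an OU process with a common pull `alpha` and diffusion `sigma2`
#' and one optimum per regime of a painting. Expected tip values are the
#' exponentially decaying regime-history weights of each lineage (computed
#' segment-exactly, so mid-edge transitions from stochastic maps are honoured);
#' the tip covariance under a stationary root is
#' `sigma2/(2 alpha) * exp(-alpha * d_ij)` with `d_ij` the patristic distance,
#' and under a fixed root the non-stationary analogue. The optima and the
#' scale are profiled analytically, leaving a one-dimensional search over
#' `log(alpha)`.
#'
#' @param trait Named numeric vector (or `species`/value data frame).
#' @param tree A `phylo` object (resolved to binary if needed).
#' @param painting Optional `regime_painting` (single regime if absent).
#' @param root `"stationary"` (root drawn from the root regime's stationary
#'   distribution; the default for ultrametric trees) or `"fixed"` (root value
#'   clamped at the root regime's optimum; this is the parameterisation whose
#'   `alpha -> 0` limit is BM).
#' @param alpha_bounds Search interval for `alpha` (per MY).
#' @return An `ou_fit`: `alpha`, `sigma2`, `theta` (named, with SEs),
#'   `half_life`, `stationary_variance`, `logLik`, `AICc`.
#' @export
fit_ou <- function(trait, tree, painting = NULL,
                   root = c("stationary", "fixed"),
                   alpha_bounds = c(1e-8, 1)) {
  root <- match.arg(root)
  tree <- validate_tree(tree)
  if (!ape::is.binary(tree)) tree <- resolve_binary(tree)
  y <- as_trait_vector(trait, tree)
  n <- length(y)
  if (is.null(painting)) painting <- painting_single(tree)
  regimes <- attr(painting, "regimes")
  D <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
  depths <- node_depths(tree)[seq_len(n)]
  S <- outer(depths, depths, `+`)
  seqs <- tip_regime_sequences(tree, painting)
  prof <- function(log_alpha) {
    a <- exp(log_alpha)
    Rm <- if (root == "stationary") exp(-a * D) else exp(-a * D) - exp(-a * S)
    W <- ou_weight_matrix(tree, painting, a, seqs = seqs)
    L <- tryCatch(chol(Rm), error = function(e) NULL)
    if (is.null(L)) return(list(nll = 1e10))
    Ws <- backsolve(L, W, transpose = TRUE)
    ys <- backsolve(L, y, transpose = TRUE)
    XtX <- crossprod(Ws)
    theta <- tryCatch(drop(solve(XtX, crossprod(Ws, ys))),
                      error = function(e) NULL)
    if (is.null(theta)) return(list(nll = 1e10))
    r <- ys - Ws %*% theta
    s <- sum(r^2) / n
    lnl <- -0.5 * n * (log(2 * pi * s) + 1) - sum(log(diag(L)))
    list(nll = -lnl, s = s, theta = theta, XtX = XtX)
  }
  lb <- log(alpha_bounds[1]); ub <- log(alpha_bounds[2])
  opt <- optimize(function(p) prof(p)$nll, c(lb, ub), tol = 1e-8)
  # guard against boundary optima the interior search can miss
  cand <- c(opt$minimum, lb, ub)
  nlls <- vapply(cand, function(p) prof(p)$nll, numeric(1))
  la <- cand[which.min(nlls)]
  best <- prof(la)
  if (best$nll >= 1e10) abort("OU likelihood failed at the optimum; check the tree and trait")
  a <- exp(la)
  s <- best$s
  sigma2 <- 2 * a * s
  theta <- setNames(as.numeric(best$theta), regimes)
  theta_se <- sqrt(diag(s * solve(best$XtX)))
  structure(list(
    alpha = a, sigma2 = sigma2,
    theta = theta, theta_se = setNames(theta_se, regimes),
    theta_se_approximate = a <= alpha_bounds[1] * (1 + 1e-6),
    half_life = half_life(a), stationary_variance = sigma2 / (2 * a),
    root = root, logLik = -best$nll,
    k = 2 + length(regimes), n = n,
    AICc = aicc(-best$nll, 2 + length(regimes), n),
    model = if (length(regimes) > 1) "moOU" else "OU",
    data_id = unname(sum(y))
  ), class = "ou_fit")
}

#' OU log-likelihood for fixed parameters
#'
#' The exact Gaussian log-likelihood of a multi-optimum OU model at supplied
#' parameter values under a fixed regime painting. Used by the reversible-jump
#' sampler and convenient for cross-checking.
#'
#' @inheritParams fit_ou
#' @param alpha,sigma2 OU parameters (per MY).
#' @param theta Named vector of optima (one per painting regime).
#' @return Log-likelihood (numeric scalar).
#' @export
ou_loglik <- function(trait, tree, painting, alpha, sigma2, theta,
                      root = c("stationary", "fixed")) {
  root <- match.arg(root)
  tree <- validate_tree(tree)
  y <- as_trait_vector(trait, tree)
  n <- length(y)
  D <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
  depths <- node_depths(tree)[seq_len(n)]
  Rm <- if (root == "stationary") exp(-alpha * D) else
    exp(-alpha * D) - exp(-alpha * outer(depths, depths, `+`))
  C <- sigma2 / (2 * alpha) * Rm
  W <- ou_weight_matrix(tree, painting, alpha)
  mu <- drop(W %*% theta[attr(painting, "regimes")])
  L <- chol(C)
  r <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(r^2)
}

#' Phylogenetic half-life
#'
#' Time for a lineage to evolve halfway towards a new optimum: `ln(2) / alpha`.
#'
#' @param alpha OU pull strength (per MY).
#' @return Half-life in MY (`Inf`, with a warning, when `alpha <= 0`).
#' @export
half_life <- function(alpha) {
  if (alpha <= 0) {
    warn("alpha <= 0: half-life is infinite (no pull towards the optimum)")
    return(Inf)
  }
  log(2) / alpha
}

#' Compare macroevolutionary model fits by AICc
#'
#' @param ... Fitted `bm_fit` / `ou_fit` objects (or a single list of them),
#'   all fitted to the same data.
#' @param names Optional model names.
#' @return A `model_table` tibble: model, k, logLik, AICc, delta_AICc, weight.
#' @export
compare_models <- function(..., names = NULL) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], c("bm_fit", "ou_fit"))) {
    fits <- fits[[1]]
  }
  n <- unique(vapply(fits, function(f) f$n, numeric(1)))
  ids <- unique(vapply(fits, function(f) f$data_id %||% NA_real_, numeric(1)))
  if (length(n) != 1 || length(ids) != 1) abort("all fits must be on identical data")
  nm <- names %||% base::names(fits) %||%
    vapply(fits, function(f) f$model, character(1))
  if (is.null(nm) || any(nm == "")) nm <- vapply(fits, function(f) f$model, character(1))
  tab <- tibble::tibble(
    model = nm,
    k = vapply(fits, function(f) as.numeric(f$k), numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1))
  )
  if (any(n <= tab$k + 1)) abort("AICc undefined: n <= k + 1 for some model")
  tab$AICc <- -2 * tab$logLik + 2 * tab$k + 2 * tab$k * (tab$k + 1) / (n - tab$k - 1)
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  w <- exp(-0.5 * tab$delta_AICc)
  tab$weight <- w / sum(w)
  tab <- dplyr::arrange(tab, .data$AICc)
  structure(tab, class = c("model_table", class(tab)))
}

#' Ancestral states of a continuous trait under Brownian motion
#'
#' GLS (universal-kriging) ancestral estimates: the conditional mean of each
#' internal node given the tips, with the BM rate and root estimated by ML;
#' variances include the uncertainty of the estimated root mean. These equal
#' the re-rooted GLS root estimates node by node.
#'
#' @param trait Named numeric vector (or `species`/value data frame).
#' @param tree A `phylo` object.
#' @return Tibble with `node` (ape node number), `estimate`, `var`.
#' @export
ancestral_continuous <- function(trait, tree) {
  tree <- validate_tree(tree)
  y <- as_trait_vector(trait, tree)
  n <- length(y)
  fit <- fit_bm(y, tree)
  V <- phylo_vcv(tree)
  Vi <- chol2inv(chol(V))
  one <- rep(1, n)
  denom <- sum(Vi %*% one)
  depths <- node_depths(tree)
  M <- ape::mrca(tree, full = TRUE)
  nodes <- (n + 1L):(n + tree$Nnode)
  resid <- y - fit$root
  est <- vars <- numeric(length(nodes))
  for (j in seq_along(nodes)) {
    nd <- nodes[j]
    cj <- depths[M[nd, seq_len(n)]]
    wj <- drop(Vi %*% cj)
    est[j] <- fit$root + sum(wj * resid)
    vars[j] <- fit$sigma2[[1]] *
      (depths[nd] - sum(wj * cj) + (1 - sum(wj))^2 / denom)
  }
  tibble::tibble(node = nodes, estimate = est, var = pmax(vars, 0))
}
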