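#' Summarize an individual-level trait table to species means
#'
#' Computes per-species means and sampling variances of the means
#' (`s^2 / n`) for log10 body mass and log10 metabolic rate, carrying along
#' any grouping columns (suborder, family, behaviour). Species measured once
#' cannot supply a within-species variance; their variance is imputed as the
#' pooled within-species variance across species with `n >= 2` and flagged.
#'
#' @param data Individual-level data frame.
#' @param x,y Columns holding body mass and metabolic rate (tidy-eval).
#' @param species Species column.
#' @param log10_transform Apply `log10()` to `x` and `y` (use `FALSE` when the
#'   table is already on the log scale).
#' @param groups Character vector of grouping columns to carry through (those
#'   present are kept automatically by default).
#' @return A `species_summary` tibble with columns `species`, `n`, `mean_x`,
#'   `mean_y`, `var_x`, `var_y`, `var_imputed` and any group columns.
#' @export
summarize_species <- function(data, x = body_mass_g, y = smr,
                              species = species, log10_transform = TRUE,
                              groups = c("suborder", "family", "behaviour")) {
  xq <- rlang::enquo(x); yq <- rlang::enquo(y); sq <- rlang::enquo(species)
  df <- dplyr::transmute(data,
    species = as.character(!!sq),
    .x = as.numeric(!!xq),
    .y = as.numeric(!!yq)
  )
  if (log10_transform) {
    bad <- which(df$.x <= 0 | df$.y <= 0 | is.na(df$.x) | is.na(df$.y))
    if (length(bad)) {
      abort(paste0("nonpositive or missing raw values in rows: ",
                   paste(head(bad, 10), collapse = ", ")))
    }
    df$.x <- log10(df$.x); df$.y <- log10(df$.y)
  }
  out <- df |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_x = mean(.data$.x), mean_y = mean(.data$.y),
      s2_x = ifelse(dplyr::n() > 1, var(.data$.x), NA_real_),
      s2_y = ifelse(dplyr::n() > 1, var(.data$.y), NA_real_),
      .groups = "drop"
    )
  pooled <- function(s2, n) {
    ok <- !is.na(s2)
    if (!any(ok)) return(0)
    sum(s2[ok] * (n[ok] - 1)) / sum(n[ok] - 1)
  }
  p_x <- pooled(out$s2_x, out$n); p_y <- pooled(out$s2_y, out$n)
  out$var_imputed <- is.na(out$s2_x)
  out$var_x <- ifelse(is.na(out$s2_x), p_x, out$s2_x) / out$n
  out$var_y <- ifelse(is.na(out$s2_y), p_y, out$s2_y) / out$n
  out$s2_x <- out$s2_y <- NULL
  keep <- intersect(groups, names(data))
  if (length(keep)) {
    g <- dplyr::select(data, species = !!sq, dplyr::all_of(keep))
    g$species <- as.character(g$species)
    g <- dplyr::slice(dplyr::group_by(g, .data$species), 1) |> dplyr::ungroup()
    out <- dplyr::left_join(out, g, by = "species")
  }
  class(out) <- c("species_summary", class(out))
  out
}

# ---- GLS engine --------------------------------------------------------------

# Profile-lambda ML generalized least squares. Uses an eigendecomposition fast
# path when the covariance has constant diagonal (ultrametric tree), so the
# lambda profile costs O(n p) per evaluation after one O(n^3) factorisation.
gls_profile_fit <- function(X, y, V, transform = c("lambda", "none"),
                            lambda = NULL) {
  transform <- match.arg(transform)
  n <- length(y); p <- ncol(X)
  d <- diag(V)
  h <- d[1]
  fast <- max(abs(d - h)) <= 1e-8 * h
  if (fast) {
    E <- eigen(V, symmetric = TRUE)
    Xr <- crossprod(E$vectors, X); yr <- drop(crossprod(E$vectors, y))
    ev <- E$values
    eval_lnl <- function(lam) {
      w <- lam * (ev - h) + h
      w <- pmax(w, 1e-12)
      sw <- 1 / w
      XtWX <- crossprod(Xr, Xr * sw)
      XtWy <- crossprod(Xr, yr * sw)
      beta <- solve(XtWX, XtWy)
      r <- yr - Xr %*% beta
      rss <- sum(r^2 * sw)
      s2 <- rss / n
      list(lnl = -0.5 * n * (log(2 * pi * s2) + 1) - 0.5 * sum(log(w)),
           beta = drop(beta), s2 = s2, XtWX = XtWX)
    }
  } else {
    eval_lnl <- function(lam) {
      Vl <- lam * V; diag(Vl) <- d
      L <- chol(Vl)
      Xs <- backsolve(L, X, transpose = TRUE)
      ys <- backsolve(L, y, transpose = TRUE)
      XtWX <- crossprod(Xs)
      beta <- solve(XtWX, crossprod(Xs, ys))
      r <- ys - Xs %*% beta
      s2 <- sum(r^2) / n
      list(lnl = -0.5 * n * (log(2 * pi * s2) + 1) - sum(log(diag(L))),
           beta = drop(beta), s2 = s2, XtWX = XtWX)
    }
  }
  if (transform == "none") {
    lam_hat <- 1
  } else if (!is.null(lambda)) {
    lam_hat <- lambda
  } else {
    opt <- optimize(function(l) eval_lnl(l)$lnl, c(0, 1), maximum = TRUE,
                    tol = 1e-7)
    lam_hat <- opt$maximum
    # the interior optimum can be dominated by a boundary
    for (b in c(0, 1)) if (eval_lnl(b)$lnl > eval_lnl(lam_hat)$lnl) lam_hat <- b
  }
  fit <- eval_lnl(lam_hat)
  sigma2_u <- fit$s2 * n / max(n - p, 1)
  covb <- sigma2_u * solve(fit$XtWX)
  fitted <- drop(X %*% fit$beta)
  list(beta = fit$beta, se = sqrt(diag(covb)), cov_beta = covb,
       lambda = lam_hat, sigma2 = fit$s2, logLik = fit$lnl,
       fitted = fitted, residuals = y - fitted, n = n, p = p,
       eval_lnl = eval_lnl)
}

aicc <- function(lnl, k, n) {
  if (n <= k + 1) abort("AICc undefined: n <= k + 1")
  -2 * lnl + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

new_gls_fit <- function(method, coefs, extra = list()) {
  structure(c(list(method = method, coefficients = coefs), extra),
            class = "gls_fit")
}

coef_table <- function(terms, beta, se, df) {
  tstat <- beta / se
  tibble::tibble(
    term = terms, estimate = beta, std_error = se,
    conf_low = beta - 1.96 * se, conf_high = beta + 1.96 * se,
    statistic = tstat, p_value = 2 * pt(-abs(tstat), df)
  )
}

# Align a species summary with a tree: prune the tree to the summary species,
# error on species absent from the tree, and order rows in tip order.
align_summary_tree <- function(summary, tree) {
  tree <- validate_tree(tree)
  missing <- setdiff(summary$species, tree$tip.label)
  if (length(missing)) {
    abort(paste0("species not in tree: ", paste(missing, collapse = ", ")))
  }
  drop <- setdiff(tree$tip.label, summary$species)
  if (length(drop)) tree <- validate_tree(ape::drop.tip(tree, drop))
  summary <- summary[match(tree$tip.label, summary$species), ]
  list(summary = summary, tree = tree)
}

build_design <- function(summary, quadratic = FALSE, grouping = NULL) {
  x <- summary$mean_x
  X <- cbind(`(Intercept)` = 1, x = x)
  if (quadratic) X <- cbind(X, x2 = (x - mean(x))^2)
  group_terms <- NULL
  if (!is.null(grouping)) {
    g <- factor(summary[[grouping]])
    if (nlevels(g) < 2) abort("grouping must have at least two levels")
    if (min(table(g)) < 2) {
      abort(paste0("grouping '", grouping, "' has a level with a single ",
                   "species; its intercept and slope offsets are not ",
                   "separately identifiable"))
    }
    mm <- stats::model.matrix(~g)[, -1, drop = FALSE]
    colnames(mm) <- paste0(grouping, levels(g)[-1])
    inter <- mm * x
    colnames(inter) <- paste0("x:", colnames(mm))
    X <- cbind(X, mm, inter)
    group_terms <- list(intercept = colnames(mm), slope = colnames(inter))
  }
  list(X = X, group_terms = group_terms)
}

#' Ordinary least squares allometry fit
#'
#' Simple OLS of species-mean log10 metabolic rate on species-mean log10 body
#' mass, reported in the same container as the phylogenetic fits.
#'
#' @param data Data frame of species means (e.g., a [summarize_species()]
#'   result).
#' @param x,y Columns (tidy-eval), default `mean_x` / `mean_y`.
#' @return A `gls_fit` with coefficients, Pearson correlation `r`, `logLik`
#'   and `AICc`.
#' @export
fit_ols <- function(data, x = mean_x, y = mean_y) {
  xv <- as.numeric(dplyr::pull(data, {{ x }}))
  yv <- as.numeric(dplyr::pull(data, {{ y }}))
  if (length(xv) < 3) abort("need at least 3 points")
  if (var(xv) == 0) abort("zero variance in x")
  m <- lm(yv ~ xv)
  sm <- summary(m)
  n <- length(xv)
  beta <- coef(m); se <- sm$coefficients[, 2]
  lnl <- as.numeric(stats::logLik(m))
  new_gls_fit("ols",
    coef_table(c("(Intercept)", "x"), beta, se, df = n - 2),
    list(r = cor(xv, yv), lambda = NA_real_,
         sigma2 = sum(m$residuals^2) / n,
         logLik = lnl, AICc = aicc(lnl, 3, n), n = n, k = 3,
         residuals = setNames(m$residuals,
                              if (!is.null(data$species)) data$species else NULL),
         fitted = unname(m$fitted.values),
         data = tibble::tibble(species = data$species %||% NA_character_,
                               x = xv, y = yv))
  )
}

#' Phylogenetic generalized least squares allometry fit
#'
#' GLS with error covariance `sigma2 * V(lambda)`, where `V` is the
#' phylogenetic covariance of the (pruned) tree and Pagel's lambda multiplies
#' its off-diagonal entries. Lambda is estimated by maximum likelihood on
#' `[0, 1]` (or fixed). A quadratic term (mean-centred `x^2`) probes
#' curvilinear allometry; a grouping factor adds intercept and slope contrasts
#' (phylogenetic ANCOVA with interaction).
#'
#' @param summary A `species_summary` (or tibble with `species`, `mean_x`,
#'   `mean_y`).
#' @param tree A `phylo` object covering the summary's species.
#' @param transform `"lambda"` (profile ML) or `"none"` (lambda fixed at 1).
#' @param quadratic Add a mean-centred quadratic mass term.
#' @param grouping Optional name of a factor column in `summary`; main effect
#'   plus interaction are added and their contrasts reported.
#' @param lambda Optional fixed lambda (overrides profiling).
#' @return A `gls_fit`; when `grouping` is supplied, `$contrasts` holds the
#'   intercept- and slope-difference T tests.
#' @export
fit_pgls <- function(summary, tree, transform = c("lambda", "none"),
                     quadratic = FALSE, grouping = NULL, lambda = NULL) {
  transform <- match.arg(transform)
  al <- align_summary_tree(summary, tree)
  summary <- al$summary; tree <- al$tree
  des <- build_design(summary, quadratic, grouping)
  V <- phylo_vcv(tree)
  fit <- gls_profile_fit(des$X, summary$mean_y, V, transform, lambda)
  df <- fit$n - fit$p
  coefs <- coef_table(colnames(des$X), fit$beta, fit$se, df)
  k <- fit$p + 1 + as.integer(transform == "lambda" && is.null(lambda))
  contrasts <- NULL
  if (!is.null(des$group_terms)) {
    rows <- coefs[coefs$term %in% unlist(des$group_terms), ]
    rows$contrast <- ifelse(rows$term %in% des$group_terms$slope,
                            "slope", "intercept")
    contrasts <- rows[, c("contrast", "term", "estimate", "std_error",
                          "statistic", "p_value")]
  }
  # phylogenetically corrected correlation at the fitted lambda (simple model)
  r <- if (is.null(grouping) && !quadratic) {
    phylo_correlation(summary, tree, lambda = fit$lambda)
  } else NA_real_
  new_gls_fit("pgls",
    coefs,
    list(lambda = fit$lambda, sigma2 = fit$sigma2, logLik = fit$logLik,
         AICc = aicc(fit$logLik, k, fit$n), n = fit$n, k = k,
         residuals = setNames(fit$residuals, summary$species),
         fitted = fit$fitted, contrasts = contrasts,
         transform = transform, quadratic = quadratic, grouping = grouping,
         species = summary$species, r = r,
         data = tibble::tibble(species = summary$species, x = summary$mean_x,
                               y = summary$mean_y))
  )
}

#' Phylogenetically corrected correlation coefficient
#'
#' Correlation of two traits after whitening by the phylogenetic covariance
#' and centring at the GLS mean:
#' `r = x~' V^-1 y~ / sqrt((x~' V^-1 x~)(y~' V^-1 y~))`.
#'
#' @param summary Species summary (or tibble with `species` and the two trait
#'   columns).
#' @param tree A `phylo` object.
#' @param x,y Trait columns (tidy-eval), default `mean_x` / `mean_y`.
#' @param lambda Pagel's lambda applied to `V` before whitening (default 1).
#' @return The correlation (numeric scalar).
#' @export
phylo_correlation <- function(summary, tree, x = mean_x, y = mean_y,
                              lambda = 1) {
  al <- align_summary_tree(summary, tree)
  xv <- as.numeric(dplyr::pull(al$summary, {{ x }}))
  yv <- as.numeric(dplyr::pull(al$summary, {{ y }}))
  V <- apply_lambda(phylo_vcv(al$tree), lambda)
  L <- chol(V)
  one <- backsolve(L, rep(1, length(xv)), transpose = TRUE)
  xs <- backsolve(L, xv, transpose = TRUE)
  ys <- backsolve(L, yv, transpose = TRUE)
  cx <- xs - one * sum(one * xs) / sum(one^2)
  cy <- ys - one * sum(one * ys) / sum(one^2)
  sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
}

#' Measurement-error PGLS (Ives-type iterative estimator)
#'
#' Corrects the allometric slope for within-species sampling variance in both
#' variables. The response covariance is
#' `sigma2 * V(lambda) + diag(var_y) + beta^2 * diag(var_x)` and the slope is
#' de-attenuated through the structural relation
#' `beta = (x~' W y) / (x~' W x~ - sum_i W_ii var_x,i)` with `W` the inverse
#' of that covariance; `(sigma2, lambda)` are re-estimated by ML at each
#' update and the scheme is iterated to convergence. Confidence intervals come
#' from a parametric bootstrap that re-simulates both the latent predictor
#' process and the sampling errors.
#'
#' @param summary A `species_summary` with `var_x`, `var_y`, `n`.
#' @param tree A `phylo` object.
#' @param nboot Parametric-bootstrap draws for the CI (0 skips the bootstrap).
#' @param tol Relative slope change declaring convergence.
#' @param max_iter Iteration cap.
#' @param seed Seed for the bootstrap.
#' @return A `gls_fit` with method `"pgls_ives"`.
#' @export
fit_pgls_ives <- function(summary, tree, nboot = 200, tol = 1e-6,
                          max_iter = 100, seed = 1L) {
  if (any(summary$var_x < 0) || any(summary$var_y < 0)) {
    abort("negative within-species variances")
  }
  al <- align_summary_tree(summary, tree)
  s <- al$summary; tree <- al$tree
  V <- phylo_vcv(tree)
  est <- ives_estimate(s$mean_x, s$mean_y, s$var_x, s$var_y, V, tol, max_iter)
  boot <- NULL
  if (nboot > 0) {
    xproc <- me_gls_intercept(s$mean_x, s$var_x, V)
    set.seed(seed)
    Lx <- chol(apply_lambda(V, xproc$lambda) * xproc$sigma2)
    Le <- chol(apply_lambda(V, est$lambda) * max(est$sigma2, 1e-12) +
                 diag(1e-12, nrow(V)))
    nsp <- nrow(V)
    bs <- replicate(nboot, {
      xt <- xproc$mu + drop(crossprod(Lx, rnorm(nsp)))
      yt <- est$intercept + est$slope * xt + drop(crossprod(Le, rnorm(nsp)))
      xo <- xt + rnorm(nsp, 0, sqrt(s$var_x))
      yo <- yt + rnorm(nsp, 0, sqrt(s$var_y))
      tryCatch(ives_estimate(xo, yo, s$var_x, s$var_y, V, tol, max_iter)$slope,
               error = function(e) NA_real_)
    })
    boot <- bs[is.finite(bs)]
  }
  se_slope <- if (length(boot) > 1) sd(boot) else NA_real_
  ci <- if (length(boot) > 1) {
    quantile(boot, c(0.025, 0.975), names = FALSE)
  } else c(NA_real_, NA_real_)
  coefs <- tibble::tibble(
    term = c("(Intercept)", "x"),
    estimate = c(est$intercept, est$slope),
    std_error = c(NA_real_, se_slope),
    conf_low = c(NA_real_, ci[1]), conf_high = c(NA_real_, ci[2]),
    statistic = c(NA_real_, if (!is.na(se_slope)) est$slope / se_slope else NA_real_),
    p_value = c(NA_real_,
                if (!is.na(se_slope)) 2 * pnorm(-abs(est$slope / se_slope)) else NA_real_)
  )
  n <- nrow(s); k <- 4
  new_gls_fit("pgls_ives", coefs,
    list(lambda = est$lambda, sigma2 = est$sigma2, logLik = est$logLik,
         AICc = aicc(est$logLik, k, n), n = n, k = k,
         residuals = setNames(s$mean_y - est$intercept - est$slope * s$mean_x,
                              s$species),
         iterations = est$iterations, converged = est$converged,
         bootstrap_slopes = boot, species = s$species))
}

# core structural iteration
ives_estimate <- function(x, y, vx, vy, V, tol = 1e-6, max_iter = 100) {
  n <- length(y)
  d <- diag(V)
  init <- gls_profile_fit(cbind(1, x), y, V, "lambda")
  beta <- init$beta[2]; lam <- init$lambda; sig2 <- init$sigma2
  lnl <- init$logLik
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    C <- apply_lambda(V, lam) * sig2 + diag(vy + beta^2 * vx, n)
    W <- chol2inv(chol(C))
    w1 <- rowSums(W)
    xbar <- sum(w1 * x) / sum(w1)
    xt <- x - xbar
    denom <- drop(xt %*% W %*% xt) - sum(diag(W) * vx)
    if (denom <= 0) abort("measurement variance in x too large: corrected slope undefined")
    beta_new <- drop(xt %*% W %*% y) / denom
    # re-estimate (sigma2, lambda) by ML on the intercept-only residual model
    resid <- y - beta_new * x
    ml <- me_gls_intercept(resid, vy + beta_new^2 * vx, V)
    rel <- abs(beta_new - beta) / max(abs(beta), 1e-12)
    beta <- beta_new; lam <- ml$lambda; sig2 <- ml$sigma2; lnl <- ml$logLik
    if (rel < tol) { conv <- TRUE; break }
  }
  C <- apply_lambda(V, lam) * sig2 + diag(vy + beta^2 * vx, n)
  W <- chol2inv(chol(C))
  w1 <- rowSums(W)
  a <- sum(w1 * (y - beta * x)) / sum(w1)
  list(slope = beta, intercept = a, lambda = lam, sigma2 = sig2,
       logLik = lnl, iterations = it, converged = conv)
}

# ML fit of an intercept-only GLS with covariance sigma2 V(lambda) + diag(vd)
me_gls_intercept <- function(z, vd, V) {
  n <- length(z)
  vd <- rep_len(vd, n)
  nll <- function(par) {
    lam <- par[1]; s2 <- exp(par[2])
    C <- apply_lambda(V, lam) * s2 + diag(vd, n)
    L <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    zs <- backsolve(L, z, transpose = TRUE)
    os <- backsolve(L, rep(1, n), transpose = TRUE)
    mu <- sum(os * zs) / sum(os^2)
    r <- zs - mu * os
    0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(r^2))
  }
  s2_0 <- max(var(z) / mean(diag(V)), 1e-10)
  opt <- optim(c(0.5, log(s2_0)), nll, method = "L-BFGS-B",
               lower = c(0, log(s2_0) - 20), upper = c(1, log(s2_0) + 10))
  lam <- opt$par[1]; s2 <- exp(opt$par[2])
  C <- apply_lambda(V, lam) * s2 + diag(vd, n)
  L <- chol(C)
  zs <- backsolve(L, z, transpose = TRUE)
  os <- backsolve(L, rep(1, n), transpose = TRUE)
  mu <- sum(os * zs) / sum(os^2)
  list(mu = mu, lambda = lam, sigma2 = s2, logLik = -opt$value)
}

#' Phylogenetic signal (Pagel's lambda) of a trait
#'
#' ML estimate of lambda for an intercept-only PGLS, with a likelihood-ratio
#' test against `lambda = 0` (no signal).
#'
#' @param data Data frame with a species column and the trait column, or a
#'   named numeric vector.
#' @param trait Trait column (tidy-eval; ignored for a named vector).
#' @param tree A `phylo` object.
#' @param species Species column.
#' @return One-row tibble: `lambda`, `logLik`, `logLik0`, `LR`, `p_value`.
#' @export
pagel_lambda_signal <- function(data, trait, tree, species = species) {
  if (is.numeric(data) && !is.null(names(data))) {
    df <- tibble::tibble(species = names(data), mean_y = as.numeric(data))
  } else {
    df <- dplyr::transmute(data, species = as.character({{ species }}),
                           mean_y = as.numeric({{ trait }}))
  }
  if (nrow(df) < 4) abort("need at least 4 species")
  if (var(df$mean_y) == 0) abort("trait is constant")
  al <- align_summary_tree(df, tree)
  V <- phylo_vcv(al$tree)
  X <- cbind(rep(1, nrow(al$summary)))
  f1 <- gls_profile_fit(X, al$summary$mean_y, V, "lambda")
  f0 <- gls_profile_fit(X, al$summary$mean_y, V, "lambda", lambda = 0)
  lr <- 2 * (f1$logLik - f0$logLik)
  tibble::tibble(lambda = f1$lambda, logLik = f1$logLik, logLik0 = f0$logLik,
                 LR = lr, p_value = pchisq(pmax(lr, 0), df = 1,
                                           lower.tail = FALSE))
}

#' Repeatability (intraclass correlation) from a one-way design
#'
#' ANOVA-based ICC with the Lessells-Boag correction `n0` for unequal group
#' sizes: `R = s2_among / (s2_among + s2_within)` with
#' `s2_among = (MS_among - MS_within) / n0`,
#' `n0 = (N - sum(n_i^2) / N) / (k - 1)`; `R` is truncated to `[0, 1]`.
#'
#' @param data Individual-level data frame.
#' @param trait Trait column (tidy-eval). Set `log10_transform = TRUE` to
#'   analyse on the log10 scale.
#' @param group Grouping column (default `species`).
#' @param log10_transform Apply log10 first.
#' @return One-row tibble: `var_among`, `var_within`, `n0`, `R`, `k_groups`,
#'   `N`.
#' @export
repeatability_icc <- function(data, trait, group = species,
                              log10_transform = FALSE) {
  df <- dplyr::transmute(data, g = as.character({{ group }}),
                         y = as.numeric({{ trait }}))
  if (log10_transform) {
    if (any(df$y <= 0)) abort("nonpositive values cannot be log10-transformed")
    df$y <- log10(df$y)
  }
  ni <- table(df$g)
  k <- length(ni); N <- nrow(df)
  if (k < 2) abort("need at least 2 groups")
  if (all(ni == 1)) abort("all groups have a single observation")
  gm <- tapply(df$y, df$g, mean)
  ss_within <- sum((df$y - gm[df$g])^2)
  ss_among <- sum(ni * (gm - mean(df$y))^2)
  ms_within <- ss_within / (N - k)
  ms_among <- ss_among / (k - 1)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  s2_among <- max((ms_among - ms_within) / n0, 0)
  R <- s2_among / (s2_among + ms_within)
  R <- min(max(R, 0), 1)
  tibble::tibble(var_among = s2_among, var_within = ms_within, n0 = n0,
                 R = R, k_groups = k, N = N)
}

#' Correct a regression slope for attenuation
#'
#' Divides a slope by the reliability (repeatability) of the predictor, the
#' classical de-attenuation of a slope biased downward by measurement error
#' in x.
#'
#' @param slope Estimated slope.
#' @param reliability_x Reliability of the predictor in `(0, 1]`.
#' @return The corrected slope.
#' @examples
#' attenuation_correct(0.95, 0.96) # ~0.99
#' @export
attenuation_correct <- function(slope, reliability_x) {
  if (!is.numeric(reliability_x) || any(reliability_x <= 0)) {
    abort("`reliability_x` must be positive")
  }
  if (any(reliability_x > 1)) abort("`reliability_x` cannot exceed 1")
  slope / reliability_x
}

#' Mass-independent residuals from a lambda-PGLS size correction
#'
#' Raw residuals `y - y_hat` of the profile-lambda PGLS of log10 SMR on log10
#' body mass, in tip order: the "mass-independent" metabolic rate used by the
#' downstream macroevolutionary analyses.
#'
#' @param summary A `species_summary`.
#' @param tree A `phylo` object.
#' @return Tibble with `species` and `residual`.
#' @export
mass_independent_residuals <- function(summary, tree) {
  fit <- fit_pgls(summary, tree, transform = "lambda")
  tibble::tibble(species = names(fit$residuals),
                 residual = unname(fit$residuals))
}

#' Scan families for outlying allometry
#'
#' For each family with at least `min_species` species, fits a phylogenetic
#' ANCOVA contrasting that family against all others (intercept and slope
#' contrasts with interaction) and reports the T statistics with raw and
#' Holm-adjusted p values. Families flagged at `alpha` (raw p, either
#' contrast) are then excluded and the measurement-error PGLS refitted.
#'
#' @param summary A `species_summary` with a `family` column.
#' @param tree A `phylo` object.
#' @param family Family column (tidy-eval).
#' @param min_species Minimum species per family for a contrast (default 3).
#' @param alpha Flagging level on the raw p value.
#' @param refit Refit [fit_pgls_ives()] excluding flagged families.
#' @param nboot Bootstrap draws for the refit CI.
#' @return List (class `family_scan`): `table` (per-family contrasts),
#'   `flagged`, `skipped`, and `refit_ives` (or `NULL`).
#' @export
family_outlier_scan <- function(summary, tree, family = family,
                                min_species = 3, alpha = 0.05, refit = TRUE,
                                nboot = 0) {
  fam <- dplyr::pull(summary, {{ family }})
  counts <- table(fam)
  eligible <- names(counts)[counts >= min_species]
  skipped <- setdiff(names(counts), eligible)
  if (length(eligible) < 1) abort("no family with enough species for contrasts")
  rows <- purrr::map_dfr(eligible, function(f) {
    s2 <- summary
    s2$.focal <- factor(ifelse(fam == f, "focal", "rest"),
                        levels = c("rest", "focal"))
    fit <- fit_pgls(s2, tree, grouping = ".focal")
    ct <- fit$contrasts
    tibble::tibble(family = f, n_species = as.integer(counts[[f]]),
                   contrast = ct$contrast, estimate = ct$estimate,
                   statistic = ct$statistic, p_value = ct$p_value)
  })
  rows <- rows |>
    dplyr::group_by(.data$contrast) |>
    dplyr::mutate(p_holm = p.adjust(.data$p_value, "holm")) |>
    dplyr::ungroup()
  flagged <- unique(rows$family[rows$p_value < alpha])
  refit_ives <- NULL
  if (refit && length(flagged) && sum(!fam %in% flagged) >= 4) {
    refit_ives <- fit_pgls_ives(summary[!fam %in% flagged, ], tree,
                                nboot = nboot)
  }
  structure(list(table = rows, flagged = flagged, skipped = skipped,
                 refit_ives = refit_ives), class = "family_scan")
}

#' Leave-one-species-out predictive accuracy of the allometry
#'
#' For each species, refits the profile-lambda PGLS without it and predicts
#' its log10 SMR two ways: the regression mean alone (`pred_mean`) and the
#' phylogenetic conditional mean that also exploits the residual covariance
#' with the training species (`pred_phylo`). Reports out-of-sample R-squared
#' and median absolute error (log10 units) for the phylogenetic prediction.
#'
#' @param summary A `species_summary`.
#' @param tree A `phylo` object.
#' @return Tibble of per-species predictions with attributes `r2_loo`,
#'   `mae_loo` (and the same for the mean-only prediction); also accessible
#'   via [glance()].
#' @export
loo_prediction <- function(summary, tree) {
  al <- align_summary_tree(summary, tree)
  s <- al$summary; tree <- al$tree
  V <- phylo_vcv(tree)
  n <- nrow(s)
  pred_phylo <- pred_mean <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- cbind(1, s$mean_x[-i])
    fit <- gls_profile_fit(Xi, s$mean_y[-i], V[-i, -i, drop = FALSE], "lambda")
    mu_i <- fit$beta[1] + fit$beta[2] * s$mean_x[i]
    Vl <- apply_lambda(V, fit$lambda)
    w <- solve(Vl[-i, -i, drop = FALSE], Vl[-i, i])
    pred_mean[i] <- mu_i
    pred_phylo[i] <- mu_i + sum(w * fit$residuals)
  }
  out <- tibble::tibble(species = s$species, observed = s$mean_y,
                        pred_phylo = pred_phylo, pred_mean = pred_mean)
  sst <- sum((s$mean_y - mean(s$mean_y))^2)
  attr(out, "r2_loo") <- 1 - sum((s$mean_y - pred_phylo)^2) / sst
  attr(out, "mae_loo") <- median(abs(s$mean_y - pred_phylo))
  attr(out, "r2_loo_mean") <- 1 - sum((s$mean_y - pred_mean)^2) / sst
  attr(out, "mae_loo_mean") <- median(abs(s$mean_y - pred_mean))
  out
}
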