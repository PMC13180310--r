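#' Prior for the reversible-jump shift model
#'
#' Shift count k has a conditional (truncated, renormalised) Poisson prior;
#' given k, shifts occupy k distinct edges with probability proportional to
#' the product of their lengths (at most one shift per branch) and uniform
#' position within the edge. Optima (and slopes, in the allometry flavour)
#' take Normal priors; the pull `alpha` and diffusion `sigma2` take
#' half-Cauchy priors.
#'
#' @param k_mean Poisson mean of the shift-count prior. Default 1.
#' @param k_max Maximum shifts (default: half the number of edges).
#' @param theta_mean,theta_sd Normal prior on optima; defaults are the trait
#'   mean and twice the trait SD (set when the sampler sees the data).
#' @param beta_mean,beta_sd Normal prior on regime slopes (allometry flavour).
#' @param alpha_scale,sigma2_scale Half-Cauchy scales.
#' @return A `shift_prior` list.
#' @export
shift_prior <- function(k_mean = 1, k_max = NULL,
                        theta_mean = NULL, theta_sd = NULL,
                        beta_mean = 1, beta_sd = 0.5,
                        alpha_scale = 0.1, sigma2_scale = 0.1) {
  structure(list(k_mean = k_mean, k_max = k_max,
                 theta_mean = theta_mean, theta_sd = theta_sd,
                 beta_mean = beta_mean, beta_sd = beta_sd,
                 alpha_scale = alpha_scale, sigma2_scale = sigma2_scale),
            class = "shift_prior")
}

log_half_cauchy <- function(x, scale) {
  ifelse(x > 0, log(2 / pi) - log(scale) - log1p((x / scale)^2), -Inf)
}

# log elementary symmetric polynomials e_0..e_kmax of the edge lengths,
# on the original MY scale (computed on rescaled lengths for stability).
log_esp <- function(len, kmax) {
  c0 <- mean(len)
  x <- len / c0
  e <- numeric(kmax + 1)
  e[1] <- 1
  for (xi in x) {
    top <- min(kmax, length(e) - 1)
    for (k in rev(seq_len(top))) e[k + 1] <- e[k + 1] + xi * e[k]
  }
  log(e) + (0:kmax) * log(c0)
}

# ---- the sampler -------------------------------------------------------------

# One chain of the reversible-jump multi-optima OU shift sampler.
# flavour "trait": Hansen mean with exponentially decaying shift weights.
# flavour "allometry": mean = theta_r(i) + beta_r(i) * x_i with r(i) the
# regime at tip i; theta and beta are born jointly at a shift.
rj_chain <- function(y, x, geom, prior, iterations, thin, burn_in_frac,
                     seed, likelihood = TRUE, flavour = "trait",
                     init = NULL) {
  set.seed(seed)
  n <- length(y)
  E <- geom$E; len <- geom$len; td <- geom$td; pd <- geom$pd
  etm <- geom$etm; ancE <- geom$ancE
  lesp <- geom$lesp
  kmax <- prior$k_max
  lpk <- stats::dpois(0:kmax, prior$k_mean, log = TRUE)
  lpk <- lpk - log(sum(exp(lpk - max(lpk))) ) - max(lpk) # normalised (constant, cancels anyway)
  mt <- prior$theta_mean; st <- prior$theta_sd
  mb <- prior$beta_mean; sb <- prior$beta_sd
  allom <- identical(flavour, "allometry")

  # state
  alpha <- init$alpha %||% exp(rnorm(1, log(0.05 / max(td)), 0.5))
  sigma2 <- init$sigma2 %||% exp(rnorm(1, log(max(var(y), 1e-6) * 2 * alpha), 0.5))
  theta0 <- rnorm(1, mt, st / 4)
  beta0 <- if (allom) rnorm(1, mb, sb / 4) else 0
  sh_edge <- integer(0); sh_pos <- numeric(0)
  sh_theta <- numeric(0); sh_beta <- numeric(0)

  chol_cache <- function(a) {
    R <- exp(-a * geom$D)
    L <- chol(R)
    list(L = L, logdet = 2 * sum(log(diag(L))))
  }
  cc <- chol_cache(alpha)

  shift_parents <- function() {
    k <- length(sh_edge)
    if (k == 0) return(integer(0))
    t_s <- pd[sh_edge] + sh_pos
    vapply(seq_len(k), function(j) {
      anc <- which(ancE[sh_edge, sh_edge[j]])
      if (!length(anc)) return(0L)
      anc[which.max(t_s[anc])]
    }, integer(1))
  }

  mean_vec <- function() {
    k <- length(sh_edge)
    if (!allom) {
      m <- rep(theta0, n)
      if (k) {
        t_s <- pd[sh_edge] + sh_pos
        par <- shift_parents()
        thp <- ifelse(par == 0L, theta0, sh_theta[par])
        for (j in seq_len(k)) {
          sel <- etm[sh_edge[j], ]
          m[sel] <- m[sel] + (sh_theta[j] - thp[j]) * (1 - exp(-alpha * (td[sel] - t_s[j])))
        }
      }
      m
    } else {
      th <- rep(theta0, n); be <- rep(beta0, n)
      if (k) {
        t_s <- pd[sh_edge] + sh_pos
        gov <- rep(0L, n); gt <- rep(-Inf, n)
        for (j in seq_len(k)) {
          sel <- etm[sh_edge[j], ] & t_s[j] > gt
          gov[sel] <- j; gt[sel] <- t_s[j]
        }
        hit <- gov > 0L
        th[hit] <- sh_theta[gov[hit]]
        be[hit] <- sh_beta[gov[hit]]
      }
      th + be * x
    }
  }

  loglik_full <- function() {
    if (!likelihood) return(list(ll = 0, quad = 0, z = NULL))
    m <- mean_vec()
    z <- backsolve(cc$L, y - m, transpose = TRUE)
    quad <- sum(z^2)
    sv <- sigma2 / (2 * alpha)
    ll <- -0.5 * n * log(2 * pi * sv) - 0.5 * cc$logdet - 0.5 * quad / sv
    list(ll = ll, quad = quad)
  }
  cur <- loglik_full()

  log_prior_theta <- function(v) dnorm(v, mt, st, log = TRUE)
  log_prior_beta <- function(v) dnorm(v, mb, sb, log = TRUE)

  # move probabilities (fixed; invalid proposals auto-reject)
  p_move <- c(birth = 0.15, death = 0.15, relocate = 0.15,
              theta = if (allom) 0.15 else 0.30,
              beta = if (allom) 0.15 else 0,
              alpha = 0.125, sigma2 = 0.125)
  p_move <- p_move / sum(p_move)
  move_names <- names(p_move)
  theta_step <- st / 2
  beta_step <- sb / 2
  log_step <- 0.4

  acc <- att <- setNames(numeric(length(move_names)), move_names)
  n_keep <- floor((iterations - floor(burn_in_frac * iterations)) / thin)
  trace <- matrix(NA_real_, n_keep, 6,
                  dimnames = list(NULL, c("iter", "k", "alpha", "sigma2",
                                          "logLik", "theta0")))
  beta0_trace <- numeric(n_keep)
  shifts_out <- vector("list", n_keep)
  keep_i <- 0L
  burn <- floor(burn_in_frac * iterations)

  for (it in seq_len(iterations)) {
    mv <- sample(move_names, 1, prob = p_move)
    att[mv] <- att[mv] + 1
    k <- length(sh_edge)
    if (mv == "birth" && k < kmax) {
      free <- setdiff(seq_len(E), sh_edge)
      Lfree <- sum(len[free])
      e <- free[sample.int(length(free), 1, prob = len[free])]
      u <- runif(1, 0, len[e])
      th_new <- rnorm(1, mt, st)
      be_new <- if (allom) rnorm(1, mb, sb) else 0
      old <- list(sh_edge, sh_pos, sh_theta, sh_beta, cur)
      sh_edge <- c(sh_edge, e); sh_pos <- c(sh_pos, u)
      sh_theta <- c(sh_theta, th_new); sh_beta <- c(sh_beta, be_new)
      prop <- loglik_full()
      la <- (prop$ll - old[[5]]$ll) + (lpk[k + 2] - lpk[k + 1]) +
        (lesp[k + 1] - lesp[k + 2]) + log(Lfree) - log(k + 1)
      if (is.finite(la) && log(runif(1)) < la) {
        cur <- prop; acc[mv] <- acc[mv] + 1
      } else {
        sh_edge <- old[[1]]; sh_pos <- old[[2]]
        sh_theta <- old[[3]]; sh_beta <- old[[4]]; cur <- old[[5]]
      }
    } else if (mv == "death" && k > 0) {
      j <- sample.int(k, 1)
      old <- list(sh_edge, sh_pos, sh_theta, sh_beta, cur)
      sh_edge <- sh_edge[-j]; sh_pos <- sh_pos[-j]
      sh_theta <- sh_theta[-j]; sh_beta <- sh_beta[-j]
      prop <- loglik_full()
      free_after <- setdiff(seq_len(E), sh_edge)
      la <- (prop$ll - old[[5]]$ll) + (lpk[k] - lpk[k + 1]) +
        (lesp[k + 1] - lesp[k]) + log(k) - log(sum(len[free_after]))
      if (is.finite(la) && log(runif(1)) < la) {
        cur <- prop; acc[mv] <- acc[mv] + 1
      } else {
        sh_edge <- old[[1]]; sh_pos <- old[[2]]
        sh_theta <- old[[3]]; sh_beta <- old[[4]]; cur <- old[[5]]
      }
    } else if (mv == "relocate" && k > 0) {
      j <- sample.int(k, 1)
      old <- list(sh_edge, sh_pos, cur)
      if (runif(1) < 0.5) {
        # slide within the edge, reflecting at the boundaries
        e <- sh_edge[j]
        u <- sh_pos[j] + rnorm(1, 0, len[e] / 4)
        u <- u %% (2 * len[e]); if (u > len[e]) u <- 2 * len[e] - u
        sh_pos[j] <- min(max(u, 1e-9), len[e] - 1e-9)
        la_extra <- 0
      } else {
        # jump to a random edge free of the other shifts
        avail <- setdiff(seq_len(E), sh_edge[-j])
        e <- avail[sample.int(length(avail), 1, prob = len[avail])]
        sh_edge[j] <- e
        sh_pos[j] <- runif(1, 0, len[e])
        la_extra <- 0 # edge-length weights cancel between prior and proposal
      }
      prop <- loglik_full()
      la <- prop$ll - old[[3]]$ll + la_extra
      if (is.finite(la) && log(runif(1)) < la) {
        cur <- prop; acc[mv] <- acc[mv] + 1
      } else {
        sh_edge <- old[[1]]; sh_pos <- old[[2]]; cur <- old[[3]]
      }
    } else if (mv == "theta") {
      j <- sample.int(k + 1, 1) - 1L # 0 = root regime
      oldv <- if (j == 0) theta0 else sh_theta[j]
      newv <- oldv + rnorm(1, 0, theta_step)
      oldcur <- cur
      if (j == 0) theta0 <- newv else sh_theta[j] <- newv
      prop <- loglik_full()
      la <- prop$ll - oldcur$ll + log_prior_theta(newv) - log_prior_theta(oldv)
      if (is.finite(la) && log(runif(1)) < la) {
        cur <- prop; acc[mv] <- acc[mv] + 1
      } else {
        if (j == 0) theta0 <- oldv else sh_theta[j] <- oldv
        cur <- oldcur
      }
    } else if (mv == "beta") {
      j <- sample.int(k + 1, 1) - 1L
      oldv <- if (j == 0) beta0 else sh_beta[j]
      newv <- oldv + rnorm(1, 0, beta_step)
      oldcur <- cur
      if (j == 0) beta0 <- newv else sh_beta[j] <- newv
      prop <- loglik_full()
      la <- prop$ll - oldcur$ll + log_prior_beta(newv) - log_prior_beta(oldv)
      if (is.finite(la) && log(runif(1)) < la) {
        cur <- prop; acc[mv] <- acc[mv] + 1
      } else {
        if (j == 0) beta0 <- oldv else sh_beta[j] <- oldv
        cur <- oldcur
      }
    } else if (mv == "alpha") {
      olda <- alpha; oldcc <- cc; oldcur <- cur
      alpha <- exp(log(alpha) + rnorm(1, 0, log_step))
      if (likelihood) cc <- chol_cache(alpha)
      prop <- loglik_full()
      la <- prop$ll - oldcur$ll +
        log_half_cauchy(alpha, prior$alpha_scale) -
        log_half_cauchy(olda, prior$alpha_scale) +
        log(alpha) - log(olda)
      if (is.finite(la) && log(runif(1)) < la) {
        cur <- prop; acc[mv] <- acc[mv] + 1
      } else {
        alpha <- olda; cc <- oldcc; cur <- oldcur
      }
    } else if (mv == "sigma2") {
      olds <- sigma2
      sigma2 <- exp(log(sigma2) + rnorm(1, 0, log_step))
      ll_new <- if (likelihood) {
        sv <- sigma2 / (2 * alpha)
        -0.5 * n * log(2 * pi * sv) - 0.5 * cc$logdet - 0.5 * cur$quad / sv
      } else 0
      la <- ll_new - cur$ll +
        log_half_cauchy(sigma2, prior$sigma2_scale) -
        log_half_cauchy(olds, prior$sigma2_scale) +
        log(sigma2) - log(olds)
      if (is.finite(la) && log(runif(1)) < la) {
        cur$ll <- ll_new; acc[mv] <- acc[mv] + 1
      } else {
        sigma2 <- olds
      }
    }
    if (it > burn && (it - burn) %% thin == 0 && keep_i < n_keep) {
      keep_i <- keep_i + 1L
      trace[keep_i, ] <- c(it, length(sh_edge), alpha, sigma2, cur$ll, theta0)
      beta0_trace[keep_i] <- beta0
      shifts_out[[keep_i]] <- list(edge = sh_edge, pos = sh_pos,
                                   theta = sh_theta, beta = sh_beta)
    }
  }
  list(trace = tibble::as_tibble(as.data.frame(trace[seq_len(keep_i), , drop = FALSE])),
       beta0 = beta0_trace[seq_len(keep_i)],
       shifts = shifts_out[seq_len(keep_i)],
       acceptance = ifelse(att > 0, acc / att, NA_real_))
}

# shared tree geometry for the sampler
rj_geometry <- function(tree) {
  n <- ape::Ntip(tree)
  depths <- node_depths(tree)
  list(
    E = nrow(tree$edge),
    len = tree$edge.length,
    td = depths[seq_len(n)],
    pd = depths[tree$edge[, 1]],
    etm = edge_tip_matrix(tree),
    ancE = edge_ancestor_matrix(tree),
    D = ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
  )
}

# E x E logical: is edge a a strict ancestor of edge b
# (b's descendant tips are a proper subset of a's)?
edge_ancestor_matrix <- function(tree) {
  etm <- edge_tip_matrix(tree)
  E <- nrow(etm)
  out <- matrix(FALSE, E, E)
  for (a in seq_len(E)) for (b in seq_len(E)) {
    out[a, b] <- a != b && all(!etm[b, ] | etm[a, ]) && !all(etm[a, ] == etm[b, ])
  }
  out
}

finalize_prior <- function(prior, y, geom) {
  prior <- prior %||% shift_prior()
  prior$k_max <- prior$k_max %||% floor(geom$E / 2)
  prior$theta_mean <- prior$theta_mean %||% mean(y)
  prior$theta_sd <- prior$theta_sd %||% (2 * sd(y))
  prior
}

run_rjmcmc_impl <- function(y, x, tree, prior, iterations, thin, burn_in,
                            chains, seed, likelihood, flavour) {
  tree <- validate_tree(tree)
  if (!ape::is.binary(tree)) tree <- resolve_binary(tree)
  if (chains < 2) abort("at least 2 chains are required for diagnostics")
  if (iterations < 10 * thin) abort("iterations must be at least 10 * thin")
  y <- as_trait_vector(y, tree)
  if (!is.null(x)) x <- as_trait_vector(x, tree)
  geom <- rj_geometry(tree)
  prior <- finalize_prior(prior, y, geom)
  geom$lesp <- log_esp(geom$len, prior$k_max)
  runs <- lapply(seq_len(chains), function(ch) {
    rj_chain(y, x, geom, prior, iterations, thin, burn_in,
             seed = derive_seed(seed, ch), likelihood = likelihood,
             flavour = flavour)
  })
  build_shift_posterior(runs, tree, geom, prior, flavour, y, x,
                        list(iterations = iterations, thin = thin,
                             burn_in = burn_in, chains = chains, seed = seed))
}

#' Reversible-jump MCMC for shifts in a trait's OU optima
#'
#' Samples the number, placement and values of adaptive-optimum shifts of a
#' multi-optima Ornstein-Uhlenbeck model, with no predefined regimes: the
#' reversible-jump moves add, remove and relocate shifts while slide moves
#' update the optima, `alpha` and `sigma2`.
#'
#' @param trait Named numeric vector (or `species`/value data frame).
#' @param tree A `phylo` object (resolved to binary if needed).
#' @param prior A [shift_prior()] (defaults filled from the data).
#' @param iterations Iterations per chain.
#' @param thin Keep every `thin`-th draw after burn-in.
#' @param burn_in Burn-in fraction.
#' @param chains Number of chains (>= 2).
#' @param seed Integer seed (chain seeds are derived deterministically).
#' @param likelihood Set `FALSE` to sample the prior only (validation runs).
#' @return A `shift_posterior`: per-branch posterior shift probabilities and
#'   edge-wise posterior mean optima, the posterior of k with median and 95%
#'   HPD, traces, acceptance rates and convergence diagnostics.
#' @export
run_rjmcmc_trait <- function(trait, tree, prior = NULL, iterations = 200000,
                             thin = 100, burn_in = 0.3, chains = 2,
                             seed = 1L, likelihood = TRUE) {
  run_rjmcmc_impl(trait, NULL, tree, prior, iterations, thin, burn_in,
                  chains, seed, likelihood, "trait")
}

#' Reversible-jump MCMC for shifts in allometric intercept and slope
#'
#' As [run_rjmcmc_trait()], but the mean of species `i` is
#' `theta_r(i) + beta_r(i) * x_i` with `r(i)` the regime governing tip `i`;
#' a shift carries a new intercept and slope drawn jointly at birth, and the
#' residual is OU-correlated.
#'
#' @inheritParams run_rjmcmc_trait
#' @param y Response (log10 SMR), named by species.
#' @param x Predictor (log10 body mass), named by species.
#' @return A `shift_posterior` with per-edge slope summaries in addition to
#'   the optima.
#' @export
run_rjmcmc_allometry <- function(y, x, tree, prior = NULL, iterations = 200000,
                                 thin = 100, burn_in = 0.3, chains = 2,
                                 seed = 1L, likelihood = TRUE) {
  run_rjmcmc_impl(y, x, tree, prior, iterations, thin, burn_in,
                  chains, seed, likelihood, "allometry")
}

# pool chains, compute branch pp, edge-wise posterior means, k posterior
build_shift_posterior <- function(runs, tree, geom, prior, flavour, y, x,
                                  settings) {
  E <- geom$E
  traces <- dplyr::bind_rows(lapply(seq_along(runs), function(i) {
    tr <- runs[[i]]$trace
    tr$chain <- i
    tr$beta0 <- runs[[i]]$beta0
    tr
  }))
  shifts <- do.call(c, lapply(runs, `[[`, "shifts"))
  S <- length(shifts)
  hit <- matrix(FALSE, S, E)
  theta_edge_sum <- beta_edge_sum <- numeric(E)
  pd <- geom$pd; len <- geom$len; ancE <- geom$ancE
  mid_t <- pd + len / 2
  for (s in seq_len(S)) {
    sh <- shifts[[s]]
    th0 <- traces$theta0[s]; b0 <- traces$beta0[s]
    gov_theta <- rep(th0, E); gov_beta <- rep(b0, E)
    if (length(sh$edge)) {
      hit[s, sh$edge] <- TRUE
      t_s <- pd[sh$edge] + sh$pos
      gt <- rep(-Inf, E)
      for (j in seq_along(sh$edge)) {
        covered <- ancE[sh$edge[j], ] # strict descendants of the shift edge
        covered[sh$edge[j]] <- sh$pos[j] <= len[sh$edge[j]] / 2
        sel <- covered & t_s[j] > gt
        gov_theta[sel] <- sh$theta[j]
        gov_beta[sel] <- sh$beta[j]
        gt[sel] <- t_s[j]
      }
    }
    theta_edge_sum <- theta_edge_sum + gov_theta
    beta_edge_sum <- beta_edge_sum + gov_beta
  }
  branch <- tibble::tibble(
    edge = seq_len(E),
    parent = tree$edge[, 1], child = tree$edge[, 2],
    pp = colMeans(hit),
    mean_theta = theta_edge_sum / S
  )
  if (flavour == "allometry") branch$mean_beta <- beta_edge_sum / S
  kp <- table(factor(traces$k, levels = 0:max(traces$k)))
  k_post <- tibble::tibble(k = as.integer(names(kp)),
                           prob = as.numeric(kp) / S)
  khpd <- discrete_hpd(k_post$k, k_post$prob, 0.95)
  params <- c("alpha", "sigma2", "k", "logLik")
  diag <- convergence_diagnostics(
    lapply(runs, function(r) r$trace[, params])
  )
  structure(list(
    flavour = flavour,
    samples = traces,
    shift_samples = shifts,
    branch = branch,
    k_posterior = k_post,
    k_median = median(traces$k),
    k_mode = k_post$k[which.max(k_post$prob)],
    k_hpd = khpd,
    root_theta = mean(traces$theta0),
    root_beta = if (flavour == "allometry") mean(traces$beta0) else NULL,
    diagnostics = diag,
    acceptance = lapply(runs, `[[`, "acceptance"),
    prior = prior, settings = settings,
    rhat_flag = any(diag$rhat[diag$parameter %in% c("alpha", "k")] > 1.1,
                    na.rm = TRUE)
  ), class = "shift_posterior")
}

# 95% HPD set on a discrete posterior by highest-mass accumulation,
# ties broken toward smaller k; reported as the range of the included set.
discrete_hpd <- function(k, prob, level = 0.95) {
  ord <- order(-prob, k)
  cum <- cumsum(prob[ord])
  take <- seq_len(which(cum >= level)[1])
  range(k[ord][take])
}

#' Summarise a shift posterior
#'
#' @param posterior A `shift_posterior`.
#' @param pp_threshold Report branches with posterior shift probability at or
#'   above this (default 0.2).
#' @return List: `branches` (tibble of reported branches with their posterior
#'   mean optima/slopes), `k_summary`, `theta_histogram` (per-edge posterior
#'   mean optima across all edges, for plotting).
#' @export
summarize_shifts <- function(posterior, pp_threshold = 0.2) {
  br <- posterior$branch
  sel <- br[br$pp >= pp_threshold, ]
  sel <- sel[order(-sel$pp), ]
  list(
    branches = sel,
    k_summary = tibble::tibble(
      k_median = posterior$k_median, k_mode = posterior$k_mode,
      hpd_low = posterior$k_hpd[1], hpd_high = posterior$k_hpd[2]
    ),
    theta_histogram = posterior$branch$mean_theta,
    pp_threshold = pp_threshold
  )
}

#' Convergence diagnostics for MCMC chains
#'
#' Potential scale reduction factor (R-hat across chains, clamped at 1 from
#' below so identical chains report exactly 1) and effective sample size by
#' Geyer's initial-positive-sequence truncation of the pooled within-chain
#' autocorrelation.
#'
#' @param chains List (>= 2) of equal-length data frames of parameter draws.
#' @return Tibble: `parameter`, `rhat`, `ess`.
#' @export
convergence_diagnostics <- function(chains) {
  if (length(chains) < 2) abort("need at least 2 chains")
  lens <- vapply(chains, nrow, integer(1))
  if (length(unique(lens)) != 1) abort("chains have unequal lengths")
  params <- names(chains[[1]])
  purrr::map_dfr(params, function(p) {
    draws <- vapply(chains, function(ch) as.numeric(ch[[p]]),
                    numeric(lens[1]))
    tibble::tibble(parameter = p, rhat = rhat_stat(draws),
                   ess = ess_stat(draws))
  })
}

rhat_stat <- function(draws) {
  n <- nrow(draws); m <- ncol(draws)
  mu <- colMeans(draws)
  W <- mean(apply(draws, 2, var))
  B <- n * var(mu)
  if (!is.finite(W) || W <= 0) {
    return(if (is.finite(B) && B > 0) Inf else 1)
  }
  max(1, sqrt(((n - 1) / n * W + B / n) / W))
}

ess_stat <- function(draws, max_lag = NULL) {
  n <- nrow(draws); m <- ncol(draws)
  max_lag <- max_lag %||% min(n - 2, 500)
  W <- mean(apply(draws, 2, var))
  if (!is.finite(W) || W <= 0) return(NA_real_)
  rho <- vapply(seq_len(max_lag), function(l) {
    mean(vapply(seq_len(m), function(j) {
      x <- draws[, j]
      sum((x[1:(n - l)] - mean(x)) * (x[(l + 1):n] - mean(x))) / ((n - 1) * var(x))
    }, numeric(1)))
  }, numeric(1))
  s <- 0
  for (l in seq(1, max_lag - 1, by = 2)) {
    pair <- rho[l] + rho[l + 1]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
  }
  max(1, n * m / (1 + 2 * s))
}
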