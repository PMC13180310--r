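# ---- two-state Markov (Mk) machinery ----------------------------------------

# Exact 2x2 transition-probability matrix for rates q12 (state1 -> state2),
# q21 and elapsed time t.
p2_matrix <- function(q12, q21, t) {
  s <- q12 + q21
  if (s <= 0) return(diag(2))
  e <- exp(-s * t)
  matrix(c((q21 + q12 * e) / s, q21 * (1 - e) / s,
           q12 * (1 - e) / s, (q12 + q21 * e) / s), 2, 2)
}

mk_stationary <- function(q12, q21, degenerate_tol = 1e-12) {
  s <- q12 + q21
  if (s <= 0 || min(q12, q21) <= degenerate_tol * s) return(c(0.5, 0.5))
  c(q21, q12) / s
}

# Felsenstein pruning: conditional likelihoods of the data below each node,
# rescaled per node to avoid underflow (log scaling factor accumulated).
mk_down_pass <- function(tree, tip_idx, q12, q21) {
  n <- ape::Ntip(tree)
  down <- matrix(1, n + tree$Nnode, 2)
  down[cbind(seq_len(n), 3 - tip_idx)] <- 0
  po <- ape::reorder.phylo(tree, "postorder")
  eord <- match(paste(po$edge[, 1], po$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  Ps <- lapply(tree$edge.length, p2_matrix, q12 = q12, q21 = q21)
  log_scale <- 0
  for (k in seq_len(nrow(po$edge))) {
    e <- eord[k]
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    down[p, ] <- down[p, ] * as.numeric(Ps[[e]] %*% down[ch, ])
    s <- sum(down[p, ])
    if (s > 0 && s < 1e-12) {
      down[p, ] <- down[p, ] / s
      log_scale <- log_scale + log(s)
    }
  }
  list(down = down, P = Ps, log_scale = log_scale)
}

mk_loglik <- function(tree, tip_idx, q12, q21, pi = NULL) {
  pi <- pi %||% mk_stationary(q12, q21)
  dp <- mk_down_pass(tree, tip_idx, q12, q21)
  lik <- sum(pi * dp$down[ape::Ntip(tree) + 1L, ])
  if (lik <= 0) return(-1e10)
  log(lik) + dp$log_scale
}

mk_model_defs <- function(states) {
  list(
    ER = list(free = 1, expand = function(p) c(p[1], p[1]),
              description = "equal rates"),
    ARD = list(free = 2, expand = function(p) p,
               description = "all rates different"),
    IRR12 = list(free = 1, expand = function(p) c(p[1], 0),
                 description = paste0("irreversible ", states[1], " -> ", states[2])),
    IRR21 = list(free = 1, expand = function(p) c(0, p[1]),
                 description = paste0("irreversible ", states[2], " -> ", states[1]))
  )
}

#' Fit a binary Mk model of discrete-character evolution
#'
#' Maximum-likelihood fit by the pruning algorithm, for one of four candidate
#' transition structures on a binary character: equal rates (`ER`), all rates
#' different (`ARD`), and the two irreversible models (`IRR12`: transitions
#' only from the alphabetically first state to the second; `IRR21`: the
#' reverse). The root prior is the stationary distribution of the fitted rate
#' matrix, falling back to uniform when the chain is degenerate (an
#' irreversible matrix or all-zero rates).
#'
#' @param tree A `phylo` object (branch lengths in MY).
#' @param tip_states Named character vector of binary states at the tips.
#' @param model One of `"ER"`, `"ARD"`, `"IRR12"`, `"IRR21"`.
#' @param rate_bounds Search interval for each rate (per MY).
#' @return An `mk_fit`: `rates` (q12, q21), `Q`, `pi` (root prior), `logLik`,
#'   `k`, `AICc`, `states`.
#' @export
fit_mk <- function(tree, tip_states, model = c("ER", "ARD", "IRR12", "IRR21"),
                   rate_bounds = c(1e-9, 10)) {
  model <- match.arg(model)
  tree <- validate_tree(tree)
  st <- tip_states[tree$tip.label]
  if (anyNA(st)) abort("tip_states must cover all tips")
  states <- sort(unique(as.character(st)))
  if (length(states) > 2) abort("only binary characters are supported")
  n <- ape::Ntip(tree)
  def <- mk_model_defs(if (length(states) == 2) states else c(states, "?"))[[model]]
  if (length(states) == 1) {
    # degenerate data: the ML is at the zero-rate boundary with all mass on
    # the shared state, where the likelihood is exactly 1
    rates <- c(q12 = 0, q21 = 0)
    out <- list(model = model, rates = rates,
                Q = matrix(c(0, 0, 0, 0), 2, 2), pi = c(1, 0),
                logLik = 0, k = def$free, n = n,
                AICc = aicc(0, def$free, n),
                states = c(states, NA_character_), degenerate = TRUE)
    return(structure(out, class = "mk_fit"))
  }
  tip_idx <- match(as.character(st), states)
  nll <- function(logp) {
    q <- def$expand(exp(logp))
    -mk_loglik(tree, tip_idx, q[1], q[2])
  }
  lb <- log(rate_bounds[1]); ub <- log(rate_bounds[2])
  if (def$free == 1) {
    opt <- optimize(nll, c(lb, ub), tol = 1e-9)
    par <- opt$minimum; val <- opt$objective
  } else {
    starts <- list(c(-3, -3), c(-5, -2), c(-2, -5), c(-6, -6), c(-1, -1))
    fits <- lapply(starts, function(s0) {
      optim(s0, nll, method = "L-BFGS-B", lower = lb, upper = ub)
    })
    best <- which.min(vapply(fits, `[[`, numeric(1), "value"))
    par <- fits[[best]]$par; val <- fits[[best]]$value
  }
  if (!is.finite(val)) abort("Mk likelihood optimisation failed to converge")
  q <- def$expand(exp(par))
  pi <- mk_stationary(q[1], q[2])
  Q <- matrix(c(-q[1], q[2], q[1], -q[2]), 2, 2,
              dimnames = list(states, states))
  structure(list(model = model, rates = c(q12 = q[1], q21 = q[2]), Q = Q,
                 pi = pi, logLik = -val, k = def$free, n = n,
                 AICc = aicc(-val, def$free, n), states = states,
                 degenerate = FALSE),
            class = "mk_fit")
}

#' Fit the four candidate Mk models and weight them
#'
#' @inheritParams fit_mk
#' @return An `mk_model_set`: list of `mk_fit`s plus a `table` tibble with
#'   AICc, delta AICc and Akaike weights.
#' @export
fit_mk_models <- function(tree, tip_states, rate_bounds = c(1e-9, 10)) {
  models <- c("ER", "ARD", "IRR12", "IRR21")
  fits <- lapply(models, function(m) fit_mk(tree, tip_states, m, rate_bounds))
  names(fits) <- models
  tab <- tibble::tibble(
    model = models,
    k = vapply(fits, function(f) as.numeric(f$k), numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    AICc = vapply(fits, function(f) f$AICc, numeric(1))
  )
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  w <- exp(-0.5 * tab$delta_AICc)
  tab$weight <- w / sum(w)
  structure(list(fits = fits, table = tab), class = "mk_model_set")
}

#' Marginal ancestral states of a binary character
#'
#' Marginal (empirical-Bayes) state probabilities at each internal node, by
#' the standard inside-outside computation. Given several fitted models, the
#' per-model marginals are averaged by Akaike weight.
#'
#' @param tree A `phylo` object.
#' @param tip_states Named character vector of tip states.
#' @param fit An `mk_fit` or an `mk_model_set` (model-averaged).
#' @return Tibble: `node`, one probability column per state.
#' @export
marginal_ancestral <- function(tree, tip_states, fit) {
  tree <- validate_tree(tree)
  if (inherits(fit, "mk_model_set")) {
    tabs <- Map(function(f, w) {
      m <- marginal_ancestral(tree, tip_states, f)
      m[, -1] <- m[, -1] * w
      m
    }, fit$fits, fit$table$weight[match(names(fit$fits), fit$table$model)])
    out <- tabs[[1]]
    for (t2 in tabs[-1]) out[, -1] <- out[, -1] + t2[, -1]
    return(out)
  }
  states <- fit$states
  st <- tip_states[tree$tip.label]
  n <- ape::Ntip(tree)
  if (isTRUE(fit$degenerate)) {
    out <- tibble::tibble(node = (n + 1L):(n + tree$Nnode))
    out[[states[1]]] <- 1
    return(out)
  }
  tip_idx <- match(as.character(st), states)
  q <- fit$rates
  dp <- mk_down_pass(tree, tip_idx, q[1], q[2])
  down <- dp$down; Ps <- dp$P
  root <- n + 1L
  outside <- matrix(NA_real_, n + tree$Nnode, 2)
  outside[root, ] <- fit$pi
  pre <- ape::reorder.phylo(tree, "cladewise")
  eord <- match(paste(pre$edge[, 1], pre$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  for (k in seq_len(nrow(pre$edge))) {
    e <- eord[k]
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sib_contrib <- c(1, 1)
    for (e2 in children[[as.character(p)]]) {
      if (e2 == e) next
      sib_contrib <- sib_contrib * as.numeric(Ps[[e2]] %*% down[tree$edge[e2, 2], ])
    }
    outside[ch, ] <- as.numeric(crossprod(Ps[[e]], outside[p, ] * sib_contrib))
  }
  nodes <- (n + 1L):(n + tree$Nnode)
  marg <- outside[nodes, , drop = FALSE] * down[nodes, , drop = FALSE]
  marg <- marg / rowSums(marg)
  out <- tibble::tibble(node = nodes)
  out[[states[1]]] <- marg[, 1]
  out[[states[2]]] <- marg[, 2]
  out
}

# sample a CTMC bridge on an edge by uniformization, given endpoint states
sample_bridge <- function(q12, q21, t, a, b) {
  Q <- matrix(c(-q12, q21, q12, -q21), 2, 2)
  omega <- max(q12, q21)
  if (omega <= 0 || t <= 0) return(numeric(0)) # no transitions possible
  R <- diag(2) + Q / omega
  # R^N[a, b] for N = 0..Ncap
  ncap <- max(10, ceiling(omega * t + 10 * sqrt(omega * t) + 20))
  Rpow <- vector("list", ncap + 1)
  Rpow[[1]] <- diag(2)
  for (j in seq_len(ncap)) Rpow[[j + 1]] <- Rpow[[j]] %*% R
  pab <- vapply(Rpow, function(m) m[a, b], numeric(1))
  wts <- stats::dpois(0:ncap, omega * t) * pab
  tot <- sum(wts)
  if (tot <= 0) abort("uniformization failed: endpoint pair has zero probability")
  N <- sample.int(ncap + 1, 1, prob = wts) - 1L
  if (N == 0) return(numeric(0))
  # bridge over the jump chain
  z <- integer(N + 1); z[1] <- a; z[N + 1] <- b
  if (N > 1) {
    for (j in 2:N) {
      pr <- R[z[j - 1], ] * vapply(1:2, function(s) Rpow[[N - j + 2]][s, b], numeric(1))
      z[j] <- sample.int(2, 1, prob = pr)
    }
  }
  times <- sort(runif(N, 0, t))
  real <- which(z[-1] != z[-(N + 1)])
  times[real] # times of actual state changes, in (0, t)
}

#' Stochastic character maps of a binary regime
#'
#' Samples full character histories conditional on the tip data: node states
#' are drawn from their joint conditional distribution and within-edge paths
#' by uniformization bridges, so mapped histories are exact draws (no
#' rejection). With an `mk_model_set`, the model used for each map is chosen
#' with probability equal to its Akaike weight. The summary painting assigns
#' each edge its modal regime (state at the edge midpoint) across maps.
#'
#' @param tree A `phylo` object.
#' @param tip_states Named character vector of tip states.
#' @param fit An `mk_fit` or `mk_model_set`.
#' @param n_maps Number of sampled histories (default 701).
#' @param seed Integer seed.
#' @return A `stochastic_maps` object: list with `maps` (each a
#'   `regime_painting` with `n_transitions` and `model` attributes),
#'   `summary_painting`, and `mean_transitions`.
#' @export
stochastic_map <- function(tree, tip_states, fit, n_maps = 701, seed = 1L) {
  tree <- validate_tree(tree)
  set.seed(seed)
  if (inherits(fit, "mk_model_set")) {
    fits <- fit$fits
    weights <- fit$table$weight[match(names(fits), fit$table$model)]
  } else {
    fits <- list(fit); weights <- 1
  }
  states <- fits[[1]]$states
  st <- tip_states[tree$tip.label]
  n <- ape::Ntip(tree)
  if (all(st == st[1])) {
    maps <- replicate(n_maps, {
      p <- painting_single(tree, st[1])
      attr(p, "n_transitions") <- 0L
      p
    }, simplify = FALSE)
    return(structure(list(maps = maps,
                          summary_painting = painting_single(tree, st[1]),
                          mean_transitions = 0,
                          tip_states = st),
                     class = "stochastic_maps"))
  }
  tip_idx <- match(as.character(st), states)
  pre <- ape::reorder.phylo(tree, "cladewise")
  eord <- match(paste(pre$edge[, 1], pre$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  model_pick <- sample.int(length(fits), n_maps, replace = TRUE, prob = weights)
  down_cache <- lapply(fits, function(f) {
    if (isTRUE(f$degenerate)) return(NULL)
    mk_down_pass(tree, tip_idx, f$rates[1], f$rates[2])
  })
  maps <- vector("list", n_maps)
  mid_state <- matrix(NA_integer_, n_maps, nrow(tree$edge))
  for (m in seq_len(n_maps)) {
    f <- fits[[model_pick[m]]]
    dp <- down_cache[[model_pick[m]]]
    q12 <- f$rates[1]; q21 <- f$rates[2]
    node_state <- integer(n + tree$Nnode)
    node_state[seq_len(n)] <- tip_idx
    pr <- f$pi * dp$down[n + 1L, ]
    node_state[n + 1L] <- sample.int(2, 1, prob = pr)
    segs <- vector("list", nrow(tree$edge))
    n_trans <- 0L
    for (k in seq_len(nrow(pre$edge))) {
      e <- eord[k]
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      len <- tree$edge.length[e]
      if (ch > n) {
        pr <- dp$P[[e]][node_state[p], ] * dp$down[ch, ]
        node_state[ch] <- sample.int(2, 1, prob = pr)
      }
      brk <- sample_bridge(q12, q21, len, node_state[p], node_state[ch])
      n_trans <- n_trans + length(brk)
      ss <- node_state[p]
      seq_states <- integer(length(brk) + 1)
      seq_states[1] <- ss
      for (j in seq_along(brk)) seq_states[j + 1] <- 3 - seq_states[j]
      starts <- c(0, brk); ends <- c(brk, len)
      segs[[e]] <- tibble::tibble(edge = e, start = starts, end = ends,
                                  regime = states[seq_states])
      mid_state[m, e] <- seq_states[findInterval(len / 2, starts)]
    }
    painting <- regime_painting(tree, dplyr::bind_rows(segs), regimes = states)
    attr(painting, "n_transitions") <- n_trans
    attr(painting, "model") <- f$model
    maps[[m]] <- painting
  }
  modal <- apply(mid_state, 2, function(col) {
    as.integer(names(which.max(table(col))))
  })
  summary_painting <- regime_painting(tree, tibble::tibble(
    edge = seq_len(nrow(tree$edge)), start = 0, end = tree$edge.length,
    regime = states[modal]
  ), regimes = states)
  structure(list(
    maps = maps, summary_painting = summary_painting,
    mean_transitions = mean(vapply(maps, function(p) as.numeric(attr(p, "n_transitions")),
                                   numeric(1))),
    tip_states = st
  ), class = "stochastic_maps")
}
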