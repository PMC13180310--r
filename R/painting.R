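#' Regime paintings
#'
#' A regime painting assigns an adaptive regime to every point of every edge
#' of a tree, allowing within-edge breakpoints (e.g., from stochastic character
#' maps, where transitions fall mid-edge). It is stored as a tibble with one
#' row per constant-regime segment: `edge` (row index into `tree$edge`),
#' `start` and `end` (MY from the edge's parent node) and `regime` (character).
#'
#' @param tree The `phylo` object the painting refers to.
#' @param segments A data frame with columns `edge`, `start`, `end`, `regime`.
#' @param regimes Optional character vector declaring the regime label set;
#'   defaults to the labels present.
#' @return A `regime_painting` tibble.
#' @export
regime_painting <- function(tree, segments, regimes = NULL) {
  tree <- validate_tree(tree)
  seg <- tibble::as_tibble(segments)
  stopifnot(all(c("edge", "start", "end", "regime") %in% names(seg)))
  seg <- dplyr::arrange(seg, .data$edge, .data$start)
  len <- tree$edge.length
  for (e in unique(seg$edge)) {
    rows <- seg[seg$edge == e, ]
    if (abs(rows$start[1]) > 1e-8 ||
        abs(rows$end[nrow(rows)] - len[e]) > 1e-8 * max(1, len[e]) ||
        (nrow(rows) > 1 && any(abs(rows$end[-nrow(rows)] - rows$start[-1]) > 1e-8))) {
      abort(sprintf("painting does not cover edge %d contiguously from 0 to its length", e))
    }
    if (any(rows$end < rows$start - 1e-12)) abort(sprintf("negative segment on edge %d", e))
  }
  missing_edges <- setdiff(seq_len(nrow(tree$edge)), unique(seg$edge))
  if (length(missing_edges)) {
    abort(paste0("painting misses edges: ", paste(missing_edges, collapse = ", ")))
  }
  regimes <- regimes %||% unique(seg$regime)
  if (!all(seg$regime %in% regimes)) abort("segment regimes outside declared regime set")
  structure(seg, class = c("regime_painting", class(seg)), regimes = regimes)
}

#' Single-regime painting of a whole tree
#'
#' @param tree A `phylo` object.
#' @param regime Regime label.
#' @return A `regime_painting`.
#' @export
painting_single <- function(tree, regime = "base") {
  tree <- validate_tree(tree)
  regime_painting(tree, tibble::tibble(
    edge = seq_len(nrow(tree$edge)),
    start = 0,
    end = tree$edge.length,
    regime = regime
  ), regimes = regime)
}

#' Paint edges by a discrete state at their child node
#'
#' A quick hypothesis painting (e.g., suborder regimes): each edge takes the
#' state of its child node; internal-node states must be supplied or are
#' propagated from the tips by parsimony-like majority of descendant tips.
#'
#' @param tree A `phylo` object.
#' @param tip_states Named character vector of states, names = tip labels.
#' @param node_states Optional character vector of states for internal nodes
#'   (in node order `Ntip+1 ... Ntip+Nnode`).
#' @return A `regime_painting`.
#' @export
painting_from_tip_states <- function(tree, tip_states, node_states = NULL) {
  tree <- validate_tree(tree)
  st <- tip_states[tree$tip.label]
  if (anyNA(st)) abort("tip_states must cover all tips")
  n <- ape::Ntip(tree)
  if (is.null(node_states)) {
    etm <- edge_tip_matrix(tree)
    node_states <- character(tree$Nnode)
    for (nd in seq_len(tree$Nnode)) {
      e <- which(tree$edge[, 2] == n + nd)
      tips <- if (length(e)) which(etm[e, ]) else seq_len(n) # root: all tips
      tab <- table(st[tips])
      node_states[nd] <- names(tab)[which.max(tab)]
    }
  }
  all_states <- c(st, node_states)
  regime_painting(tree, tibble::tibble(
    edge = seq_len(nrow(tree$edge)),
    start = 0,
    end = tree$edge.length,
    regime = all_states[tree$edge[, 2]]
  ), regimes = sort(unique(all_states)))
}

#' Build a painting from a set of regime shifts
#'
#' Each shift introduces a new regime at a point on an edge (position in MY
#' from the edge's parent node); the regime governs everything downstream of
#' that point until overridden by a nested shift. Everything above the
#' shallowest governing shift keeps `base_regime`.
#'
#' @param tree A `phylo` object.
#' @param shifts Data frame with columns `edge`, `pos`, `regime`.
#' @param base_regime Regime label for the unshifted background.
#' @return A `regime_painting`.
#' @export
painting_from_shifts <- function(tree, shifts, base_regime = "base") {
  tree <- validate_tree(tree)
  anc <- edge_ancestor_matrix(tree)
  pd <- node_depths(tree)[tree$edge[, 1]]
  t_s <- pd[shifts$edge] + shifts$pos
  segs <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    len <- tree$edge.length[e]
    own <- which(shifts$edge == e)
    gov <- base_regime; gt <- -Inf
    for (j in seq_len(nrow(shifts))) {
      if (anc[shifts$edge[j], e] && t_s[j] > gt) {
        gov <- shifts$regime[j]; gt <- t_s[j]
      }
    }
    if (length(own)) {
      own <- own[order(shifts$pos[own])]
      starts <- c(0, shifts$pos[own]); ends <- c(shifts$pos[own], len)
      segs[[e]] <- tibble::tibble(edge = e, start = starts, end = ends,
                                  regime = c(gov, shifts$regime[own]))
    } else {
      segs[[e]] <- tibble::tibble(edge = e, start = 0, end = len, regime = gov)
    }
  }
  regime_painting(tree, dplyr::bind_rows(segs),
                  regimes = unique(c(base_regime, shifts$regime)))
}

#' Regime at each tip under a painting
#'
#' @param tree A `phylo` object.
#' @param painting A `regime_painting`.
#' @return Named character vector of terminal regimes, one per tip.
#' @export
tip_regimes <- function(tree, painting) {
  n <- ape::Ntip(tree)
  term_edge <- match(seq_len(n), tree$edge[, 2])
  out <- vapply(term_edge, function(e) {
    rows <- painting[painting$edge == e, ]
    rows$regime[nrow(rows)]
  }, character(1))
  setNames(out, tree$tip.label)
}

# Time spent in each regime on each edge: E x R matrix.
painting_regime_times <- function(tree, painting) {
  regimes <- attr(painting, "regimes")
  E <- nrow(tree$edge)
  out <- matrix(0, E, length(regimes), dimnames = list(NULL, regimes))
  dt <- painting$end - painting$start
  for (i in seq_len(nrow(painting))) {
    out[painting$edge[i], painting$regime[i]] <-
      out[painting$edge[i], painting$regime[i]] + dt[i]
  }
  out
}

# Per tip: data frame of absolute-time segments (t0, t1, regime), root -> tip.
tip_regime_sequences <- function(tree, painting) {
  depths <- node_depths(tree)
  lins <- lineage_edges(tree)
  ord <- order(painting$edge, painting$start)
  by_edge <- split(seq_len(nrow(painting))[ord], painting$edge[ord])
  e_t0 <- depths[tree$edge[, 1]]
  lapply(seq_len(ape::Ntip(tree)), function(tip) {
    idx <- unlist(by_edge[as.character(lins[[tip]])], use.names = FALSE)
    eg <- painting$edge[idx]
    data.frame(t0 = e_t0[eg] + painting$start[idx],
               t1 = e_t0[eg] + painting$end[idx],
               regime = painting$regime[idx])
  })
}

# Hansen regime weight matrix: n x R, row i gives the weight of each regime's
# optimum in E[y_i] under OU with pull alpha. Rows sum to 1; the pre-root
# weight exp(-alpha * depth_i) is assigned to the regime at the root (both for
# the stationary start and for a fixed root tied to the root regime's optimum).
ou_weight_matrix <- function(tree, painting, alpha, seqs = NULL) {
  regimes <- attr(painting, "regimes")
  n <- ape::Ntip(tree)
  depths <- node_depths(tree)[seq_len(n)]
  # the regime sequences are alpha-independent; callers evaluating many alphas
  # (the ML profile, the rj sampler) precompute them once
  seqs <- seqs %||% tip_regime_sequences(tree, painting)
  root_regime <- vapply(seqs, function(s) s$regime[1], character(1))
  W <- matrix(0, n, length(regimes), dimnames = list(tree$tip.label, regimes))
  for (i in seq_len(n)) {
    s <- seqs[[i]]
    ti <- depths[i]
    if (alpha <= 0) {
      # BM limit: all weight on the root regime (mean never moves)
      W[i, root_regime[i]] <- 1
      next
    }
    w <- exp(-alpha * (ti - s$t1)) - exp(-alpha * (ti - s$t0))
    for (j in seq_len(nrow(s))) W[i, s$regime[j]] <- W[i, s$regime[j]] + w[j]
    W[i, root_regime[i]] <- W[i, root_regime[i]] + exp(-alpha * ti)
  }
  W
}

# Shared path time per regime: list of R matrices V_r with
# sum_r V_r = phylo_vcv(tree). Used by multi-rate BM.
regime_vcv <- function(tree, painting) {
  regimes <- attr(painting, "regimes")
  n <- ape::Ntip(tree)
  rt <- painting_regime_times(tree, painting)
  # regime-time profile from root to each node
  prof <- matrix(0, n + tree$Nnode, length(regimes), dimnames = list(NULL, regimes))
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    eid <- which(tree$edge[, 1] == pre$edge[e, 1] & tree$edge[, 2] == pre$edge[e, 2])
    prof[pre$edge[e, 2], ] <- prof[pre$edge[e, 1], ] + rt[eid, ]
  }
  M <- ape::mrca(tree)
  out <- lapply(regimes, function(r) {
    Vr <- matrix(prof[M, r], n, n, dimnames = list(tree$tip.label, tree$tip.label))
    diag(Vr) <- prof[seq_len(n), r]
    Vr
  })
  names(out) <- regimes
  out
}
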