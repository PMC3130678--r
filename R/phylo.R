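# Tree ingestion, time bookkeeping, contrasts, ancestral states and
# regime painting.  Trees are ape "phylo" objects throughout; tips are
# addressed by label, internal nodes by ape's integer indexing
# (tips 1..n, root n+1, ...).

#' Parse a Newick string into a phylogeny
#'
#' Thin validating wrapper around [ape::read.tree()].  The tree must be
#' rooted, binary, and carry branch lengths (interpreted as time, My).
#'
#' @param text a Newick string.
#' @return an object of class `"phylo"`.
#' @export
read_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr))
    stop_invalid("malformed Newick string: ", substr(text, 1, 60))
  if (is.null(tr$edge.length))
    stop_invalid("Newick string has no branch lengths")
  if (any(tr$edge.length < 0))
    stop_invalid("negative branch lengths")
  if (anyDuplicated(tr$tip.label))
    stop_invalid("duplicate tip labels")
  tr
}

#' Node times measured from the root
#'
#' @param tree a `phylo` object with branch lengths.
#' @return numeric vector over all nodes (tips first, ape ordering), time
#'   from the root in the units of the branch lengths.
#' @export
node_times <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Tree depth (maximum root-to-tip time)
#' @param tree a `phylo` object.
#' @export
tree_depth <- function(tree) max(node_times(tree)[seq_len(ape::Ntip(tree))])

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips,
#' i.e. `t_ij = depth_i + depth_j - 2 * time(MRCA)`.
#'
#' @param tree a `phylo` object.
#' @return symmetric species-by-species matrix with zero diagonal,
#'   dimnames the tip labels.
#' @export
patristic_distances <- function(tree) {
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Times of most recent common ancestors for all tip pairs
#'
#' @param tree a `phylo` object.
#' @return n x n matrix of MRCA times from the root; the diagonal holds
#'   each tip's own depth.
#' @export
mrca_times <- function(tree) {
  n <- ape::Ntip(tree)
  nt <- node_times(tree)
  M <- ape::mrca(tree)              # node indices, n x n
  S <- matrix(nt[M], n, n, dimnames = dimnames(M))
  diag(S) <- nt[seq_len(n)]
  S[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Phylogenetic independent contrasts and the contrast rate matrix
#'
#' Felsenstein's standardized contrasts per trait, plus the evolutionary
#' rate covariance estimated as the cross-products of the contrasts
#' divided by (n - 1).
#'
#' @param tree a `phylo` object.
#' @param traits species-by-trait matrix or data frame; rownames must be
#'   tip labels.
#' @return list with `contrasts` ((n-1) x p) and `rate` (p x p).
#' @export
independent_contrasts <- function(tree, traits) {
  traits <- as.matrix(traits)
  if (is.null(rownames(traits)))
    stop_invalid("traits must have species rownames")
  if (!all(tree$tip.label %in% rownames(traits)))
    stop_invalid("missing tip values for: ",
                 paste(setdiff(tree$tip.label, rownames(traits)), collapse = ", "))
  traits <- traits[tree$tip.label, , drop = FALSE]
  if (anyNA(traits)) stop_invalid("missing trait values")
  pc <- apply(traits, 2L, function(x) ape::pic(x, tree))
  pc <- matrix(pc, ncol = ncol(traits),
               dimnames = list(NULL, colnames(traits)))
  list(contrasts = pc, rate = crossprod(pc) / nrow(pc))
}

#' Maximum-likelihood ancestral states for a continuous trait
#'
#' Brownian-motion ML estimates at internal nodes (equivalently the GLS /
#' re-rooted weighted means); the root estimate equals the BM-GLS grand
#' mean.
#'
#' @param tree a `phylo` object.
#' @param trait named numeric vector over the tips.
#' @return list with `node_values` (named by internal node index).
#' @export
ancestral_continuous_ml <- function(tree, trait) {
  if (is.null(names(trait))) stop_invalid("trait must be named by tip label")
  if (!all(tree$tip.label %in% names(trait)))
    stop_invalid("missing tip values")
  x <- trait[tree$tip.label]
  if (anyNA(x)) stop_invalid("missing trait values")
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  if (any(tree$edge.length <= 0)) {
    z <- tree$edge[tree$edge.length <= 0, , drop = FALSE]
    if (any(z[, 2L] <= n)) stop_invalid("degenerate zero-length pendant branch")
  }
  # the BM ML reconstruction makes every internal node the
  # 1/branch-length weighted mean of its neighbours: a linear system
  L <- matrix(0, m, m)
  b <- numeric(m)
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
    w <- 1 / tree$edge.length[e]
    if (!is.finite(w)) stop_invalid("degenerate zero-length branch")
    iu <- u - n
    L[iu, iu] <- L[iu, iu] + w
    if (v > n) {
      iv <- v - n
      L[iv, iv] <- L[iv, iv] + w
      L[iu, iv] <- L[iu, iv] - w
      L[iv, iu] <- L[iv, iu] - w
    } else {
      b[iu] <- b[iu] + w * x[v]
    }
  }
  nv <- drop(solve(L, b))
  names(nv) <- as.character(n + seq_len(m))
  list(node_values = nv)
}

# --- discrete Mk (equal rates) machinery ------------------------------

# ER transition probability matrix entries for k states, rate q, time t:
# P(same) = 1/k + (k-1)/k exp(-k q t); P(diff) = 1/k - 1/k exp(-k q t)
mk_er_pmat <- function(k, q, t) {
  e <- exp(-k * q * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- (1 + (k - 1) * e) / k
  P
}

# Postorder conditional (downward) likelihoods with scaling.
# Returns list(L = matrix nodes x k, logscale, postorder tree).
mk_er_down <- function(tree, tip_idx, k, q) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  L <- matrix(0, nn, k)
  L[cbind(seq_len(n), tip_idx)] <- 1
  logscale <- 0
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]; t <- po$edge.length[e]
    m <- as.vector(mk_er_pmat(k, q, t) %*% L[ch, ])
    L[par, ] <- if (all(L[par, ] == 0)) m else L[par, ] * m
    s <- max(L[par, ])
    if (s > 0 && s < 1e-100) {
      L[par, ] <- L[par, ] / s
      logscale <- logscale + log(s)
    }
  }
  list(L = L, logscale = logscale, postorder = po)
}

mk_er_loglik <- function(tree, tip_idx, k, q) {
  d <- mk_er_down(tree, tip_idx, k, q)
  root <- ape::Ntip(tree) + 1L
  log(sum(d$L[root, ] / k)) + d$logscale
}

#' Maximum-likelihood ancestral states for a discrete character
#'
#' Equal-rates Mk model: the single transition rate is fitted by maximum
#' likelihood (pruning algorithm), then marginal state probabilities at
#' every internal node are computed by the standard re-rooting
#' (outside-message) recursion under a flat root prior.
#'
#' @param tree a `phylo` object.
#' @param tip_states named character vector or factor over the tips.
#' @param levels optional ordered state labels; defaults to the sorted
#'   observed states.
#' @return list with `node_state_probabilities` (internal nodes x states,
#'   rows sum to 1), `rate` (fitted ER rate), `log_likelihood`, `levels`.
#' @export
ancestral_discrete_ml <- function(tree, tip_states, levels = NULL) {
  if (is.null(names(tip_states)))
    stop_invalid("tip_states must be named by tip label")
  if (!all(tree$tip.label %in% names(tip_states)))
    stop_invalid("missing tip states")
  st <- as.character(tip_states[tree$tip.label])
  levels <- levels %||% sort(unique(st))
  if (!all(st %in% levels)) stop_invalid("tip state outside provided levels")
  k <- length(levels)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  tip_idx <- match(st, levels)

  if (length(unique(st)) == 1L) {
    probs <- matrix(0, tree$Nnode, k, dimnames = list(n + seq_len(tree$Nnode), levels))
    probs[, unique(tip_idx)] <- 1
    return(list(node_state_probabilities = probs, rate = 0,
                log_likelihood = 0, levels = levels))
  }

  nll <- function(lq) -mk_er_loglik(tree, tip_idx, k, exp(lq))
  opt <- stats::optimize(nll, interval = c(log(1e-8), log(1e3)))
  q <- exp(opt$minimum)

  d <- mk_er_down(tree, tip_idx, k, q)
  L <- d$L
  po <- d$postorder
  root <- n + 1L

  # upward (outside) messages, preorder
  up <- matrix(0, nn, k)
  up[root, ] <- 1 / k
  pre <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  prelen <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  for (e in seq_len(nrow(pre))) {
    par <- pre[e, 1L]; ch <- pre[e, 2L]; t <- prelen[e]
    # message from parent side excluding the child's own subtree:
    sib_rows <- which(po$edge[, 1L] == par & po$edge[, 2L] != ch)
    out <- up[par, ]
    for (r in sib_rows) {
      sib <- po$edge[r, 2L]
      P <- mk_er_pmat(k, q, po$edge.length[r])
      out <- out * as.vector(P %*% L[sib, ])
    }
    P <- mk_er_pmat(k, q, t)
    up[ch, ] <- as.vector(t(P) %*% out)
    s <- max(up[ch, ]); if (s > 0) up[ch, ] <- up[ch, ] / s
  }

  marg <- up * L
  marg <- marg / rowSums(marg)
  probs <- marg[n + seq_len(tree$Nnode), , drop = FALSE]
  dimnames(probs) <- list(n + seq_len(tree$Nnode), levels)
  list(node_state_probabilities = probs, rate = q,
       log_likelihood = -opt$objective, levels = levels)
}

# --- regime painting --------------------------------------------------

new_regime_painting <- function(tree, node_states, tip_states, labels,
                                events_per_edge = NULL) {
  n <- ape::Ntip(tree)
  child <- tree$edge[, 2L]
  edge_regime <- ifelse(child <= n,
                        as.character(tip_states[tree$tip.label[child]]),
                        as.character(node_states[as.character(child)]))
  structure(list(edge_regime = edge_regime,
                 regime_labels = labels,
                 tip_states = tip_states[tree$tip.label],
                 node_states = node_states,
                 root_state = as.character(node_states[as.character(n + 1L)]),
                 events_per_edge = events_per_edge),
            class = "regime_painting")
}

#' @export
print.regime_painting <- function(x, ...) {
  cat("Regime painting:", length(x$edge_regime), "branches,",
      length(x$regime_labels), "regimes\n")
  print(table(x$edge_regime))
  cat("root regime:", x$root_state, "\n")
  invisible(x)
}

#' Paint selective regimes onto the branches of a tree
#'
#' Each internal node is assigned its maximum-marginal-probability state
#' from a discrete ancestral estimate; each branch is painted with the
#' state of its child node, so a terminal branch carries the tip's own
#' state.  Ties are broken toward the parent's state (root ties toward
#' the first label in the level order).
#'
#' @param tree a `phylo` object.
#' @param estimate result of [ancestral_discrete_ml()].
#' @param tip_states named character vector of tip states.
#' @return an object of class `"regime_painting"`.
#' @export
paint_regimes <- function(tree, estimate, tip_states) {
  n <- ape::Ntip(tree)
  probs <- estimate$node_state_probabilities
  levels <- estimate$levels
  node_states <- character(tree$Nnode)
  names(node_states) <- as.character(n + seq_len(tree$Nnode))
  tol <- 1e-12
  # preorder so parents resolve before children
  po <- ape::reorder.phylo(tree, "postorder")
  pre_nodes <- c(n + 1L,
                 rev(po$edge[, 2L][po$edge[, 2L] > n]))
  pre_nodes <- unique(pre_nodes)
  parent_of <- integer(n + tree$Nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  for (v in pre_nodes) {
    pr <- probs[as.character(v), ]
    best <- which(pr >= max(pr) - tol)
    if (length(best) > 1L) {
      if (v == n + 1L) best <- best[1L]
      else {
        ps <- node_states[as.character(parent_of[v])]
        best <- if (match(ps, levels) %in% best) match(ps, levels) else best[1L]
      }
    }
    node_states[as.character(v)] <- levels[best[1L]]
  }
  new_regime_painting(tree, node_states, tip_states, levels)
}
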