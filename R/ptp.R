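## Poisson tree processes (single-rate) species delimitation.
##
## Model: every branch is either a "speciation" branch or a
## "within-species coalescent" branch; branch lengths in each class are
## exponential with a class-specific rate estimated by maximum
## likelihood (the class mean). A valid assignment is defined by an
## antichain of "crown" nodes: all branches strictly inside a crown
## node's subtree are coalescent, everything else is speciation. Leaves
## not covered by a crown are singleton species. The search over crown
## sets is heuristic (greedy add/split hill-climbing with restarts).

## exponential ML log-likelihood of n lengths summing to S
.exp_ll <- function(n, S) {
  if (n == 0) return(0)
  S <- max(S, 1e-12)
  n * log(n / S) - n
}

.ptp_precompute <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  kids <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  elen <- numeric(n_node)          # length of edge above each node
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- n_tip + 1L
  ## postorder accumulation of subtree edge counts/sums and DFS intervals
  sub_n <- integer(n_node); sub_s <- numeric(n_node)
  tin <- integer(n_node); tout <- integer(n_node)
  clock <- 0L
  stack <- list(list(node = root, phase = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- top$node
    if (top$phase == 1L) {
      clock <- clock + 1L; tin[v] <- clock
      stack[[length(stack) + 1L]] <- list(node = v, phase = 2L)
      for (c in kids[[v]])
        stack[[length(stack) + 1L]] <- list(node = c, phase = 1L)
    } else {
      clock <- clock + 1L; tout[v] <- clock
      if (length(kids[[v]])) {
        sub_n[v] <- sum(sub_n[kids[[v]]]) + length(kids[[v]])
        sub_s[v] <- sum(sub_s[kids[[v]]], elen[kids[[v]]])
      }
    }
  }
  list(n_tip = n_tip, n_node = n_node, root = root, kids = kids,
       elen = elen, sub_n = sub_n, sub_s = sub_s, tin = tin, tout = tout,
       total_n = nrow(tree$edge), total_s = sum(tree$edge.length))
}

.ptp_ll <- function(pc, crowns) {
  m_c <- sum(pc$sub_n[crowns]); s_c <- sum(pc$sub_s[crowns])
  .exp_ll(m_c, s_c) + .exp_ll(pc$total_n - m_c, pc$total_s - s_c)
}

## BIC-style score: one parameter per rate class plus one per transition
## (crown) node, each costing log(#edges)/2. Without a complexity cost
## the two-class exponential fit improves for almost any crown, so pure
## ML could never return the all-singleton partition on structureless
## trees and would shed tail-length coalescent edges freely.
.ptp_score <- function(pc, crowns) {
  k <- if (length(crowns)) 2 + length(crowns) else 1
  .ptp_ll(pc, crowns) - k * log(pc$total_n) / 2
}

## hill-climb from a crown antichain; moves: add an uncovered internal
## node (absorbing covered descendants), or split a crown into its
## internal children
.ptp_climb <- function(pc, crowns, max_iters) {
  internal <- setdiff(seq_len(pc$n_node), seq_len(pc$n_tip))
  is_desc <- function(a, b) pc$tin[b] < pc$tin[a] & pc$tout[a] < pc$tout[b]
  ll <- .ptp_score(pc, crowns)
  for (iter in seq_len(max_iters)) {
    best_ll <- ll; best_state <- NULL
    covered <- rep(FALSE, pc$n_node)
    for (cr in crowns)
      covered[pc$tin >= pc$tin[cr] & pc$tout <= pc$tout[cr]] <- TRUE
    for (v in internal) {
      if (covered[v]) next
      inside <- crowns[pc$tin[crowns] > pc$tin[v] &
                       pc$tout[crowns] < pc$tout[v]]
      cand <- c(setdiff(crowns, inside), v)
      cll <- .ptp_score(pc, cand)
      if (cll > best_ll + 1e-10) { best_ll <- cll; best_state <- cand }
    }
    for (cr in crowns) {
      reps <- pc$kids[[cr]]
      reps <- reps[reps > pc$n_tip]      # leaf children become singletons
      cand <- c(setdiff(crowns, cr), reps)
      cll <- .ptp_score(pc, cand)
      if (cll > best_ll + 1e-10) { best_ll <- cll; best_state <- cand }
    }
    if (is.null(best_state)) break
    crowns <- best_state; ll <- best_ll
  }
  list(crowns = crowns, score = ll, ll = .ptp_ll(pc, crowns))
}

.ptp_partition <- function(tree, pc, crowns) {
  part <- integer(pc$n_tip)
  pid <- 0L
  for (cr in sort(crowns)) {
    pid <- pid + 1L
    tips <- which(pc$tin[seq_len(pc$n_tip)] > pc$tin[cr] &
                  pc$tout[seq_len(pc$n_tip)] < pc$tout[cr])
    part[tips] <- pid
  }
  for (t in which(part == 0L)) { pid <- pid + 1L; part[t] <- pid }
  stats::setNames(part, tree$tip.label)
}

#' Poisson tree processes (PTP) species delimitation
#'
#' Fits a two-class branch-length model to a rooted tree: speciation
#' branches and within-species coalescent branches, each exponential
#' with its own maximum-likelihood rate, with the coalescent class
#' constrained to whole subtrees (below any speciation-to-coalescent
#' transition all branches are coalescent). The transition-set search
#' is heuristic: greedy hill-climbing from an all-singleton start plus
#' random restarts. Deterministic given \code{seed}.
#'
#' @param tree a rooted \code{phylo} tree with branch lengths in
#'   expected substitutions/site (unrooted input is midpoint-rooted
#'   with a message).
#' @param max_iters hill-climb iteration cap per start, default 200.
#' @param n_restarts random restarts in addition to the greedy start,
#'   default 10.
#' @param seed RNG seed for restarts.
#' @return object of class \code{ptp_delimitation}: list with
#'   \code{partition} (named integer vector leaf -> part id),
#'   \code{n_parts}, \code{log_likelihood}, \code{null_log_likelihood}
#'   (one-class model), \code{method}, \code{params}.
#' @export
ptp_delimit <- function(tree, max_iters = 200, n_restarts = 10, seed = 1) {
  if (length(tree$tip.label) < 2) stop("need >= 2 leaves")
  if (!ape::is.rooted(tree)) {
    message("unrooted input: applying midpoint rooting")
    tree <- midpoint_root(tree)
  }
  pc <- .ptp_precompute(tree)
  if (pc$total_s <= 0) {
    warning("zero-length tree: returning a single part")
    part <- stats::setNames(rep(1L, pc$n_tip), tree$tip.label)
    return(structure(list(partition = part, n_parts = 1L,
                          log_likelihood = NA_real_,
                          null_log_likelihood = NA_real_,
                          method = "ptp", params = list()),
                     class = "ptp_delimitation"))
  }
  internal <- setdiff(seq_len(pc$n_node), seq_len(pc$n_tip))
  best <- .with_seed(seed, {
    b <- .ptp_climb(pc, integer(0), max_iters)
    for (r in seq_len(n_restarts)) {
      ## random antichain: sample nodes, keep maximal ones
      cand <- sample(internal, max(1, floor(length(internal) / 3)))
      keep <- cand
      for (v in cand)
        keep <- keep[!(pc$tin[keep] > pc$tin[v] &
                         pc$tout[keep] < pc$tout[v])]
      res <- .ptp_climb(pc, unique(keep), max_iters)
      if (res$score > b$score) b <- res
    }
    b
  })
  null_ll <- .exp_ll(pc$total_n, pc$total_s)
  part <- .ptp_partition(tree, pc, best$crowns)
  structure(list(partition = part, n_parts = length(unique(part)),
                 log_likelihood = best$ll, null_log_likelihood = null_ll,
                 method = "ptp",
                 params = list(max_iters = max_iters,
                               n_restarts = n_restarts, seed = seed)),
            class = "ptp_delimitation")
}

#' @export
print.ptp_delimitation <- function(x, ...) {
  cat(sprintf("PTP delimitation: %d parts over %d leaves (logL %.3f vs null %.3f)\n",
              x$n_parts, length(x$partition), x$log_likelihood,
              x$null_log_likelihood))
  invisible(x)
}
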