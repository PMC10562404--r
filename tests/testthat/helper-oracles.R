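# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: parsimony steps by exhaustive enumeration of all
# internal-node assignments, diagnosticity by direct definition.

# vectorised exhaustive minimum over all internal state assignments; a tip
# edge costs 0 iff the parent state is in the tip's set
brute_fitch_steps <- function(tree, tip_states, vocabulary) {
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  ns <- length(vocabulary)
  sets <- lapply(tree$tip.label, function(l) {
    s <- as.character(tip_states[[l]])
    if (length(s) == 1L && s == "?") s <- vocabulary
    vocabulary %in% s
  })
  G <- as.matrix(expand.grid(rep(list(seq_len(ns)), nint)))
  cost <- numeric(nrow(G))
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L] - ntip
    child <- tree$edge[k, 2L]
    if (child <= ntip) cost <- cost + !sets[[child]][G[, p]]
    else cost <- cost + (G[, p] != G[, child - ntip])
  }
  min(cost)
}

# random rooted tree, optionally with polytomies, without branch lengths
random_test_tree <- function(n_tips, allow_polytomies = TRUE) {
  t <- ape::rtree(n_tips)
  if (allow_polytomies && n_tips > 3L && stats::runif(1) < 0.5) {
    t$edge.length <- stats::runif(nrow(t$edge))
    internal <- which(t$edge[, 2L] > ape::Ntip(t))
    if (length(internal))
      t$edge.length[sample(internal, min(length(internal),
                                         sample.int(2L, 1L)))] <- 0
    t <- ape::di2multi(t)
  }
  t$edge.length <- NULL
  t
}

# random tip state sets over a vocabulary (polymorphism and unknowns allowed)
random_tip_states <- function(tree, vocabulary, p_poly = 0.2, p_unknown = 0.1) {
  ts <- lapply(tree$tip.label, function(l) {
    if (stats::runif(1) < p_unknown) return("?")
    k <- if (stats::runif(1) < p_poly) min(2L, length(vocabulary)) else 1L
    sample(vocabulary, k)
  })
  names(ts) <- tree$tip.label
  ts
}

# diagnosticity straight from the definition, independent of the package's
# subset search
oracle_is_diagnostic <- function(matrix, taxon, chars) {
  for (other in setdiff(matrix$taxa, taxon)) {
    separated <- any(vapply(chars, function(id)
      !values_overlap(matrix$values[[taxon]][[id]],
                      matrix$values[[other]][[id]]), TRUE))
    if (!separated) return(FALSE)
  }
  TRUE
}
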