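# Rooted-tree handling (ape phylo throughout) and unordered-parsimony
# ancestral-state reconstruction with polytomies (Hartigan generalisation),
# plus synapomorphy detection and homoplasy indices.

#' Parse a Newick tree
#'
#' Thin validated wrapper around [ape::read.tree()]: requires balanced
#' parentheses, labelled unique tips; polytomies are permitted.
#'
#' @param text Newick string or file path.
#' @return A rooted `phylo` object.
#' @export
parse_newick <- function(text) {
  if (length(text) == 1L && !grepl("[();]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  opens <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  closes <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (opens != closes)
    stop("parse_newick: unbalanced parentheses", call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = text), error = function(e)
    stop("parse_newick: ", conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("parse_newick: not a Newick tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("parse_newick: duplicate tip label: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (any(!nzchar(tree$tip.label)))
    stop("parse_newick: unlabelled tip", call. = FALSE)
  tree
}

# children of each node, from the edge matrix
children_of <- function(tree) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  out <- vector("list", n_all)
  for (k in seq_len(nrow(tree$edge)))
    out[[tree$edge[k, 1L]]] <- c(out[[tree$edge[k, 1L]]], tree$edge[k, 2L])
  out
}

# internal nodes in postorder (children before parents)
postorder_nodes <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  unique(po$edge[, 1L])
}

tip_state_matrix <- function(tree, tip_states, vocabulary) {
  ntip <- ape::Ntip(tree)
  M <- matrix(FALSE, nrow = ntip + tree$Nnode, ncol = length(vocabulary),
              dimnames = list(NULL, vocabulary))
  for (i in seq_len(ntip)) {
    lab <- tree$tip.label[i]
    st <- tip_states[[lab]]
    if (is.null(st))
      stop(sprintf("fitch: tip '%s' has no state", lab), call. = FALSE)
    st <- as.character(st)
    if (length(st) == 1L && st == "?") st <- vocabulary
    bad <- setdiff(st, vocabulary)
    if (length(bad))
      stop(sprintf("fitch: tip '%s' has state(s) outside the vocabulary: %s",
                   lab, paste(bad, collapse = ", ")), call. = FALSE)
    M[i, st] <- TRUE
  }
  M
}

#' Unordered-parsimony reconstruction of one character
#'
#' Minimum-change (Fitch) reconstruction of an unordered multistate
#' character on a rooted tree, generalised to polytomies (Hartigan) and to
#' polymorphic or unknown tips, which enter the downpass as multi-state
#' sets. Implemented as a two-pass unit-cost dynamic programme, so the
#' reported per-node sets are exact: `down` holds the states attaining the
#' minimum subtree cost below each node, `up` the states each node takes in
#' at least one most-parsimonious reconstruction of the whole tree.
#'
#' @param tree A rooted `phylo`; polytomies permitted.
#' @param tip_states Named list (or named character vector) giving each tip
#'   its state set; `"?"` means unknown (full vocabulary).
#' @param vocabulary State tokens; defaults to the union of the observed tip
#'   states.
#' @return A `fitch_result`: list with `steps` (minimum number of state
#'   changes), `down` and `up` (per-node state-set lists, tips first in
#'   `tree$tip.label` order then internal nodes in postorder position),
#'   `vocabulary`, `postorder` (internal node indices in postorder) and
#'   `tree`.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' fitch(tr, c(A = "0", B = "0", C = "1", D = "1"))$steps # 1
#' @export
fitch <- function(tree, tip_states, vocabulary = NULL) {
  if (is.character(tip_states) || is.factor(tip_states))
    tip_states <- as.list(stats::setNames(as.character(tip_states),
                                          names(tip_states)))
  if (is.null(vocabulary)) {
    obs <- unlist(tip_states, use.names = FALSE)
    vocabulary <- sort(unique(as.character(obs[obs != "?"])))
  }
  if (length(vocabulary) < 1L)
    stop("fitch: empty vocabulary", call. = FALSE)
  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  ns <- length(vocabulary)
  INF <- 1e9
  M <- tip_state_matrix(tree, tip_states, vocabulary)
  kids <- children_of(tree)
  po <- postorder_nodes(tree)
  root <- po[length(po)]

  # down_cost[v, s]: minimum changes in the subtree below v given v = s
  down_cost <- matrix(INF, n_all, ns)
  down_cost[seq_len(ntip), ] <- ifelse(M[seq_len(ntip), , drop = FALSE], 0, INF)
  # a polymorphic tip can realise any member state at no cost; a change on
  # its edge costs 1 regardless, captured by min(cost, min(cost) + 1) below
  edge_in <- function(costs) pmin(costs, min(costs) + 1)
  for (v in po) {
    acc <- numeric(ns)
    for (c in kids[[v]]) acc <- acc + edge_in(down_cost[c, ])
    down_cost[v, ] <- acc
  }
  steps <- min(down_cost[root, ])

  # up_cost[v, s]: minimum changes outside the subtree of v given v = s
  up_cost <- matrix(0, n_all, ns)
  preorder <- rev(po)
  for (p in preorder) {
    ch <- kids[[p]]
    contrib <- lapply(ch, function(c) edge_in(down_cost[c, ]))
    total_in <- Reduce(`+`, contrib)
    for (i in seq_along(ch)) {
      c <- ch[i]
      # parent cost given parent state t, excluding child c's subtree
      base <- up_cost[p, ] + total_in - contrib[[i]]
      up_cost[c, ] <- vapply(seq_len(ns), function(s)
        min(base + ifelse(seq_len(ns) == s, 0, 1)), 0)
    }
  }

  sets_from <- function(costs) vocabulary[costs <= min(costs)]
  down <- lapply(seq_len(n_all), function(v)
    if (v <= ntip) vocabulary[M[v, ]] else sets_from(down_cost[v, ]))
  up <- lapply(seq_len(n_all), function(v) {
    if (v <= ntip) return(vocabulary[M[v, ]])
    tot <- down_cost[v, ] + up_cost[v, ]
    vocabulary[tot <= steps]
  })
  structure(list(steps = as.integer(round(steps)), down = down, up = up,
                 vocabulary = vocabulary, postorder = po, tree = tree),
            class = "fitch_result")
}

#' @export
print.fitch_result <- function(x, ...) {
  cat(sprintf("<fitch_result: %d steps, %d states, %d tips>\n", x$steps,
              length(x$vocabulary), ape::Ntip(x$tree)))
  invisible(x)
}

#' Export a reconstruction as JSON
#'
#' Per-node state sets keyed by a stable numbering documented in the output
#' header: tips carry their labels, internal nodes are `node<k>` with `k`
#' the 1-based postorder position.
#'
#' @param result A [fitch()] result.
#' @param path Optional output file path.
#' @return JSON text (invisibly when `path` is given).
#' @export
fitch_to_json <- function(result, path = NULL) {
  tree <- result$tree
  ntip <- ape::Ntip(tree)
  keys <- character(ntip + tree$Nnode)
  keys[seq_len(ntip)] <- tree$tip.label
  keys[result$postorder] <- sprintf("node%d", seq_along(result$postorder))
  j <- list(
    header = paste("internal nodes are numbered node1..nodeN in postorder;",
                   "tips carry their labels"),
    steps = result$steps,
    vocabulary = result$vocabulary,
    down = stats::setNames(result$down, keys),
    up = stats::setNames(result$up, keys))
  txt <- as.character(jsonlite::toJSON(j, auto_unbox = TRUE, pretty = TRUE))
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

mrca_node <- function(tree, tips) {
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

descendant_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- children_of(tree)
  acc <- character()
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= ntip) acc <- c(acc, tree$tip.label[v])
    else stack <- c(stack, kids[[v]])
  }
  acc
}

#' Synapomorphy detection for a clade
#'
#' A character is reported as a synapomorphy of the clade when its
#' most-parsimonious state set at the clade's most recent common ancestor
#' contains only states that are derived relative to the outgroup (absent
#' from the outgroup's state set). Because polymorphic tips enter the
#' reconstruction as multi-state sets, they can pull the ancestral state
#' into the ancestor's set and mask a shared derived state; a second tier
#' therefore reports characters for which a single state is (i) present in
#' every clade tip's set, (ii) absent from the outgroup, and (iii) the
#' unique reconstruction at the ancestor once the polymorphic tips are
#' resolved to it — flagged with the polymorphic-tip caveat.
#'
#' @param tree Rooted `phylo` containing the clade and the outgroup tip.
#' @param tip_states_by_char Named list: one entry per character, each a
#'   named list/vector of tip state sets as in [fitch()].
#' @param clade Tip labels of the clade (must be monophyletic in `tree`).
#' @param outgroup Outgroup tip label (outside the clade).
#' @return Data frame with columns `character`, `states` (comma-joined stem
#'   states), `tier` (`"strict"` or `"polymorphism_resolved"`) and
#'   `polymorphic_tips`; zero rows when no character qualifies.
#' @export
synapomorphies <- function(tree, tip_states_by_char, clade, outgroup) {
  if (!outgroup %in% tree$tip.label || outgroup %in% clade)
    stop("synapomorphies: outgroup must be a tree tip outside the clade",
         call. = FALSE)
  node <- mrca_node(tree, clade)
  if (!setequal(descendant_tips(tree, node), clade))
    stop("synapomorphies: clade is not monophyletic in the tree",
         call. = FALSE)
  rows <- list()
  for (char in names(tip_states_by_char)) {
    ts <- tip_states_by_char[[char]]
    if (is.character(ts)) ts <- as.list(ts)
    res <- fitch(tree, ts)
    vocab <- res$vocabulary
    expand <- function(lab) {
      s <- as.character(ts[[lab]])
      if (length(s) == 1L && s == "?") vocab else s
    }
    out_states <- expand(outgroup)
    derived <- setdiff(vocab, out_states)
    if (!length(derived)) next
    F_mrca <- res$up[[node]]
    poly <- clade[vapply(clade, function(l) length(expand(l)) > 1L, TRUE)]
    if (all(F_mrca %in% derived)) {
      rows[[length(rows) + 1L]] <- data.frame(
        character = char, states = paste(F_mrca, collapse = ","),
        tier = "strict", polymorphic_tips = paste(poly, collapse = ","),
        stringsAsFactors = FALSE)
      next
    }
    shared <- Reduce(intersect, lapply(clade, expand), vocab)
    for (s in intersect(shared, derived)) {
      ts2 <- ts
      for (l in poly) ts2[[l]] <- s
      res2 <- fitch(tree, ts2, vocabulary = vocab)
      if (identical(res2$up[[node]], s)) {
        rows[[length(rows) + 1L]] <- data.frame(
          character = char, states = s, tier = "polymorphism_resolved",
          polymorphic_tips = paste(poly, collapse = ","),
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (!length(rows))
    return(data.frame(character = character(), states = character(),
                      tier = character(), polymorphic_tips = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Homoplasy indices per character
#'
#' Consistency index `ci = (k - 1) / steps` for `k` observed states and
#' retention index `ri = (g - s) / (g - m)` with `m = k - 1` and
#' `g = known tips - modal-state frequency` (the maximum steps attainable).
#' Both are `NA` when undefined (constant characters, or `g = m`).
#'
#' @param tree Rooted `phylo`.
#' @param tip_states_by_char Named list of per-character tip state sets (as
#'   in [synapomorphies()]).
#' @return Data frame with columns `character`, `steps`, `k`, `ci`, `ri`.
#' @export
homoplasy <- function(tree, tip_states_by_char) {
  rows <- lapply(names(tip_states_by_char), function(char) {
    ts <- tip_states_by_char[[char]]
    if (is.character(ts)) ts <- as.list(ts)
    res <- fitch(tree, ts)
    vocab <- res$vocabulary
    sets <- lapply(tree$tip.label, function(l) {
      s <- as.character(ts[[l]])
      if (length(s) == 1L && s == "?") vocab else s
    })
    known <- lengths(sets) < length(vocab) | length(vocab) == 1L
    observed <- sort(unique(unlist(sets[known])))
    k <- length(observed)
    s <- res$steps
    freq <- vapply(observed, function(st)
      sum(vapply(sets[known], function(x) st %in% x, TRUE)), 1L)
    g <- if (k) sum(known) - max(freq) else 0L
    m <- max(k - 1L, 0L)
    ci <- if (s > 0L) m / s else NA_real_
    ri <- if (g > m) (g - s) / (g - m) else NA_real_
    data.frame(character = char, steps = s, k = k, ci = ci, ri = ri,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
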