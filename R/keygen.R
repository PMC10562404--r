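# Greedy construction of a dichotomous key from a character matrix.
#
# At each node the generator enumerates binary splits of one character's
# value space (state-subset splits for qualitative characters, integer
# thresholds for counts and for each lobe of a formula). Splits that assign
# every taxon at the node wholly to one side ("exact") are preferred; when a
# node admits none (wide ranges, polymorphism, unknowns), a fallback split
# built from one incompatible taxon pair is used and taxa compatible with
# both sides descend both branches. Ties are broken by character order, then
# by a lexicographic split description, so construction is deterministic.

split_desc <- function(char, kind, what) paste(char, kind, what, sep = "|")

# enumerate candidate splits at a node; each is a list with left/right taxa,
# predicates, n_dup, desc, char_index
node_splits <- function(matrix, taxa, chars) {
  out <- list()
  add <- function(s) out[[length(out) + 1L]] <<- s
  for (ci in seq_along(chars)) {
    id <- chars[ci]
    ch <- matrix$characters[[id]]
    vals <- lapply(taxa, function(tx) matrix$values[[tx]][[id]])
    names(vals) <- taxa
    unknown <- vapply(vals, is_unknown, TRUE)

    assign_sides <- function(in_left, in_right) {
      # in_left/in_right: per-taxon compatibility with each side
      left <- taxa[in_left]; right <- taxa[in_right]
      if (!length(setdiff(left, right)) || !length(setdiff(right, left)))
        return(NULL)
      if (length(union(left, right)) != length(taxa)) return(NULL)
      list(left = left, right = right,
           n_dup = sum(in_left & in_right))
    }

    if (ch$kind == "qualitative" && !any(unknown)) {
      v <- ch$vocabulary
      if (length(v) >= 2L) {
        subsets <- unlist(lapply(seq_len(length(v) - 1L), function(k)
          utils::combn(v, k, simplify = FALSE)), recursive = FALSE)
        subsets <- Filter(function(s) v[1] %in% s, subsets)
        ord <- order(lengths(subsets),
                     vapply(subsets, paste, "", collapse = ","))
        for (S in subsets[ord]) {
          Sc <- setdiff(v, S)
          in_left <- vapply(vals, function(x)
            length(intersect(x$states, S)) > 0L, TRUE)
          in_right <- vapply(vals, function(x)
            length(intersect(x$states, Sc)) > 0L, TRUE)
          sides <- assign_sides(in_left, in_right)
          if (is.null(sides)) next
          add(c(sides, list(
            preds = list(pred_state(id, S), pred_state(id, Sc)),
            char_index = ci,
            desc = split_desc(id, "state", paste(S, collapse = ",")))))
        }
      }
    } else if (ch$kind == "count" && !any(unknown)) {
      los <- vapply(vals, function(x) x$lo, 1L)
      his <- vapply(vals, function(x) x$hi, 1L)
      for (t in sort(unique(his))) {
        if (t >= max(his)) next
        in_left <- los <= t
        in_right <- his > t
        sides <- assign_sides(in_left, in_right)
        if (is.null(sides)) next
        add(c(sides, list(
          preds = list(pred_count(id, min(los), t),
                       pred_count(id, t + 1L, max(his))),
          char_index = ci, desc = split_desc(id, "count", t))))
      }
    } else if (ch$kind == "caudal_formula" && !any(unknown)) {
      for (lobe in c("upper", "lower")) {
        los <- vapply(vals, function(x) x[[lobe]]$lo, 1L)
        his <- vapply(vals, function(x) x[[lobe]]$hi, 1L)
        for (t in sort(unique(his))) {
          if (t >= max(his)) next
          in_left <- los <= t
          in_right <- his > t
          sides <- assign_sides(in_left, in_right)
          if (is.null(sides)) next
          add(c(sides, list(
            preds = list(pred_lobe(id, lobe, min(los), t),
                         pred_lobe(id, lobe, t + 1L, max(his))),
            char_index = ci, desc = split_desc(id, lobe, t))))
        }
      }
    }
  }
  out
}

# fallback: split separating one incompatible pair; other taxa may go both ways
pair_splits <- function(matrix, taxa, chars) {
  out <- list()
  for (ci in seq_along(chars)) {
    id <- chars[ci]
    ch <- matrix$characters[[id]]
    vals <- lapply(taxa, function(tx) matrix$values[[tx]][[id]])
    names(vals) <- taxa
    for (a in taxa) for (b in taxa) {
      if (a >= b) next
      va <- vals[[a]]; vb <- vals[[b]]
      if (is_unknown(va) || is_unknown(vb) || values_overlap(va, vb)) next
      if (ch$kind == "qualitative") {
        S <- va$states; Sc <- setdiff(ch$vocabulary, S)
        preds <- list(pred_state(id, S), pred_state(id, Sc))
        in_left <- vapply(vals, function(x)
          is_unknown(x) || length(intersect(x$states, S)) > 0L, TRUE)
        in_right <- vapply(vals, function(x)
          is_unknown(x) || length(intersect(x$states, Sc)) > 0L, TRUE)
        desc <- split_desc(id, "pair_state", paste(S, collapse = ","))
      } else {
        pick <- function(x, lobe) if (is.null(lobe)) x else x[[lobe]]
        lobe <- NULL
        if (ch$kind == "caudal_formula") {
          lobe <- if (!ranges_overlap(va$upper, vb$upper)) "upper" else "lower"
        }
        ra <- pick(va, lobe); rb <- pick(vb, lobe)
        t <- if (ra$hi < rb$lo) ra$hi else rb$hi
        lo_all <- min(vapply(vals, function(x)
          if (is_unknown(x)) t else pick(x, lobe)$lo, 1L))
        hi_all <- max(vapply(vals, function(x)
          if (is_unknown(x)) t + 1L else pick(x, lobe)$hi, 1L))
        preds <- if (is.null(lobe))
          list(pred_count(id, lo_all, t), pred_count(id, t + 1L, hi_all))
        else list(pred_lobe(id, lobe, lo_all, t),
                  pred_lobe(id, lobe, t + 1L, hi_all))
        in_left <- vapply(vals, function(x)
          is_unknown(x) || pick(x, lobe)$lo <= t, TRUE)
        in_right <- vapply(vals, function(x)
          is_unknown(x) || pick(x, lobe)$hi > t, TRUE)
        desc <- split_desc(id, paste0("pair_", if (is.null(lobe)) "count" else lobe), t)
      }
      left <- taxa[in_left]; right <- taxa[in_right]
      if (!length(setdiff(left, right)) || !length(setdiff(right, left))) next
      out[[length(out) + 1L]] <- list(
        left = left, right = right, n_dup = sum(in_left & in_right),
        preds = preds, char_index = ci, desc = desc)
    }
  }
  out
}

score_split <- function(s, objective) {
  nl <- length(s$left); nr <- length(s$right)
  obj <- if (objective == "minimax-branch") max(nl, nr)
  else nl * log2(max(nl, 1)) + nr * log2(max(nr, 1))
  c(s$n_dup, obj)
}

best_split <- function(splits, objective) {
  stopifnot(length(splits) > 0L)
  scores <- t(vapply(splits, score_split, c(0, 0), objective = objective))
  ord <- order(scores[, 1L], scores[, 2L],
               vapply(splits, function(s) s$char_index, 1L),
               vapply(splits, function(s) s$desc, ""))
  splits[[ord[1L]]]
}

#' Generate a dichotomous key from a character matrix
#'
#' Greedy top-down construction: at each node the (character, binary split)
#' optimising the objective over the taxa compatible with that node is
#' chosen, ties broken by character order then by a lexicographic split
#' description. The result always passes [verify_key()] (every taxon routes
#' uniquely to itself); for matrices where every node admits an exact
#' partition the key has exactly `n - 1` couplets.
#'
#' @param matrix A [morph_matrix()] in which every pair of taxa is
#'   distinguishable by at least one candidate character (checked first).
#' @param objective `"minimax-branch"` (minimise the larger branch) or
#'   `"min-expected-depth"` (minimise an expected-depth proxy).
#' @param chars Candidate character ids (default: all).
#' @return A [dich_key()].
#' @export
generate_key <- function(matrix,
                         objective = c("minimax-branch", "min-expected-depth"),
                         chars = NULL) {
  objective <- match.arg(objective)
  if (is.null(chars)) chars <- names(matrix$characters)
  chk <- unique_combination_check(matrix, chars = chars)
  if (!chk$ok) {
    p <- chk$offending_pairs
    stop("generate_key: indistinguishable taxon pair(s): ",
         paste(sprintf("(%s, %s)", p$taxon_a, p$taxon_b), collapse = ", "),
         "; see pairwise_diffs() for the full report", call. = FALSE)
  }
  if (length(matrix$taxa) < 2L)
    stop("generate_key: need at least two taxa", call. = FALSE)

  couplets <- list()
  next_id <- 0L
  build <- function(taxa) {
    # returns a target: list(taxon=) or list(couplet=)
    if (length(taxa) == 1L) return(list(taxon = taxa))
    splits <- node_splits(matrix, taxa, chars)
    if (!length(splits)) splits <- pair_splits(matrix, taxa, chars)
    if (!length(splits))
      stop("generate_key: no admissible split for node {",
           paste(taxa, collapse = ", "), "}", call. = FALSE)
    s <- best_split(splits, objective)
    next_id <<- next_id + 1L
    id <- next_id
    couplets[[id]] <<- NA  # reserve preorder slot
    t_left <- build(s$left)
    t_right <- build(s$right)
    couplets[[id]] <<- key_couplet(
      id,
      key_lead(s$preds[[1]], couplet = t_left$couplet, taxon = t_left$taxon),
      key_lead(s$preds[[2]], couplet = t_right$couplet, taxon = t_right$taxon))
    list(couplet = id)
  }
  build(matrix$taxa)
  dich_key(couplets, start = 1L)
}
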