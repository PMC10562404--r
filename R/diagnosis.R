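# Diagnosability: pairwise distinguishing characters, unique-combination
# verification, exhaustive minimal diagnostic sets, specimen classification
# with conflict reporting, and panel tallies.

# character ids usable to distinguish a given pair: values must not overlap
distinguishing_chars <- function(matrix, a, b, chars = NULL) {
  if (is.null(chars)) chars <- names(matrix$characters)
  chars[!vapply(chars, function(id)
    values_overlap(matrix$values[[a]][[id]], matrix$values[[b]][[id]]), TRUE)]
}

#' Pairwise distinguishing characters
#'
#' For every unordered pair of taxa, lists the characters on which the two
#' values are incompatible (disjoint ranges / state sets; unknown never
#' distinguishes). Soft-graded characters (pore counts) are listed but
#' separately from the hard diagnostic ones.
#'
#' @param matrix A [morph_matrix()] with at least two taxa.
#' @return A data frame with columns `taxon_a`, `taxon_b`,
#'   `distinguishing` (comma-joined ids, all grades), `hard` (hard-graded
#'   ids only) and `n_hard`.
#' @export
pairwise_diffs <- function(matrix) {
  if (length(matrix$taxa) < 2L)
    stop("pairwise_diffs: need at least two taxa", call. = FALSE)
  hard_ids <- character_ids(matrix, grade = "hard")
  pairs <- utils::combn(matrix$taxa, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    d <- distinguishing_chars(matrix, a, b)
    h <- intersect(d, hard_ids)
    data.frame(taxon_a = a, taxon_b = b,
               distinguishing = paste(d, collapse = ","),
               hard = paste(h, collapse = ","),
               n_hard = length(h), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Check that every taxon has a unique combination of character states
#'
#' `TRUE` iff every pair of taxa is distinguished by at least one character
#' (of any grade); otherwise the indistinguishable pairs are listed.
#'
#' @param matrix A [morph_matrix()].
#' @param chars Optional character-id subset to restrict the check to.
#' @return A list with `ok` (logical) and `offending_pairs` (data frame with
#'   columns `taxon_a`, `taxon_b`; empty when `ok`).
#' @export
unique_combination_check <- function(matrix, chars = NULL) {
  taxa <- matrix$taxa
  bad <- list()
  if (length(taxa) >= 2L) {
    pairs <- utils::combn(taxa, 2L)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      if (!length(distinguishing_chars(matrix, a, b, chars)))
        bad[[length(bad) + 1L]] <- data.frame(taxon_a = a, taxon_b = b,
                                              stringsAsFactors = FALSE)
    }
  }
  offending <- if (length(bad)) do.call(rbind, bad)
  else data.frame(taxon_a = character(), taxon_b = character(),
                  stringsAsFactors = FALSE)
  list(ok = nrow(offending) == 0L, offending_pairs = offending)
}

# is `chars` diagnostic for `taxon`: no other taxon overlaps it on ALL members
is_diagnostic_set <- function(matrix, taxon, chars) {
  others <- setdiff(matrix$taxa, taxon)
  for (o in others) {
    sep <- FALSE
    for (id in chars) {
      if (!values_overlap(matrix$values[[taxon]][[id]],
                          matrix$values[[o]][[id]])) { sep <- TRUE; break }
    }
    if (!sep) return(FALSE)
  }
  TRUE
}

#' Minimal diagnostic character sets for one taxon
#'
#' Exhaustively enumerates all character subsets of size up to `k_max` and
#' returns the minimal ones that separate the focal taxon from every other
#' taxon (a set is diagnostic when for each other taxon at least one member
#' character has non-overlapping values). Characters on which the focal taxon
#' is unknown can never contribute; characters whose focal value carries an
#' uncertainty annotation (e.g. the "9 + 8?" caudal entry) are demoted by
#' default.
#'
#' @param matrix A [morph_matrix()].
#' @param taxon Focal taxon name.
#' @param k_max Largest subset size to enumerate (default 4).
#' @param include_uncertain Allow characters with uncertainty-annotated focal
#'   values (default `FALSE`).
#' @param chars Optional candidate character subset (default: all hard-graded
#'   characters).
#' @return A list of diagnostic sets, each a list with `taxon`, `characters`
#'   (id vector) and `minimal = TRUE`; sorted by size then character order.
#'   Empty list when no diagnostic set exists within `k_max`.
#' @export
minimal_diagnostic_sets <- function(matrix, taxon, k_max = 4L,
                                    include_uncertain = FALSE,
                                    chars = NULL) {
  if (!taxon %in% matrix$taxa)
    stop(sprintf("minimal_diagnostic_sets: taxon '%s' not in matrix", taxon),
         call. = FALSE)
  if (is.null(chars)) chars <- character_ids(matrix, grade = "hard")
  k_max <- as.integer(k_max)
  if (k_max < 1L || k_max > length(matrix$characters))
    stop("minimal_diagnostic_sets: k_max out of range", call. = FALSE)
  usable <- vapply(chars, function(id) {
    v <- matrix$values[[taxon]][[id]]
    if (is_unknown(v)) return(FALSE)
    if (!include_uncertain && inherits(v, "caudal_formula") && v$uncertain)
      return(FALSE)
    TRUE
  }, TRUE)
  chars <- chars[usable]
  found <- list()
  is_superset_of_found <- function(set) {
    for (f in found) if (all(f$characters %in% set)) return(TRUE)
    FALSE
  }
  for (k in seq_len(min(k_max, length(chars)))) {
    combs <- utils::combn(chars, k, simplify = FALSE)
    for (set in combs) {
      if (is_superset_of_found(set)) next
      if (is_diagnostic_set(matrix, taxon, set))
        found[[length(found) + 1L]] <- list(taxon = taxon, characters = set,
                                            minimal = TRUE)
    }
  }
  found
}

#' Classify a specimen against a character matrix
#'
#' For every observed character, computes the set of taxa whose value is
#' compatible with the observation; the overall candidate set is the
#' intersection. A conflict (empty intersection with two or more observed
#' characters) is reported with the characters whose candidate sets are
#' mutually disjoint.
#'
#' @param matrix A [morph_matrix()].
#' @param spec A [specimen()] with at least one observation.
#' @return A `classification` object: list with `specimen`, `per_character`
#'   (named list of candidate taxon vectors), `overall`, `status`
#'   (`"unique"`, `"multiple"` or `"conflict"`) and `conflict_detail`.
#' @export
classify_specimen <- function(matrix, spec) {
  validate_specimen(spec, matrix)
  obs <- spec$observations
  if (!length(obs))
    stop("classify_specimen: specimen has no observations", call. = FALSE)
  per_char <- lapply(names(obs), function(id) {
    matrix$taxa[vapply(matrix$taxa, function(tx)
      compatible(matrix$values[[tx]][[id]], obs[[id]]), TRUE)]
  })
  names(per_char) <- names(obs)
  overall <- Reduce(intersect, per_char, matrix$taxa)
  status <- if (length(overall) == 1L) "unique"
  else if (length(overall) == 0L && length(obs) >= 2L) "conflict"
  else "multiple"
  conflict_detail <- character()
  if (status == "conflict") {
    ids <- names(per_char)
    for (k in seq_along(ids)) for (l in seq_len(k - 1L)) {
      if (!length(intersect(per_char[[k]], per_char[[l]])))
        conflict_detail <- union(conflict_detail, c(ids[l], ids[k]))
    }
    if (!length(conflict_detail)) conflict_detail <- ids
  }
  structure(list(specimen = spec$id, per_character = per_char,
                 overall = overall, status = status,
                 conflict_detail = conflict_detail),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("<classification '%s': %s; candidates {%s}>\n", x$specimen,
              x$status, paste(x$overall, collapse = ", ")))
  if (length(x$conflict_detail))
    cat("  conflicting characters:", paste(x$conflict_detail, collapse = ", "),
        "\n")
  invisible(x)
}

#' Tally a specimen panel against each taxon's diagnostic values
#'
#' For every observed character and every taxon, counts the panel specimens
#' whose observation is compatible with that taxon's value — the arithmetic
#' behind statements like "12 specimens have 8 + 8 branched caudal-fin rays
#' (diagnostic for S. peninsulae)".
#'
#' @param matrix A [morph_matrix()].
#' @param panel A non-empty [specimen_panel()].
#' @return A data frame with columns `character`, `taxon`, `n_match`,
#'   `n_observed`.
#' @export
panel_report <- function(matrix, panel) {
  if (!length(panel$specimens))
    stop("panel_report: empty panel", call. = FALSE)
  for (s in panel$specimens) validate_specimen(s, matrix)
  chars <- unique(unlist(lapply(panel$specimens,
                                function(s) names(s$observations))))
  out <- list()
  for (id in chars) {
    obs <- lapply(panel$specimens, function(s) s$observations[[id]])
    obs <- obs[!vapply(obs, is.null, TRUE)]
    for (tx in matrix$taxa) {
      v <- matrix$values[[tx]][[id]]
      n <- sum(vapply(obs, function(o) compatible(v, o), TRUE))
      out[[length(out) + 1L]] <- data.frame(
        character = id, taxon = tx, n_match = n, n_observed = length(obs),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Look up one tally in a panel report
#' @param report Output of [panel_report()].
#' @param char Character id.
#' @param taxon Taxon name.
#' @return Integer count of matching specimens.
#' @export
panel_tally <- function(report, char, taxon) {
  row <- report[report$character == char & report$taxon == taxon, ]
  if (nrow(row) != 1L)
    stop("panel_tally: no such (character, taxon) entry", call. = FALSE)
  row$n_match
}
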