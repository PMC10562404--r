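# Specimens: partial concrete observations of one individual, and panels
# (named collections) of specimens, with the tab-separated table format.

#' Specimen
#'
#' @param id Specimen label, unique within a panel.
#' @param observations Named list (by character id) of observation objects
#'   ([obs_count()], [obs_state()], [obs_formula()]); unobserved characters
#'   are simply absent.
#' @param provenance Free-text provenance (lot, collection, locality).
#' @return An object of class `specimen`.
#' @export
specimen <- function(id, observations = list(), provenance = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("specimen: id must be a non-empty string", call. = FALSE)
  if (length(observations) &&
      (is.null(names(observations)) || any(!nzchar(names(observations)))))
    stop("specimen: observations must be named by character id", call. = FALSE)
  ok <- vapply(observations, function(o)
    inherits(o, c("obs_count", "obs_state", "obs_formula")), TRUE)
  if (!all(ok))
    stop("specimen: observations must be observation objects", call. = FALSE)
  structure(list(id = id, observations = observations,
                 provenance = provenance), class = "specimen")
}

#' @export
print.specimen <- function(x, ...) {
  cat(sprintf("<specimen '%s': %d observation(s)>\n", x$id,
              length(x$observations)))
  for (id in names(x$observations))
    cat("  ", id, " = ", format_observation(x$observations[[id]]), "\n",
        sep = "")
  invisible(x)
}

#' Specimen panel
#'
#' @param name Panel label.
#' @param specimens List of [specimen()] objects with unique ids.
#' @param notes Provenance text for the panel.
#' @return An object of class `specimen_panel`.
#' @export
specimen_panel <- function(name, specimens = list(), notes = "") {
  ids <- vapply(specimens, function(s) s$id, "")
  if (anyDuplicated(ids))
    stop("specimen_panel: duplicate specimen id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  structure(list(name = name, specimens = specimens, notes = notes),
            class = "specimen_panel")
}

#' @export
print.specimen_panel <- function(x, ...) {
  cat(sprintf("<specimen_panel '%s': %d specimen(s)>\n", x$name,
              length(x$specimens)))
  invisible(x)
}

#' @export
length.specimen_panel <- function(x) length(x$specimens)

#' Check specimen observations against a companion matrix
#'
#' Errors when a specimen observes a character absent from the matrix or
#' with an observation of the wrong kind.
#'
#' @param spec A [specimen()].
#' @param matrix A [morph_matrix()].
#' @return `TRUE`, invisibly.
#' @export
validate_specimen <- function(spec, matrix) {
  for (id in names(spec$observations)) {
    if (!id %in% names(matrix$characters))
      stop(sprintf("specimen '%s': observed character '%s' not in matrix",
                   spec$id, id), call. = FALSE)
    kind <- matrix$characters[[id]]$kind
    o <- spec$observations[[id]]
    ok <- (kind == "count" && inherits(o, "obs_count")) ||
      (kind == "caudal_formula" && inherits(o, "obs_formula")) ||
      (kind == "qualitative" && inherits(o, "obs_state"))
    if (!ok)
      stop(sprintf("specimen '%s': observation kind mismatch for '%s'",
                   spec$id, id), call. = FALSE)
  }
  invisible(TRUE)
}

#' Parse a delimited specimen table
#'
#' Tab-separated: row 1 is `specimen` followed by character ids; each further
#' row one specimen. Cells follow [parse_observation()]; `?` (or empty) means
#' unobserved.
#'
#' @param text A file path or the document itself.
#' @param matrix Companion [morph_matrix()] supplying character kinds.
#' @param name Panel name (defaults to `"panel"`).
#' @param notes Panel provenance text.
#' @return A [specimen_panel()].
#' @export
parse_specimens <- function(text, matrix, name = "panel", notes = "") {
  lines <- read_tsv_lines(text)
  if (!length(lines)) stop("parse_specimens: empty document", call. = FALSE)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  ids <- trimws(rows[[1]])[-1]
  bad <- setdiff(ids, names(matrix$characters))
  if (length(bad))
    stop("parse_specimens: unknown character id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  kinds <- vapply(matrix$characters[ids], function(ch) ch$kind, "")
  specs <- lapply(rows[-1], function(r) {
    sid <- trimws(r[1])
    r <- c(r, rep("?", max(0L, length(ids) + 1L - length(r))))
    obs <- list()
    for (j in seq_along(ids)) {
      o <- parse_observation(trimws(r[j + 1L]), kinds[j],
                             sprintf("(specimen '%s', column '%s')", sid, ids[j]))
      if (!is.null(o)) obs[[ids[j]]] <- o
    }
    specimen(sid, obs)
  })
  panel <- specimen_panel(name, specs, notes = notes)
  for (s in specs) validate_specimen(s, matrix)
  panel
}

#' Serialise a specimen panel to its delimited table
#'
#' @param panel A [specimen_panel()].
#' @param matrix Companion [morph_matrix()] fixing the column order.
#' @param path Optional output file path.
#' @return The document as a single string.
#' @export
write_specimens <- function(panel, matrix, path = NULL) {
  ids <- names(matrix$characters)
  observed <- unique(unlist(lapply(panel$specimens,
                                   function(s) names(s$observations))))
  ids <- ids[ids %in% observed]
  header <- paste(c("specimen", ids), collapse = "\t")
  rows <- vapply(panel$specimens, function(s) {
    cells <- vapply(ids, function(id) {
      o <- s$observations[[id]]
      if (is.null(o)) "?" else format_observation(o)
    }, "")
    paste(c(s$id, cells), collapse = "\t")
  }, "")
  doc <- paste(c(header, rows), collapse = "\n")
  if (!is.null(path)) { writeLines(doc, path); return(invisible(doc)) }
  doc
}
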