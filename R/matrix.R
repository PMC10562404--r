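# Character definitions and the taxa x characters matrix, with the
# tab-separated external format and a NEXUS DATA-block writer.

#' Character definition
#'
#' @param id Short stable token, e.g. `"pectoral_rays"`.
#' @param label Human-readable name.
#' @param kind One of `"qualitative"`, `"count"`, `"caudal_formula"`.
#' @param vocabulary Ordered state tokens (qualitative characters only).
#' @param description Free text.
#' @param grade Diagnostic grade, `"hard"` (usable for diagnosis and key
#'   routing) or `"soft"` (recorded but known to vary too much between
#'   observers/samples to diagnose species, e.g. cephalic pore counts).
#' @return An object of class `character_def`.
#' @export
character_def <- function(id, label = id, kind, vocabulary = character(),
                          description = "", grade = "hard") {
  kind <- match.arg(kind, c("qualitative", "count", "caudal_formula"))
  grade <- match.arg(grade, c("hard", "soft"))
  if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", id))
    stop(sprintf("character_def: invalid id '%s'", id), call. = FALSE)
  vocabulary <- as.character(vocabulary)
  if (kind == "qualitative") {
    if (length(vocabulary) < 1L || anyDuplicated(vocabulary))
      stop(sprintf("character '%s': qualitative vocabulary must be non-empty and duplicate-free",
                   id), call. = FALSE)
  } else if (length(vocabulary))
    stop(sprintf("character '%s': only qualitative characters take a vocabulary",
                 id), call. = FALSE)
  structure(list(id = id, label = label, kind = kind,
                 vocabulary = vocabulary, description = description,
                 grade = grade),
            class = "character_def")
}

check_value_kind <- function(value, kind, where) {
  ok <- is_unknown(value) ||
    (kind == "count" && inherits(value, "count_range")) ||
    (kind == "caudal_formula" && inherits(value, "caudal_formula")) ||
    (kind == "qualitative" && inherits(value, "state_set"))
  if (!ok) stop(sprintf("value kind does not match character kind '%s' %s",
                        kind, where), call. = FALSE)
  invisible(TRUE)
}

#' Character matrix of taxa by morphological characters
#'
#' @param characters List of [character_def()] objects (ordered).
#' @param taxa Character vector of unique taxon names (ordered).
#' @param values Named list (by taxon) of named lists (by character id) of
#'   cell values; every taxon must have a value (possibly unknown) for every
#'   character, matching the character's kind, and qualitative states must be
#'   drawn from the character's vocabulary.
#' @param taxon_meta Optional data frame with column `taxon` and per-taxon
#'   metadata columns (e.g. `has_molecular_data`, `newly_described`, `notes`).
#' @return An object of class `morph_matrix`.
#' @export
morph_matrix <- function(characters, taxa, values, taxon_meta = NULL) {
  ids <- vapply(characters, function(ch) ch$id, "")
  if (anyDuplicated(ids))
    stop("morph_matrix: duplicate character ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa))
    stop("morph_matrix: duplicate taxon name: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "), call. = FALSE)
  if (!setequal(names(values), taxa) || length(values) != length(taxa))
    stop("morph_matrix: values must be a named list with one entry per taxon",
         call. = FALSE)
  values <- values[taxa]
  chmap <- stats::setNames(characters, ids)
  for (tx in taxa) {
    row <- values[[tx]]
    missing <- setdiff(ids, names(row))
    if (length(missing))
      stop(sprintf("taxon '%s': missing value for character(s) %s", tx,
                   paste(missing, collapse = ", ")), call. = FALSE)
    extra <- setdiff(names(row), ids)
    if (length(extra))
      stop(sprintf("taxon '%s': value for undeclared character(s) %s", tx,
                   paste(extra, collapse = ", ")), call. = FALSE)
    for (id in ids) {
      v <- row[[id]]
      where <- sprintf("(taxon '%s', character '%s')", tx, id)
      check_value_kind(v, chmap[[id]]$kind, where)
      if (inherits(v, "state_set")) {
        bad <- setdiff(v$states, chmap[[id]]$vocabulary)
        if (length(bad))
          stop(sprintf("state token(s) %s outside vocabulary %s",
                       paste(bad, collapse = ", "), where), call. = FALSE)
      }
    }
    values[[tx]] <- row[ids]
  }
  if (is.null(taxon_meta))
    taxon_meta <- data.frame(taxon = taxa, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(taxon_meta), "taxon" %in% names(taxon_meta))
  taxon_meta <- taxon_meta[match(taxa, taxon_meta$taxon), , drop = FALSE]
  rownames(taxon_meta) <- NULL
  structure(list(characters = chmap, taxa = taxa, values = values,
                 taxon_meta = taxon_meta),
            class = "morph_matrix")
}

#' @export
print.morph_matrix <- function(x, ...) {
  cat(sprintf("<morph_matrix: %d taxa x %d characters>\n",
              length(x$taxa), length(x$characters)))
  cat("  taxa:", paste(utils::head(x$taxa, 6L), collapse = ", "),
      if (length(x$taxa) > 6L) "..." else "", "\n")
  cat("  characters:", paste(utils::head(names(x$characters), 6L),
                             collapse = ", "),
      if (length(x$characters) > 6L) "..." else "", "\n")
  invisible(x)
}

#' Character ids of a matrix
#' @param matrix A [morph_matrix()].
#' @param grade Optional filter, `"hard"` or `"soft"`.
#' @return Character vector of ids.
#' @export
character_ids <- function(matrix, grade = NULL) {
  ids <- names(matrix$characters)
  if (!is.null(grade))
    ids <- ids[vapply(matrix$characters, function(ch) ch$grade, "") == grade]
  ids
}

#' Look up one cell value
#' @param matrix A [morph_matrix()].
#' @param taxon Taxon name.
#' @param char Character id.
#' @return The cell value object.
#' @export
matrix_value <- function(matrix, taxon, char) {
  if (!taxon %in% matrix$taxa)
    stop(sprintf("taxon '%s' not in matrix", taxon), call. = FALSE)
  if (!char %in% names(matrix$characters))
    stop(sprintf("character '%s' not in matrix", char), call. = FALSE)
  matrix$values[[taxon]][[char]]
}

# --- TSV reader/writer ------------------------------------------------------

infer_kind <- function(cells) {
  cells <- trimws(normalise_dashes(cells))
  cells <- cells[!(cells %in% c("?", "-", ""))]
  if (!length(cells)) return("qualitative")
  if (all(grepl("^/.*\\+.*/$", cells))) return("caudal_formula")
  if (all(grepl("^[0-9]+(\\s*-\\s*[0-9]+)?$", cells))) return("count")
  "qualitative"
}

read_tsv_lines <- function(text) {
  lines <- if (length(text) == 1L && (grepl("\n", text) || !file.exists(text)))
    strsplit(text, "\n", fixed = TRUE)[[1]] else readLines(text, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines[nzchar(trimws(lines))]
}

#' Parse a delimited character-matrix document
#'
#' The format is UTF-8 tab-separated values: row 1 holds character ids
#' (first cell empty or `taxon`), each further row one taxon. Cells follow
#' the grammar of [parse_cell()]. Lines starting with `#` are comments.
#'
#' @param text A file path, or the document itself (single string with
#'   newlines).
#' @param characters Optional list of [character_def()] declaring kinds and
#'   closed vocabularies. When omitted, kinds are inferred from the cells and
#'   qualitative vocabularies are the observed tokens.
#' @param taxon_meta Optional per-taxon metadata data frame (see
#'   [morph_matrix()]).
#' @return A validated [morph_matrix()].
#' @export
parse_matrix <- function(text, characters = NULL, taxon_meta = NULL) {
  lines <- read_tsv_lines(text)
  if (!length(lines)) stop("parse_matrix: empty document", call. = FALSE)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(rows[[1]])
  ids <- header[-1]
  if (!length(ids)) stop("parse_matrix: header row has no character ids",
                         call. = FALSE)
  body <- rows[-1]
  taxa <- vapply(body, function(r) trimws(r[1]), "")
  if (anyDuplicated(taxa))
    stop("parse_matrix: duplicate taxon name: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "), call. = FALSE)
  cells <- lapply(body, function(r) {
    r <- c(r, rep("?", max(0L, length(ids) + 1L - length(r))))
    trimws(r[seq_along(ids) + 1L])
  })
  if (is.null(characters)) {
    characters <- lapply(seq_along(ids), function(j) {
      col <- vapply(cells, `[[`, "", j)
      kind <- infer_kind(col)
      vocab <- character()
      if (kind == "qualitative") {
        toks <- unlist(strsplit(normalise_dashes(col), "/", fixed = TRUE))
        toks <- trimws(toks)
        vocab <- sort(unique(toks[!(toks %in% c("?", "-", ""))]))
        if (!length(vocab)) vocab <- "unknown_state"
      }
      character_def(ids[j], kind = kind, vocabulary = vocab)
    })
  } else {
    have <- vapply(characters, function(ch) ch$id, "")
    if (!identical(sort(have), sort(ids)) &&
        !all(ids %in% have))
      stop("parse_matrix: header ids not covered by supplied character definitions: ",
           paste(setdiff(ids, have), collapse = ", "), call. = FALSE)
    characters <- stats::setNames(characters, have)[ids]
  }
  kinds <- vapply(characters, function(ch) ch$kind, "")
  values <- stats::setNames(vector("list", length(taxa)), taxa)
  for (i in seq_along(taxa)) {
    row <- stats::setNames(vector("list", length(ids)), ids)
    for (j in seq_along(ids)) {
      where <- sprintf("(row %d '%s', column '%s')", i + 1L, taxa[i], ids[j])
      row[[j]] <- parse_cell(cells[[i]][j], kinds[j], where)
    }
    values[[i]] <- row
  }
  morph_matrix(characters, taxa, values, taxon_meta = taxon_meta)
}

#' Serialise a character matrix to its delimited document
#'
#' Inverse of [parse_matrix()] (round-trip identity when re-parsed with the
#' same character definitions). Ranges are emitted with a plain hyphen.
#'
#' @param matrix A [morph_matrix()].
#' @param path Optional file path; when given the document is also written
#'   there.
#' @return The document as a single string (invisibly when `path` is given).
#' @export
write_matrix <- function(matrix, path = NULL) {
  ids <- names(matrix$characters)
  header <- paste(c("taxon", ids), collapse = "\t")
  rows <- vapply(matrix$taxa, function(tx) {
    paste(c(tx, vapply(ids, function(id)
      format_value(matrix$values[[tx]][[id]]), "")), collapse = "\t")
  }, "")
  doc <- paste(c(header, rows), collapse = "\n")
  if (!is.null(path)) { writeLines(doc, path); return(invisible(doc)) }
  doc
}

# --- NEXUS writer -----------------------------------------------------------

#' Write a NEXUS DATA block for coded character strings
#'
#' Emits a syntactically valid NEXUS document with a single DATA block
#' (`DATATYPE=STANDARD`, `MISSING=?`), suitable for external phylogenetic
#' tools. Polymorphic cells are brace sets (`{01}`) and are preserved
#' verbatim.
#'
#' @param codes Named character vector of per-taxon code strings, all of the
#'   same length (braces count as one position).
#' @param path Optional output file path.
#' @param symbols Symbols declared in the FORMAT line; default is the set of
#'   digits used.
#' @return The NEXUS document as a single string (invisibly when `path` is
#'   given).
#' @export
write_nexus <- function(codes, path = NULL, symbols = NULL) {
  if (is.null(names(codes)) || any(!nzchar(names(codes))))
    stop("write_nexus: codes must be a named character vector", call. = FALSE)
  split_positions <- function(s) {
    out <- character(); i <- 1L; n <- nchar(s)
    while (i <= n) {
      ch <- substr(s, i, i)
      if (ch == "{") {
        j <- regexpr("}", substr(s, i, n), fixed = TRUE)
        if (j < 0L) stop("write_nexus: unbalanced brace in code", call. = FALSE)
        out <- c(out, substr(s, i, i + j - 1L)); i <- i + j
      } else { out <- c(out, ch); i <- i + 1L }
    }
    out
  }
  pos <- lapply(codes, split_positions)
  nchar_each <- lengths(pos)
  if (length(unique(nchar_each)) != 1L)
    stop("write_nexus: unequal code lengths: ",
         paste(sprintf("%s=%d", names(codes), nchar_each), collapse = ", "),
         call. = FALSE)
  nch <- nchar_each[[1]]
  if (is.null(symbols)) {
    used <- sort(unique(unlist(strsplit(gsub("[{}?]", "", codes), ""))))
    symbols <- if (length(used)) used else "0"
  }
  labels <- gsub("[^A-Za-z0-9_.]", "_", names(codes))
  pad <- max(nchar(labels))
  doc <- paste(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(codes), nch),
    sprintf("  FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"%s\";",
            paste(symbols, collapse = "")),
    "  MATRIX",
    sprintf("    %-*s  %s", pad, labels, unname(codes)),
    "  ;",
    "END;"), collapse = "\n")
  if (!is.null(path)) { writeLines(doc, path); return(invisible(doc)) }
  doc
}
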