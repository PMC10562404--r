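# Packaged in-paper datasets for the Schistura cincticauda species group:
# the character comparison table, the morphocode scheme, the printed
# identification key, the Phuket/MCZ specimen panels and the constraints-only
# species tree.

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "morphokey")
  if (!nzchar(p)) stop("fixture not found: ", name, call. = FALSE)
  p
}

#' The twelve species of the group
#' @return Character vector of the 12 taxon names in fixture order.
#' @export
group_taxa <- function() {
  c("Schistura_aurantiaca", "Schistura_balteata", "Schistura_cincticauda",
    "Schistura_crocotula", "Schistura_hartli", "Schistura_ataranensis",
    "Schistura_myaekanbawensis", "Schistura_kuehnei", "Schistura_robertsi",
    "Schistura_paucifasciata", "Schistura_peninsulae", "Schistura_tenebrosa")
}

#' Load the packaged character comparison table
#'
#' The 12 taxa x 18 characters matrix of selected morphological characters
#' of the species group, with closed qualitative vocabularies, diagnostic
#' grades and per-taxon metadata (molecular data availability, newly
#' described flag, literature-derived flag, discrepancy notes).
#'
#' @return A validated [morph_matrix()].
#' @export
load_table1 <- function() {
  defs <- jsonlite::fromJSON(fixture_path("table1_characters.json"),
                             simplifyVector = FALSE)
  characters <- lapply(defs$characters, function(d)
    character_def(d$id, label = d$label, kind = d$kind,
                  vocabulary = unlist(d$vocabulary),
                  description = d$description, grade = d$grade))
  meta <- jsonlite::fromJSON(fixture_path("table1_taxa.json"),
                             simplifyVector = FALSE)
  taxon_meta <- do.call(rbind, lapply(meta$taxa, function(t)
    data.frame(taxon = t$taxon, has_molecular_data = t$has_molecular_data,
               newly_described = t$newly_described,
               literature_derived = t$literature_derived, notes = t$notes,
               stringsAsFactors = FALSE)))
  parse_matrix(fixture_path("table1.tsv"), characters = characters,
               taxon_meta = taxon_meta)
}

#' Load the morphocode scheme
#'
#' The 12 integer-coded characters A-L with their state legends and the
#' mappings from matrix values to state codes; character L (body bars) is
#' shipped as direct per-taxon assignments derived from the species
#' Diagnoses.
#'
#' @return A `morphocode_scheme` object (list with `characters`, each
#'   holding `code`, `source`, `legend` and either `states` mappings or a
#'   `direct` table).
#' @export
load_morphocode <- function() {
  j <- jsonlite::fromJSON(fixture_path("morphocode.json"),
                          simplifyVector = FALSE)
  chars <- lapply(j$characters, function(ch) {
    ch$states <- lapply(ch$states, function(st) {
      if (!is.null(st$values)) st$values <- as.integer(unlist(st$values))
      if (!is.null(st$states)) st$states <- sort(unlist(st$states))
      if (!is.null(st$formula)) st$formula <- as.integer(unlist(st$formula))
      st
    })
    if (!is.null(ch$direct)) ch$direct <- unlist(ch$direct)
    ch
  })
  names(chars) <- vapply(chars, function(ch) ch$code, "")
  structure(list(characters = chars), class = "morphocode_scheme")
}

#' @export
print.morphocode_scheme <- function(x, ...) {
  cat(sprintf("<morphocode_scheme: %d characters (%s)>\n",
              length(x$characters),
              paste(names(x$characters), collapse = "")))
  invisible(x)
}

# map one matrix value through one scheme character; returns list(symbol,
# warning or NULL)
map_value <- function(value, ch, taxon) {
  if (is_unknown(value))
    return(list(symbol = "?", warning = NULL))
  value_set <- function(st) {
    if (!is.null(st$values)) return(st$values)
    if (!is.null(st$states)) return(st$states)
    st$formula
  }
  if (inherits(value, "state_set")) {
    for (st in ch$states)
      if (identical(sort(st$states), value$states))
        return(list(symbol = st$code, warning = NULL))
    hits <- unique(unlist(lapply(ch$states, function(st)
      if (length(intersect(st$states, value$states))) st$code)))
  } else if (inherits(value, "count_range")) {
    vals <- value$lo:value$hi
    for (st in ch$states)
      if (all(vals %in% st$values))
        return(list(symbol = st$code, warning = NULL))
    hits <- unique(unlist(lapply(ch$states, function(st)
      if (any(vals %in% st$values)) st$code)))
  } else { # caudal_formula
    pairs <- expand.grid(u = value$upper$lo:value$upper$hi,
                         l = value$lower$lo:value$lower$hi)
    match_st <- function(st) pairs$u == st$formula[1] & pairs$l == st$formula[2]
    covered <- Reduce(`|`, lapply(ch$states, match_st), rep(FALSE, nrow(pairs)))
    if (all(covered) && nrow(pairs) >= 1L) {
      hit <- unique(unlist(lapply(ch$states, function(st)
        if (any(match_st(st))) st$code)))
      if (length(hit) == 1L) return(list(symbol = hit, warning = NULL))
    }
    hits <- unique(unlist(lapply(ch$states, function(st)
      if (any(match_st(st))) st$code)))
  }
  value_txt <- format_value(value)
  if (!length(hits))
    return(list(symbol = "?", warning = sprintf(
      "%s, character %s: value %s matches no legend state", taxon, ch$code,
      value_txt)))
  symbol <- if (length(hits) == 1L) hits
  else paste0("{", paste(sort(hits), collapse = ""), "}")
  list(symbol = symbol, warning = sprintf(
    "%s, character %s: value %s is not a legend state; resolved to %s by range overlap",
    taxon, ch$code, value_txt, symbol))
}

#' Derive per-taxon morphocode strings from a matrix
#'
#' One symbol per scheme character per taxon. Matrix values that are not
#' legend states are resolved by the range-overlap rule: the legend state(s)
#' whose value sets intersect the matrix value, a brace set when several
#' intersect, `?` when none — each with a warning naming taxon, character
#' and offending value. Unknown matrix cells code as `?` without warning.
#'
#' @param matrix A [morph_matrix()] covering the scheme's source characters.
#' @param scheme A [load_morphocode()] scheme.
#' @return A list with `codes` (named character vector, one string per
#'   taxon) and `warnings` (character vector).
#' @export
derive_morphocode <- function(matrix, scheme = load_morphocode()) {
  warnings <- character()
  codes <- vapply(matrix$taxa, function(tx) {
    symbols <- vapply(scheme$characters, function(ch) {
      if (!is.null(ch$direct)) {
        return(if (tx %in% names(ch$direct)) ch$direct[[tx]] else ch$default)
      }
      if (!ch$source %in% names(matrix$characters))
        stop(sprintf("derive_morphocode: matrix lacks source character '%s'",
                     ch$source), call. = FALSE)
      m <- map_value(matrix$values[[tx]][[ch$source]], ch, tx)
      if (!is.null(m$warning)) warnings <<- c(warnings, m$warning)
      m$symbol
    }, "")
    paste(symbols, collapse = "")
  }, "")
  list(codes = codes, warnings = warnings)
}

#' Load the printed identification key
#'
#' The dichotomous key to the species of the group: couplets 1-11 encoded as
#' predicate pairs with 12 distinct terminal taxa. Statements about body
#' colour pattern, live coloration or geography are soft predicates.
#'
#' @return A [dich_key()].
#' @export
load_key <- function() key_from_json(fixture_path("key_cincticauda.json"))

#' Load the specimen panels
#'
#' Three panels: the 20 ZRC Phuket specimens (all with 8 pectoral rays; 8
#' with a caudal formula diagnostic for S. robertsi, 12 with the 8+8 formula
#' diagnostic for S. peninsulae), the 8 MCZ paratypes of S. robertsi from
#' Phuket (4 with 7+8, 4 with 8+8) and the re-examined S. robertsi holotype
#' (caudal 7+7, pectoral rays 8 and 7).
#'
#' @param matrix Companion matrix (defaults to [load_table1()]).
#' @return Named list of three [specimen_panel()] objects: `zrc_phuket`,
#'   `mcz_paratypes`, `robertsi_holotype`.
#' @export
load_specimen_panels <- function(matrix = load_table1()) {
  list(
    zrc_phuket = parse_specimens(
      fixture_path("panel_zrc_phuket.tsv"), matrix, name = "zrc_phuket",
      notes = "20 formalin-fixed specimens from 4 Phuket lots housed in ZRC"),
    mcz_paratypes = parse_specimens(
      fixture_path("panel_mcz_paratypes.tsv"), matrix, name = "mcz_paratypes",
      notes = "8 paratypes of S. robertsi from Phuket (MCZ 49164)"),
    robertsi_holotype = parse_specimens(
      fixture_path("panel_robertsi_holotype.tsv"), matrix,
      name = "robertsi_holotype",
      notes = "holotype of S. robertsi, re-examined"))
}

#' Constraints-only species tree
#'
#' A rooted binary tree over the 12 group species plus one outgroup tip.
#' Only two clades are supported by data: the group itself (monophyletic,
#' with the outgroup outside) and the (S. balteata, S. paucifasciata)
#' cherry, which rests on their uniquely shared colour pattern. All other
#' ingroup relationships are an arbitrary seeded resolution, flagged as such
#' via the `"arbitrary_resolution"` attribute.
#'
#' @param seed Integer seed for the arbitrary part of the resolution.
#' @param outgroup Outgroup tip label.
#' @return A rooted binary `phylo`.
#' @export
load_constraint_tree <- function(seed = 1L, outgroup = "outgroup") {
  taxa <- group_taxa()
  random_resolved_tree(
    c(taxa, outgroup),
    constraints = list(taxa,
                       c("Schistura_balteata", "Schistura_paucifasciata")),
    seed = seed)
}

#' Synapomorphy scan of the group on the constraint tree
#'
#' Reconstructs the qualitative hard-graded matrix characters on a
#' constraint-tree resolution with an outgroup whose only known state is the
#' absence of the lower-lip marks (no species outside the group shows them);
#' all other outgroup states are unknown, so only characters with an
#' informative outgroup can qualify.
#'
#' @param tree Tree from [load_constraint_tree()] (built from `seed` when
#'   omitted).
#' @param matrix Matrix from [load_table1()].
#' @param seed Seed forwarded to [load_constraint_tree()].
#' @return The [synapomorphies()] data frame.
#' @export
group_synapomorphies <- function(tree = NULL, matrix = load_table1(),
                                 seed = 1L) {
  if (is.null(tree)) tree <- load_constraint_tree(seed = seed)
  outgroup <- setdiff(tree$tip.label, matrix$taxa)
  if (length(outgroup) != 1L)
    stop("group_synapomorphies: tree must have exactly one non-group tip",
         call. = FALSE)
  qual <- names(Filter(function(ch)
    ch$kind == "qualitative" && ch$grade == "hard", matrix$characters))
  tip_states <- lapply(qual, function(id) {
    st <- lapply(matrix$taxa, function(tx) {
      v <- matrix$values[[tx]][[id]]
      if (is_unknown(v)) "?" else v$states
    })
    names(st) <- matrix$taxa
    st[[outgroup]] <- if (id == "lip_dots") "absent" else "?"
    st
  })
  names(tip_states) <- qual
  synapomorphies(tree, tip_states, clade = matrix$taxa, outgroup = outgroup)
}
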