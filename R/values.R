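# Cell value types: qualitative state sets, integer count ranges, two-lobe
# count formulas, and the universal unknown marker.

#' Integer count range
#'
#' A closed integer interval used for meristic characters (fin-ray counts,
#' pore counts). A single printed value `n` is stored as `[n, n]`.
#'
#' @param lo,hi Non-negative integers with `lo <= hi`; `hi` defaults to `lo`.
#' @return An object of class `count_range`.
#' @examples
#' count_range(7, 8)
#' count_range(9) # a point value
#' @export
count_range <- function(lo, hi = lo) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 1L || length(hi) != 1L || is.na(lo) || is.na(hi))
    stop("count_range: lo and hi must be single integers", call. = FALSE)
  if (lo < 0L || lo > hi)
    stop(sprintf("count_range: need 0 <= lo <= hi, got [%d, %d]", lo, hi),
         call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "count_range")
}

#' Two-lobe branched-ray formula
#'
#' The pair of branched-ray count ranges of a two-part meristic formula, e.g.
#' caudal-fin branched rays "8 + 8" (upper lobe + lower lobe) or infraorbital
#' pores "4 + 9".
#'
#' @param upper,lower `count_range` objects (or integers, coerced to point
#'   ranges) for the two parts of the formula.
#' @param uncertain Logical; `TRUE` when the printed value carries an
#'   uncertainty mark (e.g. "9 + 8?"). Uncertainty is an annotation only; it
#'   does not alter compatibility.
#' @return An object of class `caudal_formula`.
#' @examples
#' caudal_formula(count_range(6, 7), count_range(6, 8))
#' @export
caudal_formula <- function(upper, lower, uncertain = FALSE) {
  if (!inherits(upper, "count_range")) upper <- count_range(upper)
  if (!inherits(lower, "count_range")) lower <- count_range(lower)
  structure(list(upper = upper, lower = lower, uncertain = isTRUE(uncertain)),
            class = "caudal_formula")
}

#' Qualitative state set
#'
#' A non-empty subset of a qualitative character's vocabulary. A set of size
#' greater than one encodes polymorphism (the printed "Variable" entries map
#' to `{present, absent}`).
#'
#' @param states Character vector of state tokens; stored sorted and unique.
#' @return An object of class `state_set`.
#' @examples
#' state_set("present")
#' state_set(c("present", "absent")) # polymorphic
#' @export
state_set <- function(states) {
  states <- sort(unique(as.character(states)))
  if (length(states) < 1L || anyNA(states) || any(!nzchar(states)))
    stop("state_set: need at least one non-empty state token", call. = FALSE)
  structure(list(states = states), class = "state_set")
}

#' Unknown value marker
#'
#' The distinguished marker for a missing observation ("?" cells). Unknown is
#' compatible with every observation and never distinguishes two taxa.
#'
#' @return An object of class `morph_unknown`.
#' @export
unknown_value <- function() structure(list(), class = "morph_unknown")

#' Test for the unknown marker
#' @param x Any object.
#' @return `TRUE` iff `x` is the unknown marker.
#' @export
is_unknown <- function(x) inherits(x, "morph_unknown")

#' @export
print.count_range <- function(x, ...) {
  cat("<count ", format_value(x), ">\n", sep = ""); invisible(x)
}

#' @export
print.caudal_formula <- function(x, ...) {
  cat("<formula ", format_value(x), ">\n", sep = ""); invisible(x)
}

#' @export
print.state_set <- function(x, ...) {
  cat("<states ", format_value(x), ">\n", sep = ""); invisible(x)
}

#' @export
print.morph_unknown <- function(x, ...) { cat("<unknown>\n"); invisible(x) }

range_txt <- function(r) {
  if (r$lo == r$hi) as.character(r$lo) else sprintf("%d-%d", r$lo, r$hi)
}

#' Format a cell value in the delimited-matrix cell grammar
#'
#' @param value A `count_range`, `caudal_formula`, `state_set` or unknown
#'   marker.
#' @return A single string, e.g. `"7-8"`, `"/6-7 + 6-8/"`, `"present/absent"`
#'   or `"?"`.
#' @export
format_value <- function(value) {
  if (is_unknown(value)) return("?")
  if (inherits(value, "count_range")) return(range_txt(value))
  if (inherits(value, "caudal_formula")) {
    return(sprintf("/%s + %s%s/", range_txt(value$upper),
                   range_txt(value$lower), if (value$uncertain) "?" else ""))
  }
  if (inherits(value, "state_set")) return(paste(value$states, collapse = "/"))
  stop("format_value: unsupported value", call. = FALSE)
}

# --- observations -----------------------------------------------------------

#' Specimen observation constructors
#'
#' Observations are concrete point values taken on one individual: a single
#' state token, one or more integer counts (a set records left/right
#' asymmetry, e.g. the holotype's 8 and 7 pectoral rays; a set matches a
#' taxon value if any member matches), or an exact two-lobe formula.
#'
#' @param x A state token (character) or integer count(s).
#' @param upper,lower Integer count(s) for the two lobes of a formula
#'   observation.
#' @return An observation object (`obs_state`, `obs_count` or `obs_formula`).
#' @examples
#' obs_count(c(7, 8))
#' obs_formula(7, 7)
#' obs_state("present")
#' @export
obs_count <- function(x) {
  x <- sort(unique(as.integer(x)))
  if (length(x) < 1L || anyNA(x) || any(x < 0L))
    stop("obs_count: need non-negative integer count(s)", call. = FALSE)
  structure(list(counts = x), class = "obs_count")
}

#' @rdname obs_count
#' @export
obs_state <- function(x) {
  x <- as.character(x)
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    stop("obs_state: need a single state token", call. = FALSE)
  structure(list(state = x), class = "obs_state")
}

#' @rdname obs_count
#' @export
obs_formula <- function(upper, lower) {
  structure(list(upper = sort(unique(as.integer(upper))),
                 lower = sort(unique(as.integer(lower)))),
            class = "obs_formula")
}

#' @export
print.obs_count <- function(x, ...) {
  cat("<obs ", format_observation(x), ">\n", sep = ""); invisible(x)
}
#' @export
print.obs_state <- print.obs_count
#' @export
print.obs_formula <- print.obs_count

set_txt <- function(v) {
  if (length(v) == 1L) as.character(v) else
    paste0("{", paste(v, collapse = ","), "}")
}

#' Format an observation in the specimen-table cell grammar
#' @param obs An observation object.
#' @return A single string, e.g. `"8"`, `"{7,8}"`, `"7+7"`, `"present"`.
#' @export
format_observation <- function(obs) {
  if (inherits(obs, "obs_count")) return(set_txt(obs$counts))
  if (inherits(obs, "obs_state")) return(obs$state)
  if (inherits(obs, "obs_formula"))
    return(paste0(set_txt(obs$upper), "+", set_txt(obs$lower)))
  stop("format_observation: unsupported observation", call. = FALSE)
}

# --- compatibility ----------------------------------------------------------

in_range <- function(r, x) any(x >= r$lo & x <= r$hi)

#' Compatibility of a taxon value with a specimen observation
#'
#' A count observation is compatible with a taxon range when any of its
#' members falls inside the range; a formula observation when both lobes do;
#' a state observation when the token is a member of the taxon's state set.
#' The unknown marker is compatible with everything.
#'
#' @param value A taxon cell value (`count_range`, `caudal_formula`,
#'   `state_set` or unknown).
#' @param obs An observation (`obs_count`, `obs_formula`, `obs_state`).
#' @return `TRUE` or `FALSE`.
#' @examples
#' compatible(count_range(7, 8), obs_count(8))
#' compatible(count_range(9, 10), obs_count(8))
#' @export
compatible <- function(value, obs) {
  if (is_unknown(value)) return(TRUE)
  if (inherits(value, "count_range")) {
    if (!inherits(obs, "obs_count"))
      stop("compatible: count value requires a count observation", call. = FALSE)
    return(in_range(value, obs$counts))
  }
  if (inherits(value, "caudal_formula")) {
    if (!inherits(obs, "obs_formula"))
      stop("compatible: formula value requires a formula observation",
           call. = FALSE)
    return(in_range(value$upper, obs$upper) && in_range(value$lower, obs$lower))
  }
  if (inherits(value, "state_set")) {
    if (!inherits(obs, "obs_state"))
      stop("compatible: qualitative value requires a state observation",
           call. = FALSE)
    return(obs$state %in% value$states)
  }
  stop("compatible: unsupported value", call. = FALSE)
}

ranges_overlap <- function(a, b) a$lo <= b$hi && b$lo <= a$hi

#' Overlap of two taxon values
#'
#' Two values overlap when some concrete observation is compatible with both:
#' intersecting count ranges, state sets sharing a token, or formulas whose
#' upper and lower lobe ranges both intersect. Unknown overlaps everything.
#' Two taxa are distinguished by a character precisely when their values do
#' not overlap.
#'
#' @param a,b Taxon cell values of the same kind.
#' @return `TRUE` or `FALSE`.
#' @export
values_overlap <- function(a, b) {
  if (is_unknown(a) || is_unknown(b)) return(TRUE)
  if (inherits(a, "count_range") && inherits(b, "count_range"))
    return(ranges_overlap(a, b))
  if (inherits(a, "caudal_formula") && inherits(b, "caudal_formula"))
    return(ranges_overlap(a$upper, b$upper) && ranges_overlap(a$lower, b$lower))
  if (inherits(a, "state_set") && inherits(b, "state_set"))
    return(length(intersect(a$states, b$states)) > 0L)
  stop("values_overlap: values must be of the same kind", call. = FALSE)
}

# --- cell grammar parsing ---------------------------------------------------

# accepts both the hyphen and the en-dash in printed ranges
normalise_dashes <- function(x) gsub("–|—", "-", x)

parse_range_txt <- function(txt, where) {
  txt <- trimws(txt)
  if (grepl("^[0-9]+$", txt)) return(count_range(as.integer(txt)))
  m <- regmatches(txt, regexec("^([0-9]+)\\s*-\\s*([0-9]+)$", txt))[[1]]
  if (length(m) == 3L) return(count_range(as.integer(m[2]), as.integer(m[3])))
  stop(sprintf("malformed count range '%s' %s", txt, where), call. = FALSE)
}

#' Parse one matrix cell
#'
#' Cell grammar: `INT` | `INT-INT` | `/RANGE + RANGE/` (with an optional
#' trailing `?` inside the slashes marking uncertainty) | state token |
#' `token/token` polymorphism | `?`.
#'
#' @param txt Cell text.
#' @param kind Character kind: `"qualitative"`, `"count"` or
#'   `"caudal_formula"`.
#' @param where Context string used in error messages.
#' @return A cell value object.
#' @export
parse_cell <- function(txt, kind, where = "") {
  txt <- trimws(normalise_dashes(txt))
  if (txt == "?" || txt == "-" || txt == "") return(unknown_value())
  if (kind == "count") return(parse_range_txt(txt, where))
  if (kind == "caudal_formula") {
    m <- regmatches(txt, regexec(
      "^/\\s*([0-9]+(?:\\s*-\\s*[0-9]+)?)\\s*\\+\\s*([0-9]+(?:\\s*-\\s*[0-9]+)?)\\s*(\\?)?\\s*/$",
      txt))[[1]]
    if (length(m) < 3L)
      stop(sprintf("malformed formula cell '%s' %s", txt, where), call. = FALSE)
    return(caudal_formula(parse_range_txt(m[2], where),
                          parse_range_txt(m[3], where),
                          uncertain = identical(m[4], "?")))
  }
  if (kind == "qualitative") {
    toks <- trimws(strsplit(txt, "/", fixed = TRUE)[[1]])
    if (any(!nzchar(toks)))
      stop(sprintf("malformed state cell '%s' %s", txt, where), call. = FALSE)
    return(state_set(toks))
  }
  stop(sprintf("unknown character kind '%s' %s", kind, where), call. = FALSE)
}

#' Parse one specimen-table cell into an observation
#'
#' Cell grammar: `INT` | `{a,b}` | `U+L` formula with point or `{...}` lobes |
#' state token | `?` (returns `NULL`: not observed).
#'
#' @param txt Cell text.
#' @param kind Character kind.
#' @param where Context string used in error messages.
#' @return An observation object, or `NULL` for an unobserved cell.
#' @export
parse_observation <- function(txt, kind, where = "") {
  txt <- trimws(normalise_dashes(txt))
  if (txt == "?" || txt == "" || txt == "-") return(NULL)
  parse_set <- function(s) {
    s <- trimws(s)
    if (grepl("^\\{.*\\}$", s))
      s <- strsplit(substr(s, 2L, nchar(s) - 1L), ",", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.integer(trimws(s)))
    if (anyNA(v)) stop(sprintf("malformed count observation '%s' %s", txt, where),
                       call. = FALSE)
    v
  }
  if (kind == "count") return(obs_count(parse_set(txt)))
  if (kind == "caudal_formula") {
    parts <- strsplit(txt, "+", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("malformed formula observation '%s' %s", txt, where),
           call. = FALSE)
    return(obs_formula(parse_set(parts[1]), parse_set(parts[2])))
  }
  if (kind == "qualitative") return(obs_state(txt))
  stop(sprintf("unknown character kind '%s' %s", kind, where), call. = FALSE)
}
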