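# Dichotomous identification keys: predicates, couplets, JSON form,
# structural validation, execution (with range/polymorphism semantics),
# verification against a matrix, and couplet-style rendering.

#' Key predicates
#'
#' A predicate tests one character of a subject. Available tests: state
#' membership, count range, one lobe of a two-lobe formula in a range, or a
#' whole formula with both lobes in ranges. Predicates flagged `soft` record
#' statements that the companion matrix cannot represent (live coloration,
#' geography); they are excluded from routing unless explicitly enabled.
#'
#' @param char Character id the predicate refers to.
#' @param states State tokens (membership test).
#' @param lo,hi Integer bounds of the count test.
#' @param lobe `"upper"` or `"lower"`.
#' @param upper,lower Length-2 integer vectors `c(lo, hi)` for the whole
#'   formula test.
#' @param soft Logical soft flag.
#' @param note Free-text rendering of the printed lead statement.
#' @return An object of class `key_predicate`.
#' @export
pred_state <- function(char, states, soft = FALSE, note = "") {
  new_predicate(char, list(type = "state_in", states = as.character(states)),
                soft, note)
}

#' @rdname pred_state
#' @export
pred_count <- function(char, lo, hi = lo, soft = FALSE, note = "") {
  new_predicate(char, list(type = "count_in", lo = as.integer(lo),
                           hi = as.integer(hi)), soft, note)
}

#' @rdname pred_state
#' @export
pred_lobe <- function(char, lobe, lo, hi = lo, soft = FALSE, note = "") {
  lobe <- match.arg(lobe, c("upper", "lower"))
  new_predicate(char, list(type = "lobe_in", lobe = lobe, lo = as.integer(lo),
                           hi = as.integer(hi)), soft, note)
}

#' @rdname pred_state
#' @export
pred_formula <- function(char, upper, lower, soft = FALSE, note = "") {
  if (length(upper) == 1L) upper <- c(upper, upper)
  if (length(lower) == 1L) lower <- c(lower, lower)
  new_predicate(char, list(type = "formula_in", upper = as.integer(upper),
                           lower = as.integer(lower)), soft, note)
}

#' @rdname pred_state
#' @export
pred_soft <- function(char, note) {
  new_predicate(char, list(type = "soft_note"), soft = TRUE, note = note)
}

new_predicate <- function(char, test, soft, note) {
  structure(list(char = as.character(char), test = test, soft = isTRUE(soft),
                 note = as.character(note)), class = "key_predicate")
}

#' Couplet and key constructors
#'
#' @param id Positive integer couplet id, unique within a key.
#' @param lead1,lead2 The two leads, each built with [key_lead()].
#' @return A `key_couplet` / `dich_key` object.
#' @export
key_couplet <- function(id, lead1, lead2) {
  id <- as.integer(id)
  if (is.na(id) || id < 1L) stop("key_couplet: id must be a positive integer",
                                 call. = FALSE)
  structure(list(id = id, leads = list(lead1, lead2)), class = "key_couplet")
}

#' @rdname key_couplet
#' @param predicates Non-empty list of predicates, read as a conjunction.
#' @param couplet Target couplet id (routes on), or
#' @param taxon Terminal taxon name (keys out). Exactly one of the two.
#' @export
key_lead <- function(predicates, couplet = NULL, taxon = NULL) {
  if (inherits(predicates, "key_predicate")) predicates <- list(predicates)
  if (!length(predicates) ||
      !all(vapply(predicates, inherits, TRUE, "key_predicate")))
    stop("key_lead: need a non-empty list of predicates", call. = FALSE)
  if (is.null(couplet) == is.null(taxon))
    stop("key_lead: give exactly one of couplet or taxon", call. = FALSE)
  target <- if (!is.null(couplet)) list(couplet = as.integer(couplet))
  else list(taxon = as.character(taxon))
  structure(list(predicates = predicates, target = target),
            class = "key_lead")
}

#' @rdname key_couplet
#' @param couplets List of `key_couplet` objects.
#' @param start Id of the starting couplet.
#' @export
dich_key <- function(couplets, start = 1L) {
  ids <- vapply(couplets, function(cp) cp$id, 1L)
  if (anyDuplicated(ids))
    stop("dich_key: duplicate couplet id ", ids[duplicated(ids)][1],
         call. = FALSE)
  key <- structure(list(start = as.integer(start),
                        couplets = stats::setNames(couplets,
                                                   as.character(ids))),
                   class = "dich_key")
  validate_key_graph(key)
  key
}

#' @export
print.dich_key <- function(x, ...) {
  cat(sprintf("<dich_key: %d couplets, %d terminal taxa, start at %d>\n",
              length(x$couplets), length(key_terminals(x)), x$start))
  invisible(x)
}

#' Terminal taxa of a key
#' @param key A [dich_key()].
#' @return Character vector of distinct terminal taxon names.
#' @export
key_terminals <- function(key) {
  out <- unlist(lapply(key$couplets, function(cp)
    lapply(cp$leads, function(ld) ld$target$taxon)))
  sort(unique(out))
}

# reference graph from start must be acyclic with every couplet reachable
validate_key_graph <- function(key) {
  ids <- as.integer(names(key$couplets))
  if (!key$start %in% ids)
    stop("key: start couplet ", key$start, " does not exist", call. = FALSE)
  state <- stats::setNames(rep(0L, length(ids)), as.character(ids))
  visit <- function(id) {
    k <- as.character(id)
    if (is.na(match(k, names(state))) || is.null(key$couplets[[k]]))
      stop("key: lead targets missing couplet ", id, call. = FALSE)
    if (state[[k]] == 1L)
      stop("key: cycle through couplet ", id, call. = FALSE)
    if (state[[k]] == 2L) return(invisible())
    state[[k]] <<- 1L
    for (ld in key$couplets[[k]]$leads)
      if (!is.null(ld$target$couplet)) visit(ld$target$couplet)
    state[[k]] <<- 2L
  }
  visit(key$start)
  unreached <- ids[state[as.character(ids)] != 2L]
  if (length(unreached))
    stop("key: couplet(s) unreachable from start: ",
         paste(unreached, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# --- JSON form --------------------------------------------------------------

pred_to_json <- function(p) {
  out <- list(char = p$char)
  t <- p$test
  if (t$type == "state_in") out$`in` <- as.list(t$states)
  if (t$type == "count_in") out$count <- c(t$lo, t$hi)
  if (t$type == "lobe_in") { out$lobe <- t$lobe; out$count <- c(t$lo, t$hi) }
  if (t$type == "formula_in")
    out$formula <- list(upper = t$upper, lower = t$lower)
  if (p$soft) out$soft <- TRUE
  if (nzchar(p$note)) out$note <- p$note
  out
}

pred_from_json <- function(j, where) {
  if (is.null(j$char))
    stop("key JSON: predicate without char ", where, call. = FALSE)
  soft <- isTRUE(j$soft)
  note <- if (is.null(j$note)) "" else j$note
  if (!is.null(j$`in`))
    return(pred_state(j$char, unlist(j$`in`), soft, note))
  if (!is.null(j$lobe))
    return(pred_lobe(j$char, j$lobe, j$count[[1]], j$count[[2]], soft, note))
  if (!is.null(j$count))
    return(pred_count(j$char, j$count[[1]], j$count[[2]], soft, note))
  if (!is.null(j$formula))
    return(pred_formula(j$char, unlist(j$formula$upper),
                        unlist(j$formula$lower), soft, note))
  if (soft) return(pred_soft(j$char, note))
  stop("key JSON: predicate with no recognised test ", where, call. = FALSE)
}

#' Read and write the key JSON form
#'
#' The JSON schema is `{"start": <id>, "couplets": [{"id": <id>, "leads":
#' [{"predicates": [...], "target": {"couplet": <id>} | {"taxon": <name>}},
#' ...x2]}, ...]}`. Structure is validated on load; graph validity (acyclic,
#' reachable) is enforced by the key constructor.
#'
#' @param text A file path or a JSON string.
#' @return A [dich_key()].
#' @export
key_from_json <- function(text) {
  j <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (is.null(j$start) || is.null(j$couplets) || !length(j$couplets))
    stop("key JSON: need start and a non-empty couplets array", call. = FALSE)
  couplets <- lapply(j$couplets, function(cj) {
    if (is.null(cj$id)) stop("key JSON: couplet without id", call. = FALSE)
    where <- sprintf("(couplet %s)", cj$id)
    if (length(cj$leads) != 2L)
      stop("key JSON: couplet must have exactly two leads ", where,
           call. = FALSE)
    leads <- lapply(cj$leads, function(lj) {
      if (!length(lj$predicates))
        stop("key JSON: lead without predicates ", where, call. = FALSE)
      preds <- lapply(lj$predicates, pred_from_json, where = where)
      tg <- lj$target
      if (!is.null(tg$couplet)) key_lead(preds, couplet = tg$couplet)
      else if (!is.null(tg$taxon)) key_lead(preds, taxon = tg$taxon)
      else stop("key JSON: lead target must name a couplet or a taxon ",
                where, call. = FALSE)
    })
    key_couplet(cj$id, leads[[1]], leads[[2]])
  })
  dich_key(couplets, start = j$start)
}

#' @rdname key_from_json
#' @param key A [dich_key()].
#' @param path Optional output file path.
#' @export
key_to_json <- function(key, path = NULL) {
  j <- list(start = key$start,
            couplets = lapply(unname(key$couplets), function(cp) {
              list(id = cp$id, leads = lapply(cp$leads, function(ld) {
                list(predicates = lapply(ld$predicates, pred_to_json),
                     target = ld$target)
              }))
            }))
  txt <- jsonlite::toJSON(j, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(as.character(txt))) }
  as.character(txt)
}

# --- execution --------------------------------------------------------------

# Satisfaction of one predicate by a subject value/observation. Unknown or
# unobserved characters satisfy the predicate (both leads get explored).
pred_satisfied <- function(p, subject, matrix, use_soft) {
  if (p$soft && !use_soft) return(TRUE)
  if (p$test$type == "soft_note") return(TRUE)
  if (inherits(subject, "specimen")) {
    o <- subject$observations[[p$char]]
    if (is.null(o)) {
      known <- !is.null(matrix) && p$char %in% names(matrix$characters)
      if (!known && !p$soft)
        stop(sprintf("predicate references character '%s' absent from the subject and from the matrix",
                     p$char), call. = FALSE)
      return(TRUE)
    }
    return(obs_satisfies(p, o))
  }
  # taxon record: subject is list(matrix=, taxon=)
  if (!p$char %in% names(subject$matrix$characters)) {
    if (p$soft) return(TRUE)
    stop(sprintf("predicate references character '%s' absent from the subject and from the matrix",
                 p$char), call. = FALSE)
  }
  value_satisfies(p, subject$matrix$values[[subject$taxon]][[p$char]])
}

obs_satisfies <- function(p, o) {
  t <- p$test
  switch(t$type,
    state_in = o$state %in% t$states,
    count_in = any(o$counts >= t$lo & o$counts <= t$hi),
    lobe_in = any(o[[t$lobe]] >= t$lo & o[[t$lobe]] <= t$hi),
    formula_in = any(o$upper >= t$upper[1] & o$upper <= t$upper[2]) &&
      any(o$lower >= t$lower[1] & o$lower <= t$lower[2]),
    stop("unknown predicate test", call. = FALSE))
}

# Range/polymorphism semantics: a taxon value satisfies a lead when it
# overlaps the predicate's value set, so a wide range can satisfy both leads.
value_satisfies <- function(p, v) {
  if (is_unknown(v)) return(TRUE)
  t <- p$test
  switch(t$type,
    state_in = length(intersect(v$states, t$states)) > 0L,
    count_in = ranges_overlap(v, count_range(t$lo, t$hi)),
    lobe_in = ranges_overlap(v[[t$lobe]], count_range(t$lo, t$hi)),
    formula_in = ranges_overlap(v$upper, count_range(t$upper[1], t$upper[2])) &&
      ranges_overlap(v$lower, count_range(t$lower[1], t$lower[2])),
    stop("unknown predicate test", call. = FALSE))
}

#' Run a subject through a dichotomous key
#'
#' Deterministic descent from the start couplet. At each couplet every lead
#' whose conjunction of predicates is satisfied is followed; ranges,
#' polymorphism and unknown/unobserved characters can satisfy both leads, in
#' which case both branches are explored and all reached terminals returned.
#' A couplet where neither lead is satisfied contributes a dead end.
#'
#' @param key A [dich_key()].
#' @param subject A [specimen()], or a taxon name present in `matrix` (its
#'   Table-row record is then evaluated).
#' @param matrix Companion [morph_matrix()] (required for taxon subjects;
#'   used to resolve unobserved specimen characters).
#' @param use_soft Include soft predicates in routing (default `FALSE`).
#' @return A `key_trace`: list with `path` (couplet ids in visit order),
#'   `terminals` (taxon set reached), `dead_ends` (couplet ids where neither
#'   lead was satisfied) and `status` (`"unique"`, `"ambiguous"` or
#'   `"dead_end"`).
#' @export
evaluate_key <- function(key, subject, matrix = NULL, use_soft = FALSE) {
  if (is.character(subject)) {
    if (is.null(matrix))
      stop("evaluate_key: taxon subjects need the companion matrix",
           call. = FALSE)
    if (!subject %in% matrix$taxa)
      stop(sprintf("evaluate_key: taxon '%s' not in matrix", subject),
           call. = FALSE)
    subject <- structure(list(matrix = matrix, taxon = subject),
                         class = "taxon_subject")
  }
  path <- integer(); terminals <- character(); dead_ends <- integer()
  walk <- function(id) {
    path <<- c(path, id)
    cp <- key$couplets[[as.character(id)]]
    any_sat <- FALSE
    for (ld in cp$leads) {
      sat <- all(vapply(ld$predicates, pred_satisfied, TRUE,
                        subject = subject, matrix = matrix,
                        use_soft = use_soft))
      if (!sat) next
      any_sat <- TRUE
      if (!is.null(ld$target$taxon))
        terminals <<- c(terminals, ld$target$taxon)
      else walk(ld$target$couplet)
    }
    if (!any_sat) dead_ends <<- c(dead_ends, id)
  }
  walk(key$start)
  terminals <- sort(unique(terminals))
  status <- if (length(terminals) == 0L) "dead_end"
  else if (length(terminals) == 1L) "unique" else "ambiguous"
  structure(list(path = unique(path), terminals = terminals,
                 dead_ends = dead_ends, status = status),
            class = "key_trace")
}

#' @export
print.key_trace <- function(x, ...) {
  cat(sprintf("<key_trace: %s; path %s; terminals {%s}>\n", x$status,
              paste(x$path, collapse = ","),
              paste(x$terminals, collapse = ", ")))
  invisible(x)
}

#' Verify a key against a character matrix
#'
#' Runs every matrix taxon's own record through the key and reports the taxa
#' whose trace is not uniquely themselves (misrouted, ambiguous or
#' dead-ended), with the couplet where the failure shows.
#'
#' @param key A [dich_key()].
#' @param matrix A [morph_matrix()]. Every key terminal must be a matrix
#'   taxon.
#' @param use_soft Include soft predicates in routing.
#' @return A list with `ok` (all taxa route to themselves), `results` (data
#'   frame: taxon, status, terminals, ok, first_issue_couplet) and `traces`
#'   (named list of `key_trace`).
#' @export
verify_key <- function(key, matrix, use_soft = FALSE) {
  missing <- setdiff(key_terminals(key), matrix$taxa)
  if (length(missing))
    stop("verify_key: terminal taxon not in matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  traces <- lapply(matrix$taxa, function(tx)
    evaluate_key(key, tx, matrix, use_soft = use_soft))
  names(traces) <- matrix$taxa
  ok <- vapply(matrix$taxa, function(tx) {
    tr <- traces[[tx]]
    tr$status == "unique" && identical(tr$terminals, tx)
  }, TRUE)
  first_issue <- vapply(matrix$taxa, function(tx) {
    tr <- traces[[tx]]
    if (ok[[tx]]) return(NA_integer_)
    if (length(tr$dead_ends)) return(tr$dead_ends[1])
    tr$path[1]
  }, 1L)
  results <- data.frame(
    taxon = matrix$taxa,
    status = vapply(traces, function(tr) tr$status, ""),
    terminals = vapply(traces, function(tr)
      paste(tr$terminals, collapse = ","), ""),
    ok = unname(ok),
    first_issue_couplet = unname(first_issue),
    stringsAsFactors = FALSE, row.names = NULL)
  list(ok = all(ok), results = results, traces = traces)
}

# --- rendering --------------------------------------------------------------

render_predicate <- function(p) {
  if (nzchar(p$note)) return(p$note)
  t <- p$test
  txt <- switch(t$type,
    state_in = sprintf("%s in {%s}", p$char, paste(t$states, collapse = ", ")),
    count_in = sprintf("%s %s", p$char, range_txt(list(lo = t$lo, hi = t$hi))),
    lobe_in = sprintf("%s %s lobe %s", p$char, t$lobe,
                      range_txt(list(lo = t$lo, hi = t$hi))),
    formula_in = sprintf("%s %s + %s", p$char,
                         range_txt(list(lo = t$upper[1], hi = t$upper[2])),
                         range_txt(list(lo = t$lower[1], hi = t$lower[2]))),
    soft_note = p$note)
  if (p$soft) txt <- paste0("[soft] ", txt)
  txt
}

#' Render a key as couplet-style text
#'
#' Numbered couplets with two leads each; terminal taxa are wrapped in `*`
#' italics markers. A machine-readable sidecar (the JSON form on `#@` lines)
#' is appended so the text round-trips through [parse_rendered_key()].
#'
#' @param key A [dich_key()].
#' @param sidecar Append the JSON sidecar (default `TRUE`).
#' @return The rendered key as a single string.
#' @export
render_key <- function(key, sidecar = TRUE) {
  ids <- sort(as.integer(names(key$couplets)))
  blocks <- vapply(ids, function(id) {
    cp <- key$couplets[[as.character(id)]]
    leadtxt <- vapply(cp$leads, function(ld) {
      stmt <- paste(vapply(ld$predicates, render_predicate, ""),
                    collapse = "; ")
      tgt <- if (!is.null(ld$target$couplet)) as.character(ld$target$couplet)
      else paste0("*", ld$target$taxon, "*")
      sprintf("  - %s. ..... %s", stmt, tgt)
    }, "")
    paste(c(sprintf("%d", id), leadtxt), collapse = "\n")
  }, "")
  txt <- paste(blocks, collapse = "\n")
  if (sidecar) {
    j <- strsplit(key_to_json(key), "\n", fixed = TRUE)[[1]]
    txt <- paste(c(txt, paste0("#@ ", j)), collapse = "\n")
  }
  txt
}

#' @rdname render_key
#' @param text Rendered key text (or file path) containing the `#@` sidecar.
#' @export
parse_rendered_key <- function(text) {
  lines <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    readLines(text, warn = FALSE) else strsplit(text, "\n", fixed = TRUE)[[1]]
  side <- sub("^#@ ?", "", lines[grepl("^#@", lines)])
  if (!length(side))
    stop("parse_rendered_key: no machine-readable sidecar found", call. = FALSE)
  key_from_json(paste(side, collapse = "\n"))
}
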