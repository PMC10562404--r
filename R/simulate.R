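# Seeded generators for matrices, specimen panels and constrained random
# trees. All randomness is drawn inside a local RNG scope, so generation is
# reproducible from the explicit seed and never disturbs the caller's RNG.

# sample() treats a length-1 numeric as 1:x; this helper never does
draw1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

with_local_seed <- function(seed, code) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Describes the statistical structure of a synthetic character matrix,
#' emulating the fixture's mix of qualitative multistate characters,
#' narrow-range meristic counts, two-lobe formulas, polymorphic ("Variable")
#' cells and unknown cells.
#'
#' @param n_taxa,n_characters Matrix dimensions.
#' @param kind_mix Named numeric fractions for `qualitative`, `count`,
#'   `caudal_formula`; must sum to 1.
#' @param n_states States per qualitative character (default 3).
#' @param count_base Range of character-level base count values.
#' @param range_width Min/max width of a count range (meristic counts have
#'   small widths; default 0–2).
#' @param polymorphism_rate Probability that a qualitative cell is
#'   polymorphic (two states).
#' @param unknown_rate Probability that any cell is unknown.
#' @param seed Integer seed fixing all downstream randomness.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_taxa = 12L, n_characters = 18L,
                       kind_mix = c(qualitative = 0.5, count = 0.35,
                                    caudal_formula = 0.15),
                       n_states = 3L,
                       count_base = c(5L, 12L), range_width = c(0L, 2L),
                       polymorphism_rate = 0.05, unknown_rate = 0.03,
                       seed = 1L) {
  stopifnot(n_taxa >= 1L, n_characters >= 1L)
  kinds <- c("qualitative", "count", "caudal_formula")
  if (!all(kinds %in% names(kind_mix)) || abs(sum(kind_mix) - 1) > 1e-8)
    stop("sim_config: kind_mix must name all three kinds and sum to 1",
         call. = FALSE)
  if (polymorphism_rate < 0 || polymorphism_rate > 1 ||
      unknown_rate < 0 || unknown_rate > 1)
    stop("sim_config: rates must be in [0, 1]", call. = FALSE)
  if (n_states < 2L)
    stop("sim_config: qualitative characters need at least 2 states",
         call. = FALSE)
  structure(list(n_taxa = as.integer(n_taxa),
                 n_characters = as.integer(n_characters),
                 kind_mix = kind_mix[kinds], n_states = as.integer(n_states),
                 count_base = as.integer(count_base),
                 range_width = as.integer(range_width),
                 polymorphism_rate = polymorphism_rate,
                 unknown_rate = unknown_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from JSON
#' @param text JSON file path or string with any subset of the
#'   [sim_config()] fields.
#' @return A `sim_config`.
#' @export
sim_config_from_json <- function(text) {
  j <- jsonlite::fromJSON(text)
  if (!is.null(j$kind_mix)) j$kind_mix <- unlist(j$kind_mix)
  do.call(sim_config, j)
}

#' Generate a seeded random character matrix
#'
#' With `unknown_rate = 0` and `polymorphism_rate = 0` every cell is a point
#' value. Regeneration with the same configuration is bit-identical.
#'
#' @param config A [sim_config()].
#' @return A validated [morph_matrix()].
#' @export
random_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    nc <- config$n_characters
    n_each <- floor(config$kind_mix * nc)
    rem <- nc - sum(n_each)
    if (rem > 0)
      n_each[order(config$kind_mix, decreasing = TRUE)[seq_len(rem)]] <-
        n_each[order(config$kind_mix, decreasing = TRUE)[seq_len(rem)]] + 1L
    kinds <- rep(names(n_each), n_each)[seq_len(nc)]
    taxa <- sprintf("taxon_%02d", seq_len(config$n_taxa))
    characters <- lapply(seq_len(nc), function(j) {
      kind <- kinds[j]
      vocab <- if (kind == "qualitative")
        paste0("s", seq_len(config$n_states)) else character()
      character_def(sprintf("char_%02d", j), kind = kind, vocabulary = vocab)
    })
    base_pool <- config$count_base[1]:config$count_base[2]
    bases <- base_pool[sample.int(length(base_pool), nc, replace = TRUE)]
    rwidth <- function() draw1(config$range_width[1]:config$range_width[2])
    draw_value <- function(kind, j) {
      if (stats::runif(1) < config$unknown_rate) return(unknown_value())
      if (kind == "qualitative") {
        k <- if (stats::runif(1) < config$polymorphism_rate) 2L else 1L
        return(state_set(sample(paste0("s", seq_len(config$n_states)), k)))
      }
      if (kind == "count") {
        lo <- max(0L, bases[j] + sample(-2:2, 1L))
        return(count_range(lo, lo + rwidth()))
      }
      lo_u <- max(0L, bases[j] + sample(-2:2, 1L))
      lo_l <- max(0L, bases[j] + sample(-2:2, 1L))
      caudal_formula(count_range(lo_u, lo_u + rwidth()),
                     count_range(lo_l, lo_l + rwidth()))
    }
    values <- stats::setNames(lapply(taxa, function(tx) {
      row <- lapply(seq_len(nc), function(j) draw_value(kinds[j], j))
      stats::setNames(row, sprintf("char_%02d", seq_len(nc)))
    }), taxa)
    morph_matrix(characters, taxa, values)
  })
}

#' Generate a matrix with disjoint per-taxon values
#'
#' Every taxon gets its own point value on every character (counts offset by
#' taxon index, qualitative states cycled), so all pairs are distinguishable
#' on every character with at least `n_taxa` distinct values; used for
#' end-to-end recovery experiments.
#'
#' @param n_taxa,n_characters Dimensions.
#' @param seed Integer seed.
#' @return A [morph_matrix()].
#' @export
disjoint_matrix <- function(n_taxa = 5L, n_characters = 4L, seed = 1L) {
  with_local_seed(seed, {
    taxa <- sprintf("taxon_%02d", seq_len(n_taxa))
    kinds <- rep(c("count", "qualitative"), length.out = n_characters)
    characters <- lapply(seq_len(n_characters), function(j) {
      vocab <- if (kinds[j] == "qualitative")
        paste0("s", seq_len(n_taxa)) else character()
      character_def(sprintf("char_%02d", j), kind = kinds[j],
                    vocabulary = vocab)
    })
    offs <- sample(5:20, n_characters, replace = TRUE)
    values <- stats::setNames(lapply(seq_len(n_taxa), function(i) {
      row <- lapply(seq_len(n_characters), function(j) {
        if (kinds[j] == "count") count_range(offs[j] + 2L * i)
        else state_set(paste0("s", i))
      })
      stats::setNames(row, sprintf("char_%02d", seq_len(n_characters)))
    }), taxa)
    morph_matrix(characters, taxa, values)
  })
}

#' Simulate specimens drawn from one taxon's values
#'
#' Each observation is drawn uniformly from the taxon's value set (a state
#' from its state set, an integer from its count range, one integer per
#' formula lobe). With probability `noise_rate` an observation is perturbed
#' to an adjacent count or an alternative state; every perturbation is
#' logged, with a flag marking whether it left the taxon's value set.
#'
#' @param matrix A [morph_matrix()].
#' @param taxon Source taxon name.
#' @param n Number of specimens (0 gives an empty panel).
#' @param noise_rate Per-observation perturbation probability.
#' @param seed Integer seed.
#' @return A [specimen_panel()] with attribute `"perturbations"`: data frame
#'   `specimen`, `character`, `original`, `perturbed`, `left_taxon_values`.
#' @export
specimens_from_taxon <- function(matrix, taxon, n, noise_rate = 0,
                                 seed = 1L) {
  if (!taxon %in% matrix$taxa)
    stop(sprintf("specimens_from_taxon: taxon '%s' not in matrix", taxon),
         call. = FALSE)
  with_local_seed(seed, {
    log_rows <- list()
    ids <- names(matrix$characters)
    specs <- lapply(seq_len(n), function(i) {
      sid <- sprintf("%s_sim%03d", taxon, i)
      obs <- list()
      for (id in ids) {
        v <- matrix$values[[taxon]][[id]]
        if (is_unknown(v)) next
        kind <- matrix$characters[[id]]$kind
        o <- switch(kind,
          qualitative = obs_state(draw1(v$states)),
          count = obs_count(draw1(v$lo:v$hi)),
          caudal_formula = obs_formula(draw1(v$upper$lo:v$upper$hi),
                                       draw1(v$lower$lo:v$lower$hi)))
        if (stats::runif(1) < noise_rate) {
          orig <- format_observation(o)
          o <- perturb_observation(o, matrix$characters[[id]])
          log_rows[[length(log_rows) + 1L]] <<- data.frame(
            specimen = sid, character = id, original = orig,
            perturbed = format_observation(o),
            left_taxon_values = !compatible(v, o), stringsAsFactors = FALSE)
        }
        obs[[id]] <- o
      }
      specimen(sid, obs, provenance = sprintf("simulated from %s", taxon))
    })
    panel <- specimen_panel(sprintf("sim_%s", taxon), specs,
                            notes = sprintf("n=%d noise=%g seed=%d", n,
                                            noise_rate, seed))
    plog <- if (length(log_rows)) do.call(rbind, log_rows)
    else data.frame(specimen = character(), character = character(),
                    original = character(), perturbed = character(),
                    left_taxon_values = logical(), stringsAsFactors = FALSE)
    attr(panel, "perturbations") <- plog
    panel
  })
}

perturb_observation <- function(o, chardef) {
  if (inherits(o, "obs_state")) {
    alt <- setdiff(chardef$vocabulary, o$state)
    if (!length(alt)) return(o)
    return(obs_state(sample(alt, 1L)))
  }
  bump <- function(x) max(0L, x + sample(c(-1L, 1L), 1L))
  if (inherits(o, "obs_count")) return(obs_count(bump(o$counts[1])))
  if (inherits(o, "obs_formula")) {
    if (stats::runif(1) < 0.5) obs_formula(bump(o$upper[1]), o$lower)
    else obs_formula(o$upper, bump(o$lower[1]))
  } else o
}

# --- constrained random trees ----------------------------------------------

check_constraints <- function(tips, constraints) {
  constraints <- lapply(constraints, function(cl) sort(unique(as.character(cl))))
  for (cl in constraints) {
    bad <- setdiff(cl, tips)
    if (length(bad))
      stop("random_resolved_tree: constraint names unknown tip(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (length(cl) < 2L)
      stop("random_resolved_tree: constraints need at least two tips",
           call. = FALSE)
  }
  if (length(constraints) >= 2L) {
    for (i in seq_along(constraints)) for (j in seq_len(i - 1L)) {
      a <- constraints[[i]]; b <- constraints[[j]]
      ov <- intersect(a, b)
      if (length(ov) && !(all(a %in% b) || all(b %in% a)))
        stop(sprintf("random_resolved_tree: incompatible constraints {%s} and {%s}",
                     paste(a, collapse = ","), paste(b, collapse = ",")),
             call. = FALSE)
    }
  }
  constraints
}

# random sequential coalescence of newick fragments
join_random <- function(parts) {
  while (length(parts) > 1L) {
    k <- sample.int(length(parts), 2L)
    merged <- sprintf("(%s,%s)", parts[k[1]], parts[k[2]])
    parts <- c(parts[-k], merged)
  }
  parts
}

resolve_set <- function(tipset, constraints) {
  # units: maximal constraints inside tipset, plus free tips
  inner <- Filter(function(cl) all(cl %in% tipset) &&
                    length(cl) < length(tipset), constraints)
  maximal <- Filter(function(cl)
    !any(vapply(inner, function(o)
      length(o) > length(cl) && all(cl %in% o), TRUE)), inner)
  used <- unlist(maximal)
  free <- setdiff(tipset, used)
  units <- c(vapply(maximal, function(cl)
    resolve_set(cl, setdiff_constraints(constraints, cl)), ""),
    free)
  join_random(sample(units))
}

setdiff_constraints <- function(constraints, cl) {
  Filter(function(o) length(o) < length(cl) && all(o %in% cl), constraints)
}

#' Random fully-bifurcating tree honouring clade constraints
#'
#' Builds a rooted binary tree over the given tips in which every required
#' clade appears; the remaining resolution is a seeded random coalescence.
#' Mutually incompatible (overlapping, non-nested) constraints are an error.
#'
#' @param tips Tip labels.
#' @param constraints List of required clades (character vectors of tips).
#' @param seed Integer seed.
#' @return A rooted binary `phylo` with attribute `"arbitrary_resolution" =
#'   TRUE` (only the constraints are supported by data).
#' @export
random_resolved_tree <- function(tips, constraints = list(), seed = 1L) {
  tips <- as.character(tips)
  if (anyDuplicated(tips))
    stop("random_resolved_tree: duplicate tips", call. = FALSE)
  constraints <- check_constraints(tips, constraints)
  with_local_seed(seed, {
    nwk <- paste0(resolve_set(tips, constraints), ";")
    tree <- parse_newick(nwk)
    attr(tree, "arbitrary_resolution") <- TRUE
    tree
  })
}
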