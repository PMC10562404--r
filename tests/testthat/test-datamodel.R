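# Core value types, the compatibility relation and the matrix formats.

test_that("cell grammar parses counts, ranges, formulas, states and unknowns", {
  expect_identical(parse_cell("9", "count"), count_range(9))
  expect_identical(parse_cell("7-8", "count"), count_range(7, 8))
  # en-dash in printed ranges is accepted; the writer emits a hyphen
  expect_identical(parse_cell("7–8", "count"), count_range(7, 8))
  f <- parse_cell("/6-7 + 6-8/", "caudal_formula")
  expect_identical(f$upper, count_range(6, 7))
  expect_identical(f$lower, count_range(6, 8))
  expect_false(f$uncertain)
  fu <- parse_cell("/9 + 8?/", "caudal_formula")
  expect_identical(fu$upper, count_range(9))
  expect_identical(fu$lower, count_range(8))
  expect_true(fu$uncertain)
  expect_identical(parse_cell("present", "qualitative"), state_set("present"))
  expect_identical(parse_cell("present/absent", "qualitative"),
                   state_set(c("absent", "present")))
  expect_true(is_unknown(parse_cell("?", "count")))
  expect_error(parse_cell("7-", "count"), "malformed")
  expect_error(parse_cell("/8/", "caudal_formula"), "malformed")
})

test_that("formatting inverts parsing for every value shape", {
  cells <- list(count_range(9), count_range(7, 8),
                caudal_formula(count_range(8), count_range(7, 8)),
                caudal_formula(count_range(9), count_range(8),
                               uncertain = TRUE),
                state_set("present"), state_set(c("absent", "present")),
                unknown_value())
  kinds <- c("count", "count", "caudal_formula", "caudal_formula",
             "qualitative", "qualitative", "count")
  for (i in seq_along(cells))
    expect_identical(parse_cell(format_value(cells[[i]]), kinds[i]),
                     cells[[i]])
})

test_that("compatibility follows range, lobe and membership semantics", {
  # the Phuket argument: 8 pectoral rays inside the S. robertsi range,
  # outside the S. peninsulae range
  expect_true(compatible(count_range(7, 8), obs_count(8)))
  expect_false(compatible(count_range(9, 10), obs_count(8)))
  # asymmetric counts: the set {7,8} matches if any member matches
  expect_true(compatible(count_range(8, 8), obs_count(c(7, 8))))
  # both lobes must fall in range
  rob <- caudal_formula(count_range(6, 7), count_range(6, 8))
  expect_true(compatible(rob, obs_formula(7, 7)))
  expect_false(compatible(rob, obs_formula(8, 8)))
  expect_true(compatible(state_set(c("absent", "present")),
                         obs_state("absent")))
  expect_false(compatible(state_set("present"), obs_state("absent")))
  # unknown matches everything
  expect_true(compatible(unknown_value(), obs_count(42)))
  # point-value reflexivity
  for (n in c(0L, 3L, 9L))
    expect_true(compatible(count_range(n), obs_count(n)))
  expect_error(compatible(count_range(7, 8), obs_state("present")), "count")
})

test_that("value overlap is symmetric and unknown never distinguishes", {
  a <- count_range(7, 8); b <- count_range(9, 10); c <- count_range(8, 9)
  expect_false(values_overlap(a, b))
  expect_true(values_overlap(a, c))
  expect_true(values_overlap(unknown_value(), b))
  f1 <- caudal_formula(count_range(8, 9), count_range(7, 8))
  f2 <- caudal_formula(count_range(6, 7), count_range(7, 8))
  expect_false(values_overlap(f1, f2)) # upper lobes disjoint
  expect_true(values_overlap(f1, caudal_formula(count_range(9), count_range(8))))
  expect_identical(values_overlap(state_set("x"), state_set(c("x", "y"))),
                   values_overlap(state_set(c("x", "y")), state_set("x")))
})

test_that("matrix documents round-trip through write_matrix/parse_matrix", {
  for (seed in 1:8) {
    cfg <- sim_config(n_taxa = 5L, n_characters = 7L,
                      polymorphism_rate = 0.2, unknown_rate = 0.15,
                      seed = seed)
    m <- random_matrix(cfg)
    doc <- write_matrix(m)
    m2 <- parse_matrix(doc, characters = unname(m$characters))
    expect_identical(m2$values, m$values)
    expect_identical(m2$taxa, m$taxa)
  }
  # unknown cells survive as "?"
  cfg <- sim_config(n_taxa = 4L, n_characters = 5L, unknown_rate = 1,
                    seed = 2)
  doc <- write_matrix(random_matrix(cfg))
  expect_true(all(grepl("\\?", strsplit(doc, "\n")[[1]][-1])))
})

test_that("degenerate matrices parse and serialise", {
  m <- parse_matrix("taxon\tc1\nt1\t9")
  expect_identical(matrix_value(m, "t1", "c1"), count_range(9))
  empty <- morph_matrix(list(character_def("c1", kind = "count")),
                        character(), list())
  expect_identical(write_matrix(empty), "taxon\tc1")
  expect_identical(parse_matrix(write_matrix(empty),
                                characters = unname(empty$characters))$taxa,
                   character())
})

test_that("malformed documents are rejected with located errors", {
  expect_error(parse_matrix("taxon\tc1\nt1\tx-y",
                            characters = list(character_def("c1",
                                                            kind = "count"))),
               "row 2.*c1")
  expect_error(parse_matrix("taxon\tc1\nt1\t9\nt1\t8"), "duplicate taxon")
  defs <- list(character_def("c1", kind = "qualitative",
                             vocabulary = c("present", "absent")))
  expect_error(parse_matrix("taxon\tc1\nt1\tgreen", characters = defs),
               "outside vocabulary")
  expect_error(character_def("c1", kind = "qualitative",
                             vocabulary = c("a", "a")), "duplicate-free")
})

test_that("NEXUS writer emits a parseable DATA block and preserves symbols", {
  codes <- c(tA = "0102", tB = "1102", tC = "010{12}")
  doc <- write_nexus(codes)
  expect_match(doc, "NTAX=3")
  expect_match(doc, "NCHAR=4")
  expect_match(doc, "MISSING=\\?")
  expect_match(doc, "010\\{12\\}", all = FALSE)
  # an independent NEXUS consumer reads the brace-free block back
  plain <- c(tA = "0102", tB = "1102", tC = "0100")
  tf <- tempfile(fileext = ".nex")
  write_nexus(plain, path = tf)
  parsed <- ape::read.nexus.data(tf)
  expect_identical(names(parsed), names(plain))
  expect_identical(vapply(parsed, paste, "", collapse = ""), plain)
  # minimal block and the unequal-length error
  expect_match(write_nexus(c(one = "0")), "NTAX=1 NCHAR=1")
  expect_error(write_nexus(c(a = "01", b = "0")), "unequal code lengths")
})

test_that("specimen tables round-trip and validate against the matrix", {
  m <- load_table1()
  doc <- paste("specimen\tpectoral_rays\tcaudal_rays\tlip_dots",
               "s1\t{7,8}\t7+7\tpresent",
               "s2\t9\t?\t?", sep = "\n")
  panel <- parse_specimens(doc, m, name = "p")
  expect_length(panel$specimens, 2L)
  expect_identical(panel$specimens[[1]]$observations$pectoral_rays,
                   obs_count(c(7, 8)))
  expect_identical(panel$specimens[[1]]$observations$caudal_rays,
                   obs_formula(7, 7))
  expect_null(panel$specimens[[2]]$observations$caudal_rays)
  doc2 <- write_specimens(panel, m)
  panel2 <- parse_specimens(doc2, m, name = "p")
  expect_equal(lapply(panel2$specimens, function(s) s$observations),
               lapply(panel$specimens, function(s) s$observations))
  expect_error(parse_specimens("specimen\tno_such_char\ns1\t9", m),
               "unknown character")
})
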