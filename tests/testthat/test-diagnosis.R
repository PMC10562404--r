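# Diagnosability: pairwise differences, unique combinations, minimal
# diagnostic sets, specimen classification and panel tallies.

test_that("pairwise differences reproduce the robertsi/peninsulae diagnosis", {
  m <- load_table1()
  d <- pairwise_diffs(m)
  expect_identical(nrow(d), 66L)
  row <- d[(d$taxon_a == "Schistura_robertsi" &
              d$taxon_b == "Schistura_peninsulae") |
             (d$taxon_b == "Schistura_robertsi" &
                d$taxon_a == "Schistura_peninsulae"), ]
  # the only hard (diagnostic-grade) separators are the two ray counts
  expect_setequal(strsplit(row$hard, ",")[[1]],
                  c("pectoral_rays", "caudal_rays"))
  # the soft pore counts differ in the table but are graded out
  expect_true(all(c("supraorbital_pores", "supratemporal_pores") %in%
                    strsplit(row$distinguishing, ",")[[1]]))
})

test_that("identical or unknown-everywhere taxa never show differences", {
  defs <- list(character_def("c1", kind = "count"),
               character_def("c2", kind = "qualitative",
                             vocabulary = c("a", "b")))
  m <- parse_matrix(paste("taxon\tc1\tc2", "t1\t5\ta", "t2\t5\ta",
                          "t3\t?\t?", sep = "\n"), characters = defs)
  d <- pairwise_diffs(m)
  expect_true(all(d$distinguishing == ""))
  chk <- unique_combination_check(m)
  expect_false(chk$ok)
  expect_identical(nrow(chk$offending_pairs), 3L)
})

test_that("unique combinations hold for the comparison table and vacuously for one taxon", {
  m <- load_table1()
  expect_true(unique_combination_check(m)$ok)
  one <- morph_matrix(unname(m$characters), m$taxa[1], m$values[1])
  expect_true(unique_combination_check(one)$ok)
  # equivalence with key generation
  expect_s3_class(generate_key(m), "dich_key")
})

test_that("minimal diagnostic sets are exactly the minimal ones (oracle-checked)", {
  m <- load_table1()
  for (tx in c("Schistura_ataranensis", "Schistura_robertsi",
               "Schistura_hartli")) {
    sets <- minimal_diagnostic_sets(m, tx, k_max = 3L)
    expect_gt(length(sets), 0L)
    for (s in sets) {
      expect_true(oracle_is_diagnostic(m, tx, s$characters))
      # no proper subset is diagnostic
      if (length(s$characters) > 1L)
        for (drop in s$characters)
          expect_false(oracle_is_diagnostic(
            m, tx, setdiff(s$characters, drop)))
    }
    # ascending size, and every returned set marked minimal
    expect_true(!is.unsorted(lengths(lapply(sets, `[[`, "characters"))))
  }
})

test_that("the dorsal-stripe character alone cannot separate S. ataranensis from the table", {
  # the species Diagnosis presents the 2-3 dorsal stripes as unique, but the
  # comparison table also scores stripes present for S. balteata, so no
  # size-1 set exists and the axillary lobe or ray counts must join in
  m <- load_table1()
  expect_false(oracle_is_diagnostic(m, "Schistura_ataranensis",
                                    "dorsal_stripes"))
  sets <- minimal_diagnostic_sets(m, "Schistura_ataranensis", k_max = 2L)
  expect_true(all(lengths(lapply(sets, `[[`, "characters")) == 2L))
  expect_true(any(vapply(sets, function(s)
    "dorsal_stripes" %in% s$characters, TRUE)))
})

test_that("duplicated taxa admit no diagnostic set and uncertainty demotes a character", {
  defs <- list(character_def("c1", kind = "count"))
  dup <- parse_matrix(paste("taxon\tc1", "t1\t5", "t2\t5", sep = "\n"),
                      characters = defs)
  expect_identical(minimal_diagnostic_sets(dup, "t1", k_max = 1L,
                                           chars = "c1"), list())
  # an uncertainty-annotated value is demoted unless explicitly included
  udefs <- list(character_def("caudal", kind = "caudal_formula"))
  um <- parse_matrix(paste("taxon\tcaudal", "tU\t/9 + 8?/", "tV\t/7 + 7/",
                           sep = "\n"), characters = udefs)
  expect_identical(minimal_diagnostic_sets(um, "tU", k_max = 1L,
                                           chars = "caudal"), list())
  inc <- minimal_diagnostic_sets(um, "tU", k_max = 1L, chars = "caudal",
                                 include_uncertain = TRUE)
  expect_length(inc, 1L)
  expect_identical(inc[[1]]$characters, "caudal")
  # the S. paucifasciata caudal entry is demoted the same way by default
  m <- load_table1()
  sets_def <- minimal_diagnostic_sets(m, "Schistura_paucifasciata",
                                      k_max = 2L)
  expect_false(any(vapply(sets_def, function(s)
    "caudal_rays" %in% s$characters, TRUE)))
  expect_gt(length(sets_def), 0L)
})

test_that("classification reproduces the holotype and Phuket conflict findings", {
  m <- load_table1()
  panels <- load_specimen_panels(m)
  hol <- classify_specimen(m, panels$robertsi_holotype$specimens[[1]])
  expect_identical(hol$status, "unique")
  expect_identical(hol$overall, "Schistura_robertsi")
  # a Phuket specimen with 8 pectoral rays but the 8+8 caudal formula
  phuket <- specimen("phuket", list(pectoral_rays = obs_count(8),
                                    caudal_rays = obs_formula(8, 8)))
  r <- classify_specimen(m, phuket)
  expect_identical(r$status, "conflict")
  expect_true(all(c("Schistura_robertsi", "Schistura_myaekanbawensis") %in%
                    r$per_character$pectoral_rays))
  expect_true("Schistura_peninsulae" %in% r$per_character$caudal_rays)
  expect_false("Schistura_peninsulae" %in% r$overall)
  expect_true("caudal_rays" %in% r$conflict_detail)
  # specimens sampled from a taxon always keep it among the candidates
  set.seed(7)
  for (tx in sample(m$taxa, 4L)) {
    pan <- specimens_from_taxon(m, tx, 3L, seed = 99L)
    for (s in pan$specimens) {
      res <- classify_specimen(m, s)
      expect_true(all(vapply(res$per_character, function(cand)
        tx %in% cand, TRUE)))
      expect_true(tx %in% res$overall)
    }
  }
  expect_error(classify_specimen(m, specimen("x", list())), "no observations")
})

test_that("panel tallies reproduce the published Phuket and MCZ arithmetic", {
  m <- load_table1()
  panels <- load_specimen_panels(m)
  zrc <- panel_report(m, panels$zrc_phuket)
  expect_identical(panel_tally(zrc, "pectoral_rays", "Schistura_robertsi"),
                   20L)
  expect_identical(panel_tally(zrc, "caudal_rays", "Schistura_robertsi"), 8L)
  expect_identical(panel_tally(zrc, "caudal_rays", "Schistura_peninsulae"),
                   12L)
  mcz <- panel_report(m, panels$mcz_paratypes)
  expect_identical(panel_tally(mcz, "caudal_rays", "Schistura_robertsi"), 4L)
  expect_identical(panel_tally(mcz, "caudal_rays", "Schistura_peninsulae"),
                   4L)
  expect_error(panel_report(m, specimen_panel("empty")), "empty")
})
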