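# Key execution, verification, generation and rendering.

test_that("key structure invariants are enforced at load", {
  p <- pred_state("c1", "a")
  mk <- function(target1) dich_key(list(
    key_couplet(1, key_lead(p, couplet = target1),
                key_lead(pred_state("c1", "b"), taxon = "tX"))))
  expect_error(mk(2), "missing couplet")
  cyc <- list(
    key_couplet(1, key_lead(p, couplet = 2),
                key_lead(pred_state("c1", "b"), taxon = "tX")),
    key_couplet(2, key_lead(p, couplet = 1),
                key_lead(pred_state("c1", "b"), taxon = "tY")))
  expect_error(dich_key(cyc), "cycle")
  orphan <- list(
    key_couplet(1, key_lead(p, taxon = "tX"),
                key_lead(pred_state("c1", "b"), taxon = "tY")),
    key_couplet(2, key_lead(p, taxon = "tX"),
                key_lead(pred_state("c1", "b"), taxon = "tY")))
  expect_error(dich_key(orphan), "unreachable")
})

test_that("specimens descend the printed key with range and unknown semantics", {
  m <- load_table1()
  key <- load_key()
  # the re-examined holotype keys out as S. robertsi
  hol <- load_specimen_panels(m)$robertsi_holotype$specimens[[1]]
  tr <- evaluate_key(key, hol, m)
  expect_identical(tr$status, "unique")
  expect_identical(tr$terminals, "Schistura_robertsi")
  # a specimen observing only the absent lobe reaches all 8 lobe-absent taxa
  s <- specimen("only_lobe", list(axillary_lobe = obs_state("absent")))
  tr2 <- evaluate_key(key, s, m)
  expect_identical(tr2$status, "ambiguous")
  expect_length(tr2$terminals, 8L)
  # an impossible combination dead-ends
  s3 <- specimen("odd", list(axillary_lobe = obs_state("absent"),
                             anus_position = obs_state("closer_pelvic"),
                             pectoral_rays = obs_count(12)))
  expect_identical(evaluate_key(key, s3, m)$status, "dead_end")
  # predicates about characters unknown to both subject and matrix error
  bad <- dich_key(list(key_couplet(1,
    key_lead(pred_state("no_such", "x"), taxon = "Schistura_hartli"),
    key_lead(pred_state("no_such", "y"), taxon = "Schistura_kuehnei"))))
  expect_error(evaluate_key(bad, s, m), "absent from the subject")
})

test_that("taxon records route through the printed key as the matrix dictates", {
  m <- load_table1()
  key <- load_key()
  # clean cases
  for (tx in c("Schistura_cincticauda", "Schistura_hartli",
               "Schistura_myaekanbawensis", "Schistura_kuehnei",
               "Schistura_robertsi")) {
    tr <- evaluate_key(key, tx, m)
    expect_identical(tr$terminals, tx)
    expect_identical(tr$status, "unique")
  }
  # S. balteata reaches itself, but the body-pattern couplet is soft, so the
  # couplet-4 lead is also satisfiable from Table-row data alone
  trb <- evaluate_key(key, "Schistura_balteata", m)
  expect_true("Schistura_balteata" %in% trb$terminals)
  expect_true(all(c(1L, 2L, 3L) %in% trb$path))
})

test_that("verification flags the taxa the printed key cannot separate from the table", {
  m <- load_table1()
  key <- load_key()
  rep <- verify_key(key, m)
  expect_false(rep$ok)
  res <- rep$results
  # the anus-position conflict: S. aurantiaca dead-ends at couplet 8
  aur <- res[res$taxon == "Schistura_aurantiaca", ]
  expect_identical(aur$status, "dead_end")
  expect_identical(aur$first_issue_couplet, 8L)
  # a terminal missing from the matrix is a referential error
  key2 <- load_key()
  small <- morph_matrix(unname(m$characters), m$taxa[1:3],
                        m$values[1:3])
  expect_error(verify_key(key2, small), "not in matrix")
})

test_that("generated keys have n-1 couplets and verify perfectly on the table", {
  m <- load_table1()
  for (obj in c("minimax-branch", "min-expected-depth")) {
    key <- generate_key(m, objective = obj)
    expect_length(key$couplets, 11L)
    expect_length(key_terminals(key), 12L)
    rep <- verify_key(key, m)
    expect_true(rep$ok)
  }
})

test_that("generation is forced on two-taxon matrices and refuses duplicates", {
  doc <- paste("taxon\taxillary_lobe",
               "tA\tpresent", "tB\tabsent", sep = "\n")
  defs <- list(character_def("axillary_lobe", kind = "qualitative",
                             vocabulary = c("present", "absent")))
  m <- parse_matrix(doc, characters = defs)
  key <- generate_key(m)
  expect_length(key$couplets, 1L)
  expect_true(verify_key(key, m)$ok)
  dup <- parse_matrix(paste("taxon\taxillary_lobe",
                            "tA\tpresent", "tB\tpresent", sep = "\n"),
                      characters = defs)
  expect_error(generate_key(dup), "tA.*tB")
})

test_that("keys generated from seeded random matrices always verify", {
  n_checked <- 0L
  for (seed in 1:10) {
    cfg <- sim_config(n_taxa = 7L, n_characters = 8L,
                      polymorphism_rate = 0.1, unknown_rate = 0.05,
                      seed = seed)
    m <- random_matrix(cfg)
    chk <- unique_combination_check(m)
    if (!chk$ok) {
      expect_error(generate_key(m), "indistinguishable")
      next
    }
    key <- generate_key(m)
    expect_true(verify_key(key, m)$ok)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 5L)
})

test_that("terminal sets are monotone in the observations", {
  m <- load_table1()
  key <- load_key()
  set.seed(101)
  for (rep in 1:10) {
    tx <- sample(m$taxa, 1L)
    pan <- specimens_from_taxon(m, tx, 1L, seed = rep)
    s <- pan$specimens[[1]]
    full <- evaluate_key(key, s, m)$terminals
    drop_one <- sample(names(s$observations), 1L)
    s2 <- specimen(s$id, s$observations[setdiff(names(s$observations),
                                                drop_one)])
    reduced <- evaluate_key(key, s2, m)$terminals
    expect_true(all(full %in% reduced))
  }
})

test_that("rendered keys round-trip through the JSON sidecar", {
  key <- load_key()
  txt <- render_key(key)
  expect_identical(key_to_json(parse_rendered_key(txt)), key_to_json(key))
  expect_length(grep("^\\d+$", strsplit(txt, "\n")[[1]]), 11L)
  expect_match(txt, "\\*Schistura_robertsi\\*")
  # single-couplet key renders as one numbered block with two leads
  one <- dich_key(list(key_couplet(1,
    key_lead(pred_state("c1", "a"), taxon = "tA"),
    key_lead(pred_state("c1", "b"), taxon = "tB"))))
  lines <- strsplit(render_key(one, sidecar = FALSE), "\n")[[1]]
  expect_length(lines, 3L)
})
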