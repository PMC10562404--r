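# Packaged datasets: the comparison table, morphocode scheme, printed key,
# specimen panels and the constraints-only tree.

test_that("the comparison table loads with the published dimensions and flags", {
  m <- load_table1()
  expect_length(m$taxa, 12L)
  expect_length(m$characters, 18L)
  expect_identical(matrix_value(m, "Schistura_robertsi", "caudal_rays"),
                   caudal_formula(count_range(6, 7), count_range(6, 8)))
  # genetic data available for all species but S. paucifasciata
  expect_identical(sum(!m$taxon_meta$has_molecular_data), 1L)
  expect_false(m$taxon_meta$has_molecular_data[
    m$taxon_meta$taxon == "Schistura_paucifasciata"])
  expect_identical(sum(m$taxon_meta$literature_derived), 2L)
  expect_identical(sum(m$taxon_meta$newly_described), 5L)
  # the uncertain caudal entry keeps its annotation
  pf <- matrix_value(m, "Schistura_paucifasciata", "caudal_rays")
  expect_true(pf$uncertain)
  # unknown lip-mark cells stay unknown
  expect_true(is_unknown(matrix_value(m, "Schistura_paucifasciata",
                                      "lip_dots")))
})

test_that("the morphocode scheme matches the published state legends", {
  scheme <- load_morphocode()
  expect_identical(names(scheme$characters), LETTERS[1:12])
  C <- scheme$characters$C
  expect_identical(vapply(C$states, `[[`, "", "code"), c("0", "1", "2"))
  expect_identical(unlist(lapply(C$states, `[[`, "states")),
                   c("long", "intermediate", "short"))
  Lch <- scheme$characters$L
  expect_identical(sort(unique(c(Lch$default,
                                 unname(Lch$direct)))), c("0", "1", "2", "3"))
  Fch <- scheme$characters$F
  expect_identical(vapply(Fch$states, `[[`, "", "code"), c("0", "1"))
  expect_identical(unlist(lapply(Fch$states, `[[`, "states")),
                   c("absent", "present"))
  A <- scheme$characters$A
  expect_identical(lapply(A$states, `[[`, "values"),
                   list(9L, c(10L, 11L), 8L))
})

test_that("morphocode derivation emits one symbol per position and flags off-legend values", {
  m <- load_table1()
  derived <- derive_morphocode(m)
  expect_identical(names(derived$codes), m$taxa)
  n_positions <- function(code)
    length(regmatches(code, gregexpr("\\{[^}]*\\}|.", code))[[1]])
  expect_true(all(vapply(derived$codes, n_positions, 1L) == 12L))
  pos <- function(tx, p) {
    parts <- regmatches(derived$codes[[tx]],
                        gregexpr("\\{[^}]*\\}|.", derived$codes[[tx]]))[[1]]
    parts[p]
  }
  # H = black blotch posterior of the median incision: present in S. hartli
  expect_identical(pos("Schistura_hartli", 8L), "1")
  # A = pectoral rays: 10-11 codes as 1 in S. balteata
  expect_identical(pos("Schistura_balteata", 1L), "1")
  # S. robertsi pectoral 7-8 is off-legend: warning, resolved by overlap to 2
  expect_identical(pos("Schistura_robertsi", 1L), "2")
  expect_true(any(grepl("Schistura_robertsi, character A", derived$warnings)))
  # S. peninsulae pectoral 9-10 overlaps two legend states: brace set
  expect_identical(pos("Schistura_peninsulae", 1L), "{01}")
  # unknown matrix cells code as ? without a warning
  expect_identical(pos("Schistura_paucifasciata", 5L), "?")
  expect_false(any(grepl("character E", derived$warnings)))
  # the full set exports as a valid NEXUS block
  expect_match(write_nexus(derived$codes), "NTAX=12 NCHAR=12")
})

test_that("the printed key loads with 11 couplets and 12 distinct terminals", {
  key <- load_key()
  expect_length(key$couplets, 11L)
  expect_length(key_terminals(key), 12L)
  expect_setequal(key_terminals(key), group_taxa())
  # couplet 1, lead 1: axillary lobe present, routing to couplet 2
  l1 <- key$couplets[["1"]]$leads[[1]]
  expect_identical(l1$predicates[[1]]$char, "axillary_lobe")
  expect_identical(l1$predicates[[1]]$test$states, "present")
  expect_identical(l1$target$couplet, 2L)
  # couplet 9, lead 1: upper caudal lobe 6-7 and pectoral 7-8 -> S. robertsi
  l9 <- key$couplets[["9"]]$leads[[1]]
  tests <- lapply(l9$predicates, `[[`, "test")
  expect_identical(tests[[1]]$lobe, "upper")
  expect_identical(c(tests[[1]]$lo, tests[[1]]$hi), c(6L, 7L))
  expect_identical(c(tests[[2]]$lo, tests[[2]]$hi), c(7L, 8L))
  expect_identical(l9$target$taxon, "Schistura_robertsi")
})

test_that("the specimen panels carry the published counts", {
  m <- load_table1()
  panels <- load_specimen_panels(m)
  expect_length(panels$zrc_phuket, 20L)
  expect_length(panels$mcz_paratypes, 8L)
  expect_length(panels$robertsi_holotype, 1L)
  hol <- panels$robertsi_holotype$specimens[[1]]
  expect_identical(hol$observations$caudal_rays, obs_formula(7, 7))
  expect_identical(hol$observations$pectoral_rays, obs_count(c(7, 8)))
  # every Phuket specimen has 8 pectoral rays
  expect_true(all(vapply(panels$zrc_phuket$specimens, function(s)
    identical(s$observations$pectoral_rays, obs_count(8)), TRUE)))
})

test_that("the constraint tree honours its two supported clades", {
  tree <- load_constraint_tree(seed = 5)
  expect_true(isTRUE(attr(tree, "arbitrary_resolution")))
  expect_true(ape::is.binary(tree))
  cherry <- c("Schistura_balteata", "Schistura_paucifasciata")
  mrca <- ape::getMRCA(tree, cherry)
  expect_setequal(ape::extract.clade(tree, mrca)$tip.label, cherry)
  gmrca <- ape::getMRCA(tree, group_taxa())
  expect_setequal(ape::extract.clade(tree, gmrca)$tip.label, group_taxa())
  expect_false("outgroup" %in% ape::extract.clade(tree, gmrca)$tip.label)
  # seeded determinism
  expect_identical(ape::write.tree(load_constraint_tree(seed = 5)),
                   ape::write.tree(tree))
})
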