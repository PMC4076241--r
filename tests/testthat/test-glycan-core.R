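test_that("linkage text forms round-trip, including the Greek literature form", {
  l <- parse_linkage("β1,4")
  expect_equal(l$anomer, "b")
  expect_equal(l$donor_pos, 1L)
  expect_equal(l$acceptor_pos, 4L)
  expect_true(glyconet:::link_equal(l, parse_linkage(format_linkage(l, "greek"))))
  expect_true(glyconet:::link_equal(l, parse_linkage(format_linkage(l))))
  und <- parse_linkage("?1-?")
  expect_true(is.na(und$acceptor_pos))
  expect_equal(und$anomer, "?")
  expect_true(glyconet:::link_equal(und, parse_linkage(format_linkage(und))))
  expect_error(parse_linkage("g1-4"), "cannot parse")
  expect_error(linkage("b", 3, 4), "donor_pos")
})

test_that("LINUCS parses the core-2 trisaccharide into the expected tree", {
  g <- parse_linucs("[][GalNAc]{[(3+1)b-Gal][(6+1)b-GlcNAc]}")
  expect_equal(residue_count(g), 3L)
  expect_equal(g$root$sym, "GalNAc")
  expect_length(g$root$ch, 2L)
  expect_setequal(vapply(g$root$ch, `[[`, "", "sym"), c("Gal", "GlcNAc"))
  expect_identical(canonical_string(g), canonical_string(build_core2()))
})

test_that("a single residue is a valid one-node glycan", {
  g <- parse_linucs("[][Man]")
  expect_equal(residue_count(g), 1L)
  expect_equal(write_linucs(g), "[][Man]")
})

test_that("LINUCS parse errors name the offending token and position", {
  expect_error(parse_linucs("[][Glx]"), "unknown residue name 'Glx'")
  expect_error(parse_linucs("[][Man]{[(3+1)b-Gal]"), "position")
  expect_error(parse_linucs("[][Man]{}}"), "position")
})

test_that("random glycans round-trip through LINUCS and GlycoCT", {
  set.seed(42)
  for (i in 1:50) {
    g <- random_glycan(n_residues = sample(1:9, 1),
                       p_undetermined = if (i %% 5 == 0) 0.2 else 0)
    g2 <- parse_linucs(write_linucs(g))
    expect_identical(canonical_string(g2), canonical_string(g))
    expect_true(iso_glycan(g, g2))
    g3 <- parse_glycoct(write_glycoct(g))
    expect_identical(canonical_string(g3), canonical_string(g))
  }
})

test_that("GlycoCT writer emits one RES entry per residue and residues-1 LIN entries", {
  m5gn <- build_m5gn() # GlcNAcMan5GlcNAc2: 8 residues
  txt <- strsplit(write_glycoct(m5gn), "\n")[[1]]
  expect_equal(txt[1], "RES")
  res_n <- grep("^[0-9]+b:", txt)
  lin_n <- grep("^[0-9]+:[0-9]+o", txt)
  expect_length(res_n, 8L)
  expect_length(lin_n, 7L)
  man9 <- build_man9()
  expect_equal(residue_count(parse_glycoct(write_glycoct(man9))), 11L)
  expect_length(grep("^[0-9]+b:", strsplit(write_glycoct(man9), "\n")[[1]]), 11L)
})

test_that("GlycoCT writer output is byte-stable (golden form)", {
  golden <- paste(
    c("RES", "1b:x-dgalnac", "2b:b-dgal", "3b:b-dglcnac",
      "LIN", "1:1o(3+1)2d", "2:1o(6+1)3d"), collapse = "\n")
  expect_identical(write_glycoct(build_core2()), golden)
})

test_that("GlycoCT parse errors cover dangling indices and bad entries", {
  expect_error(parse_glycoct("RES\n1b:x-dman\nLIN\n1:1o(3+1)5d"),
               "undeclared residue")
  expect_error(parse_glycoct("RES\n1b:x-dman\n2b:q-dgal"), "bad RES entry")
  expect_error(parse_glycoct("LIN\n1:1o(3+1)2d"), "must begin with a RES")
  expect_error(parse_glycoct("RES\n1b:x-dfoo"), "unknown residue code")
})

test_that("canonical_string is sibling-order invariant and injective on isomers", {
  a <- parse_linucs("[][GlcNAc]{[(4+1)b-Gal][(3+1)a-Fuc]}")
  b <- parse_linucs("[][GlcNAc]{[(3+1)a-Fuc][(4+1)b-Gal]}")
  expect_identical(canonical_string(a), canonical_string(b))
  core13 <- parse_linucs("[][GalNAc]{[(3+1)b-Gal]}")
  core14 <- parse_linucs("[][GalNAc]{[(4+1)b-Gal]}")
  expect_false(canonical_string(core13) == canonical_string(core14))
})

test_that("canonical_string agrees with a brute-force isomorphism oracle", {
  set.seed(7)
  corpus <- replicate(60, random_glycan(n_residues = sample(2:7, 1)),
                      simplify = FALSE)
  keys <- vapply(corpus, canonical_string, "")
  for (i in seq_along(corpus)) {
    # stability under sibling shuffles
    for (r in 1:3) {
      expect_identical(canonical_string(shuffle_tree(corpus[[i]])), keys[i])
    }
  }
  # pairwise: equal keys <=> isomorphic trees
  for (i in seq_len(length(corpus) - 1L)) {
    for (j in seq((i + 1L), length(corpus))) {
      expect_identical(keys[i] == keys[j], iso_glycan(corpus[[i]], corpus[[j]]))
    }
  }
})

test_that("motif matching honors anchors, wildcards and absence", {
  bisected <- build_nglycan(a3 = list(nd("GlcNAc", "b1-2")),
                            a6 = list(nd("GlcNAc", "b1-2")), bisect = TRUE)
  chain <- glycan_motif(
    "[][GlcNAc]{[(4+1)b-GlcNAc]{[(4+1)b-Man]{[(4+1)b-GlcNAc]}}}",
    "at_reducing_end")
  expect_length(match_motif(bisected, chain), 1L)
  plain <- build_nglycan(a3 = list(nd("GlcNAc", "b1-2")))
  expect_length(match_motif(plain, chain), 0L)
  # floating single-residue motif: absent residue -> no match
  expect_length(match_motif(plain, glycan_motif("[][Gal]", "floating")), 0L)
  # self-match at the reducing end
  set.seed(11)
  for (i in 1:5) {
    g <- random_glycan(n_residues = sample(2:6, 1))
    expect_gte(length(match_motif(g, glycan_motif(g, "at_reducing_end"))), 1L)
  }
  # undetermined motif linkage matches any concrete linkage
  wild <- glycan_motif("[][GalNAc]{[(?+1)?-Gal]}", "at_reducing_end")
  expect_length(match_motif(build_core2(), wild), 1L)
})

test_that("attach/remove edit structures with value semantics", {
  m3 <- build_m3gn_gn()
  before <- canonical_string(m3)
  # find the free alpha1,6 core-arm mannose
  sites <- find_sites(db_get(builtin_database(), "GnTII")[[1]], m3)
  expect_length(sites, 1L)
  g2 <- attach_residue(m3, sites[[1]], "GlcNAc", "b1-2")
  expect_equal(residue_count(g2), residue_count(m3) + 1L)
  expect_identical(canonical_string(m3), before) # input untouched
  expect_identical(canonical_string(g2),
                   canonical_string(build_nglycan(a3 = list(nd("GlcNAc", "b1-2")),
                                                  a6 = list(nd("GlcNAc", "b1-2")))))
  # occupancy: carbon position can hold one substituent
  expect_error(attach_residue(g2, sites[[1]], "GlcNAc", "b1-2"), "occupied")
  # attach-then-remove at the same site restores the canonical string:
  # the added GlcNAc is the one whose parent mannose is alpha1,6-linked
  paths <- glyconet:::node_paths(g2)
  newnode <- Filter(function(pt) {
    nd <- glyconet:::get_node(g2, pt)
    if (length(nd$ch) || nd$sym != "GlcNAc" || is.null(nd$link) ||
        !identical(nd$link$acceptor_pos, 2L)) return(FALSE)
    par <- glyconet:::get_node(g2, pt[-length(pt)])
    !is.null(par$link) && format_linkage(par$link) == "a1-6"
  }, paths)
  g3 <- remove_residue(g2, newnode[[1]])
  expect_identical(canonical_string(g3), before)
  # removals must target terminal non-root residues
  expect_error(remove_residue(g2, integer(0)), "reducing-end")
  internal <- Filter(function(pt) length(glyconet:::get_node(g2, pt)$ch) > 0L &&
                       length(pt) > 0L, paths)
  expect_error(remove_residue(g2, internal[[1]]), "substituents")
})

test_that("composition counts residues by generic class", {
  expect_equal(unclass(composition(build_slex())),
               c(Hex = 1L, HexNAc = 1L, dHex = 1L, NeuAc = 1L))
  expect_equal(unclass(composition(parse_linucs("[][Man]"))), c(Hex = 1L))
  expect_equal(unclass(composition(build_m5gn())), c(Hex = 5L, HexNAc = 3L))
  # attaching one residue adds exactly one count of its class
  set.seed(3)
  for (i in 1:10) {
    g <- random_glycan(n_residues = sample(1:5, 1))
    free <- Filter(function(pt) {
      node <- glyconet:::get_node(g, pt)
      !any(vapply(node$ch, function(ch) identical(ch$link$acceptor_pos, 6L), TRUE))
    }, glyconet:::node_paths(g))
    if (!length(free)) next
    g2 <- attach_residue(g, free[[1]], "Fuc", "a1-6")
    d0 <- unclass(composition(g)); d1 <- unclass(composition(g2))
    expect_equal(sum(d1) - sum(d0), 1L)
    expect_equal(d1[["dHex"]], sum(c(d0["dHex"]), 1L, na.rm = TRUE))
  }
})
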