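test_that("an empty enzyme pool leaves only the seeds", {
  net <- forward_network(build_core2(), list())
  expect_equal(n_species(net), 1L)
  expect_equal(n_reactions(net), 0L)
})

test_that("forward inference is idempotent and seed-order invariant", {
  c2 <- case2_inputs()
  enzymes <- unlist(c2$enzyme_sets$five)
  net <- forward_network(c2$glycans[[1]], enzymes)
  again <- forward_network(unname(net$species), enzymes)
  expect_equal(n_species(again), n_species(net))
  expect_equal(n_reactions(again), n_reactions(net))
  # seed order: run from two seeds in both orders
  seeds <- list(c2$glycans[[1]], build_m3gn_gn())
  a <- forward_network(seeds, enzymes)
  b <- forward_network(rev(seeds), enzymes)
  expect_setequal(species_keys(a), species_keys(b))
  expect_equal(n_reactions(a), n_reactions(b))
})

test_that("adding an enzyme never removes species or reactions (monotonicity)", {
  c2 <- case2_inputs()
  net5 <- forward_network(c2$glycans[[1]], unlist(c2$enzyme_sets$five))
  net6 <- forward_network(c2$glycans[[1]], unlist(c2$enzyme_sets$six))
  expect_true(all(species_keys(net5) %in% species_keys(net6)))
  key5 <- with(net5$reactions, paste(substrate, product, enzyme))
  key6 <- with(net6$reactions, paste(substrate, product, enzyme))
  expect_true(all(key5 %in% key6))
})

test_that("open-ended poly-LacNAc extension trips the truncation flag", {
  net <- forward_network(build_core2(), c("GalT-IV", "b3GnT"), max_iter = 4L)
  expect_true(net$truncated)
})

test_that("reverse inference recovers the forward seed and reaction set", {
  c2 <- case2_inputs()
  enzymes <- unlist(c2$enzyme_sets$five)
  fwd <- forward_network(c2$glycans[[1]], enzymes)
  roles <- species_roles(fwd)
  terminals <- names(roles)[vapply(names(roles), function(k) {
    !k %in% fwd$reactions$substrate
  }, TRUE)]
  max_sz <- max(vapply(fwd$species, residue_count, 0L))
  rev_net <- reverse_network(unname(fwd$species[terminals]), enzymes,
                             max_size = max_sz)
  expect_true(canonical_string(c2$glycans[[1]]) %in% species_keys(rev_net))
  # reverse of the full species set reproduces a superset of fwd reactions
  rev_all <- reverse_network(unname(fwd$species), enzymes, max_size = max_sz)
  kf <- with(fwd$reactions, paste(substrate, product, enzyme))
  kr <- with(rev_all$reactions, paste(substrate, product, enzyme))
  expect_true(all(kf %in% kr))
})

test_that("reverse inference of a single residue is a bare pathway", {
  net <- reverse_network(parse_linucs("[][Man]"), c("GalT-IV", "b3GnT"))
  expect_equal(n_species(net), 1L)
  expect_equal(n_reactions(net), 0L)
})

test_that("a single-step pair is connected with one reaction", {
  a <- build_nglycan(a3 = list(nd("GlcNAc", "b1-2")), a6 = list(nd("GlcNAc", "b1-2")))
  b <- attach_residue(a, find_sites(db_get(builtin_database(), "GalT-IV")[[1]], a)[[1]],
                      "Gal", "b1-4")
  net <- connection_network(list(a, b), "GalT-IV")
  # two sites give two monogalactosylated isomers, but only the chain
  # reaching b is part of the connection
  expect_equal(n_species(net), 2L)
  expect_equal(n_reactions(net), 1L)
})

test_that("connection inference logs m(m-1)/2 pair analyses", {
  gl <- case1_inputs()$glycans[1:5]
  net <- connection_network(gl, unlist(case1_inputs()$enzymes))
  expect_equal(net$pairs_analyzed, 5L * 4L / 2L)
})

test_that("the O-linked case study reproduces its published network exactly", {
  c1 <- case1_inputs()
  net <- connection_network(c1$glycans, unlist(c1$enzymes), labels = c1$labels)
  expect_equal(n_species(net), 20L)
  expect_equal(n_reactions(net), 28L)
  roles <- species_roles(net)
  expect_equal(sum(roles == "inferred_intermediate"), 7L)
  # conservation: every inferred intermediate is consumed and produced
  interm <- names(roles)[roles == "inferred_intermediate"]
  for (k in interm) {
    expect_true(k %in% net$reactions$substrate, label = "intermediate consumed")
    expect_true(k %in% net$reactions$product, label = "intermediate produced")
  }
})

test_that("the N-linked case study reproduces both published network sizes", {
  c2 <- case2_inputs()
  net5 <- forward_network(c2$glycans[[1]], unlist(c2$enzyme_sets$five))
  expect_equal(n_species(net5), 14L)
  expect_equal(n_reactions(net5), 14L)
  net6 <- forward_network(c2$glycans[[1]], unlist(c2$enzyme_sets$six))
  expect_equal(n_species(net6), 28L)
  expect_equal(n_reactions(net6), 28L)
  # bisected species are terminal for branching/trimming enzymes
  db <- builtin_database()
  bisect <- glycan_motif(
    "[][GlcNAc]{[(4+1)b-GlcNAc]{[(4+1)b-Man]{[(4+1)b-GlcNAc]}}}",
    "at_reducing_end")
  for (k in species_keys(net5)) {
    g <- net5$species[[k]]
    if (length(match_motif(g, bisect))) {
      for (nm in c("GnTII", "GnTIV", "GnTV", "ManII")) {
        expect_length(infer_products(db_get(db, nm)[[1]], g), 0L)
      }
    }
  }
})
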