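db <- builtin_database()
enz <- function(nm) db_get(db, nm)[[1]]

test_that("GnTII acts on GlcNAcMan3GlcNAc2 at exactly the free alpha1,6 mannose", {
  g <- build_m3gn_gn()
  expect_true(can_act(enz("GnTII"), g))
  sites <- find_sites(enz("GnTII"), g)
  expect_length(sites, 1L)
  site <- glyconet:::get_node(g, sites[[1]])
  expect_equal(site$sym, "Man")
  expect_equal(format_linkage(site$link), "a1-6")
  rxns <- infer_products(enz("GnTII"), g)
  expect_length(rxns, 1L)
  expected <- build_nglycan(a3 = list(nd("GlcNAc", "b1-2")),
                            a6 = list(nd("GlcNAc", "b1-2")))
  expect_identical(canonical_string(rxns[[1]]$product), canonical_string(expected))
  expect_equal(rxns[[1]]$direction, "transfer")
})

test_that("blocking constraints are absolute", {
  # bisecting GlcNAc inhibits mannosidase II trimming
  bisected_m5gn <- build_nglycan(
    a3 = list(nd("GlcNAc", "b1-2")),
    a6 = list(nd("Man", "a1-3"), nd("Man", "a1-6")), bisect = TRUE)
  expect_false(can_act(enz("ManII"), bisected_m5gn))
  expect_length(infer_products(enz("ManII"), bisected_m5gn), 0L)
  # galactosylation prevents further GnT branching
  galactosylated <- build_nglycan(
    a3 = list(nd("GlcNAc", "b1-2", list(nd("Gal", "b1-4")))),
    a6 = list(nd("GlcNAc", "b1-2")))
  for (nm in c("GnTIII", "GnTIV", "GnTV")) {
    expect_false(can_act(enz(nm), galactosylated), label = nm)
  }
})

test_that("mannosidase II finds the two trimmable mannoses of M5Gn", {
  m5gn <- build_m5gn()
  sites <- find_sites(enz("ManII"), m5gn)
  expect_length(sites, 2L)
  links <- vapply(sites, function(s) format_linkage(glyconet:::get_node(m5gn, s)$link), "")
  expect_setequal(links, c("a1-3", "a1-6"))
  rxns <- infer_products(enz("ManII"), m5gn)
  expect_length(rxns, 2L) # two distinct single-trimmed products
  expect_true(all(vapply(rxns, function(r) residue_count(r$product), 0L) == 7L))
  expect_true(all(vapply(rxns, `[[`, "", "direction") == "hydrolysis"))
})

test_that("site multiplicity: a galactosyltransferase with two free acceptor antennae", {
  g <- build_nglycan(a3 = list(nd("GlcNAc", "b1-2")), a6 = list(nd("GlcNAc", "b1-2")))
  galt <- enz("GalT-IV")
  expect_length(find_sites(galt, g), 2L)
  rxns <- infer_products(galt, g)
  # brute-force oracle: attach at each site independently and deduplicate
  sites <- find_sites(galt, g)
  brute <- unique(vapply(sites, function(s) {
    canonical_string(attach_residue(g, s, "Gal", "b1-4"))
  }, ""))
  expect_length(rxns, length(brute))
  expect_setequal(vapply(rxns, function(r) canonical_string(r$product), ""), brute)
})

test_that("substrate inference inverts the published GnTII step and honors can_act", {
  product <- build_nglycan(a3 = list(nd("GlcNAc", "b1-2")),
                           a6 = list(nd("GlcNAc", "b1-2")))
  back <- infer_substrates(enz("GnTII"), product)
  expect_length(back, 1L)
  expect_identical(canonical_string(back[[1]]$substrate),
                   canonical_string(build_m3gn_gn()))
  # a product with no beta1,2 GlcNAc on the alpha1,6 arm has no GnTII precursor
  expect_length(infer_substrates(enz("GnTII"), build_m3gn_gn()), 0L)
})

test_that("forward/reverse inference are dual over the case-study reaction space", {
  # every reaction discovered forward must be recovered by reverse inference
  c2 <- case2_inputs()
  net <- forward_network(c2$glycans[[1]], unlist(c2$enzyme_sets$six))
  c1 <- case1_inputs()
  net1 <- connection_network(c1$glycans, unlist(c1$enzymes))
  pool <- c(lapply(species_keys(net), function(k) net$species[[k]]),
            lapply(species_keys(net1), function(k) net1$species[[k]]))
  enzymes <- db_get(db, unique(c(unlist(c2$enzyme_sets$six), unlist(c1$enzymes))))
  checked <- 0L
  for (g in pool) {
    for (e in enzymes) {
      for (r in infer_products(e, g)) {
        subs <- infer_substrates(e, r$product)
        expect_true(canonical_string(g) %in%
                      vapply(subs, function(x) canonical_string(x$substrate), ""),
                    label = paste(e$name, "duality"))
        checked <- checked + 1L
      }
    }
  }
  expect_gte(checked, 100L)
})

test_that("mass balance: one residue of resfuncgroup class per reaction", {
  set.seed(21)
  c2 <- case2_inputs()
  net <- forward_network(c2$glycans[[1]], unlist(c2$enzyme_sets$six))
  enzymes <- db_get(db, unlist(c2$enzyme_sets$six))
  for (key in species_keys(net)) {
    g <- net$species[[key]]
    for (e in enzymes) {
      for (r in infer_products(e, g)) {
        d <- residue_count(r$product) - residue_count(r$substrate)
        expect_equal(abs(d), 1L)
        expect_equal(d > 0, e$kind == "GT")
        cls <- residue_class(e$resfuncgroup)
        cs <- unclass(composition(r$substrate)); cp <- unclass(composition(r$product))
        cs <- cs[names(.RES_NME)][match(names(.RES_NME), names(cs))]
        delta <- sum(cp, na.rm = TRUE) - sum(cs, na.rm = TRUE)
        expect_equal(abs(delta), 1L)
      }
    }
  }
})

test_that("inference output order is deterministic across runs", {
  g <- build_nglycan(a3 = list(nd("GlcNAc", "b1-2")), a6 = list(nd("GlcNAc", "b1-2")))
  r1 <- infer_products(enz("GalT-IV"), g)
  r2 <- infer_products(enz("GalT-IV"), g)
  expect_identical(vapply(r1, function(r) canonical_string(r$product), ""),
                   vapply(r2, function(r) canonical_string(r$product), ""))
  expect_identical(names(r1), sort(names(r1), method = "radix"))
})
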