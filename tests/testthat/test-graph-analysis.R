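case1_net <- local({
  c1 <- case1_inputs()
  connection_network(c1$glycans, unlist(c1$enzymes), labels = c1$labels)
})

test_that("path finding matches a brute-force enumeration on random graphs", {
  set.seed(19)
  for (rep in 1:60) {
    nn <- sample(4:12, 1)
    p <- random_pathway(nn, n_edges = sample(nn:(2L * nn), 1),
                        acyclic = rep %% 3 != 0)
    keys <- species_keys(p)
    st <- sample(keys, 2)
    got <- path_finding(p, st[1], st[2])
    edges <- data.frame(from = p$reactions$substrate, to = p$reactions$product,
                        label = p$reactions$enzyme, stringsAsFactors = FALSE)
    want <- brute_paths(edges, st[1], st[2])
    expect_identical(path_signature(got), path_signature(want))
  }
})

test_that("source equal to target yields one zero-length path; unknown species error", {
  k <- species_keys(case1_net)[1]
  paths <- path_finding(case1_net, k, k)
  expect_length(paths, 1L)
  expect_length(paths[[1]]$enzymes, 0L)
  expect_error(path_finding(case1_net, "nonexistent", k), "not found")
})

test_that("the start-to-sLeX path union is a sub-network of the master pathway", {
  paths <- path_finding(case1_net, "glycan00", "glycan09")
  expect_gt(length(paths), 0L)
  sub <- path_subnetwork(case1_net, "glycan00", "glycan09")
  expect_true(all(species_keys(sub) %in% species_keys(case1_net)))
  ks <- with(sub$reactions, paste(substrate, product, enzyme))
  km <- with(case1_net$reactions, paste(substrate, product, enzyme))
  expect_true(all(ks %in% km))
  expect_gt(n_species(sub), 2L)
  # both endpoints present
  labs <- species_labels(sub)
  expect_true(all(c("glycan00", "glycan09") %in% labs))
})

test_that("species deletion and retention behave as set operations", {
  # deleting one sLeX product leaves the other route intact
  del5 <- subnet_by_spec_del(case1_net, "glycan05")
  expect_gt(length(path_finding(del5, "glycan00", "glycan09")), 0L)
  expect_false("glycan05" %in% species_labels(del5))
  # keep everything = identity; delete nothing = identity
  keep_all <- subnet_by_spec_keep(case1_net, species_keys(case1_net))
  expect_setequal(species_keys(keep_all), species_keys(case1_net))
  expect_equal(n_reactions(keep_all), n_reactions(case1_net))
  del_none <- subnet_by_spec_del(case1_net, character(0))
  expect_setequal(species_keys(del_none), species_keys(case1_net))
  expect_error(subnet_by_spec_del(case1_net, "no_such_species"), "not found")
})

test_that("deleting all neighbors of a species removes it as isolated", {
  labs <- species_labels(case1_net)
  g01 <- names(labs)[labs == "glycan01"] # sialyl core-2: neighbors are few
  nbrs <- unique(c(case1_net$reactions$substrate[case1_net$reactions$product == g01],
                   case1_net$reactions$product[case1_net$reactions$substrate == g01]))
  out <- subnet_by_spec_del(case1_net, nbrs)
  expect_false(g01 %in% species_keys(out))
})

test_that("isolated species detection and removal are exact and idempotent", {
  orphan <- random_glycan(4)
  p <- case1_net
  p <- glyconet:::pw_add_species(p, orphan)
  expect_identical(detect_isolated_species(p), canonical_string(orphan))
  cleaned <- remove_isolated_species(p)
  expect_false(canonical_string(orphan) %in% species_keys(cleaned))
  expect_identical(species_keys(remove_isolated_species(cleaned)),
                   species_keys(cleaned))
  # a fully connected network has no isolated species
  c2 <- case2_inputs()
  net5 <- forward_network(c2$glycans[[1]], unlist(c2$enzyme_sets$five))
  expect_length(detect_isolated_species(net5), 0L)
  # with no reactions at all, isolation is undefined and nothing is removed
  bare <- pathway(list(orphan))
  expect_length(detect_isolated_species(bare), 0L)
})

test_that("counted deletion examines exactly choose(deletable, k) candidates", {
  res <- subnet_by_num_del(case1_net, 1, protected = "glycan00",
                           require_any = c("glycan05", "glycan09"),
                           include_invalid = TRUE, keep_pathways = FALSE)
  expect_length(res, choose(19, 1))
  res2 <- subnet_by_num_del(case1_net, 2, protected = "glycan00",
                            require_any = c("glycan05", "glycan09"),
                            include_invalid = TRUE, keep_pathways = FALSE)
  expect_length(res2, choose(19, 2))
  expect_error(subnet_by_num_del(case1_net, 20, protected = "glycan00"),
               "between 1 and")
})

test_that("generated subset pathways are clean sub-networks of the master", {
  res <- subnet_by_num_del(case1_net, 2, protected = "glycan00",
                           require_any = c("glycan05", "glycan09"))
  expect_gt(length(res), 0L)
  roles <- species_roles(case1_net)
  for (r in res[seq_len(min(25, length(res)))]) {
    expect_true(r$valid)
    q <- r$pathway
    expect_true(all(species_keys(q) %in% species_keys(case1_net)))
    kq <- with(q$reactions, paste(substrate, product, enzyme))
    km <- with(case1_net$reactions, paste(substrate, product, enzyme))
    expect_true(all(kq %in% km))
    expect_length(detect_isolated_species(q), 0L)
    expect_false(any(r$deleted %in% species_keys(q)))
    # surviving in-silico intermediates flow
    interm <- intersect(names(roles)[roles == "inferred_intermediate"], species_keys(q))
    for (k in interm) {
      expect_true(k %in% q$reactions$substrate && k %in% q$reactions$product)
    }
  }
})

test_that("the sweep counter agrees with the explicit subset generator", {
  for (k in 1:2) {
    res <- subnet_by_num_del(case1_net, k, protected = "glycan00",
                             require_any = c("glycan05", "glycan09"))
    nets <- unique(vapply(res, function(r) {
      paste(sort(species_keys(r$pathway)), collapse = ";")
    }, ""))
    sw_d <- subset_sweep(case1_net, k, protected = "glycan00",
                         require_any = c("glycan05", "glycan09"))
    sw_v <- subset_sweep(case1_net, k, protected = "glycan00",
                         require_any = c("glycan05", "glycan09"), distinct = FALSE)
    expect_equal(unname(sw_d), length(nets))
    expect_equal(unname(sw_v), length(res))
  }
})

test_that("seeded random sampling mode draws the requested number of candidates", {
  set.seed(5)
  res <- subnet_by_num_del(case1_net, 3, protected = "glycan00",
                           require_any = c("glycan05", "glycan09"),
                           include_invalid = TRUE, sample_n = 40,
                           keep_pathways = FALSE)
  expect_length(res, 40L)
})
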