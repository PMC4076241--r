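# Independent oracles and shared builders. Everything here is written
# against first principles (explicit permutation enumeration, recursive
# path enumeration, atomic-mass bookkeeping) and never calls the package
# code paths it is used to check.

# ---- structure builders -----------------------------------------------------

nd <- function(sym, link = NULL, kids = list()) glycan_node(sym, link, kids)

build_core2 <- function() {
  glycan(nd("GalNAc", kids = list(nd("Gal", "b1-3"), nd("GlcNAc", "b1-6"))))
}

build_slex <- function() {
  glycan(nd("GlcNAc", kids = list(
    nd("Fuc", "a1-3"),
    nd("Gal", "b1-4", list(nd("Neu5Ac", "a2-3"))))))
}

# N-glycan scaffold: core GlcNAc2Man3 with configurable arms
build_nglycan <- function(a3 = list(), a6 = list(), bisect = FALSE, fuc = FALSE) {
  core_kids <- list(nd("Man", "a1-3", a3), nd("Man", "a1-6", a6))
  if (bisect) core_kids <- c(core_kids, list(nd("GlcNAc", "b1-4")))
  root_kids <- list(nd("GlcNAc", "b1-4", list(nd("Man", "b1-4", core_kids))))
  if (fuc) root_kids <- c(root_kids, list(nd("Fuc", "a1-6")))
  glycan(nd("GlcNAc", kids = root_kids))
}

build_m5gn <- function() {
  build_nglycan(a3 = list(nd("GlcNAc", "b1-2")),
                a6 = list(nd("Man", "a1-3"), nd("Man", "a1-6")))
}

build_m3gn_gn <- function() { # GlcNAcMan3GlcNAc2 (GnT II substrate of Fig 2B)
  build_nglycan(a3 = list(nd("GlcNAc", "b1-2")))
}

build_man9 <- function() { # Man9GlcNAc2
  m2 <- function() nd("Man", "a1-2")
  build_nglycan(
    a3 = list(nd("Man", "a1-2", list(m2()))),
    a6 = list(nd("Man", "a1-3", list(m2())), nd("Man", "a1-6", list(m2()))))
  # arms: a1,3 arm Man-a1,2-Man-a1,2; a1,6 arm (Man-a1,2 | Man-a1,2)
}

# ---- brute-force rooted-tree isomorphism -----------------------------------

link_same <- function(a, b) {
  if (is.null(a) && is.null(b)) return(TRUE)
  if (is.null(a) || is.null(b)) return(FALSE)
  identical(a$anomer, b$anomer) && identical(a$donor_pos, b$donor_pos) &&
    identical(a$acceptor_pos, b$acceptor_pos)
}

perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

iso_node <- function(a, b) {
  if (a$sym != b$sym) return(FALSE)
  if (!link_same(a$link, b$link)) return(FALSE)
  na <- length(a$ch)
  if (na != length(b$ch)) return(FALSE)
  if (na == 0L) return(TRUE)
  for (p in perms(seq_len(na))) {
    ok <- TRUE
    for (i in seq_len(na)) {
      if (!iso_node(a$ch[[i]], b$ch[[p[i]]])) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

iso_glycan <- function(a, b) iso_node(a$root, b$root)

# random shuffle of sibling order, recursively (bypasses canonical ordering)
shuffle_tree <- function(g) {
  rec <- function(node) {
    if (length(node$ch)) {
      node$ch <- lapply(node$ch, rec)
      node$ch <- node$ch[sample.int(length(node$ch))]
    }
    node
  }
  out <- g
  out$root <- rec(out$root)
  out
}

# ---- brute-force all simple paths ------------------------------------------

# edges: data.frame(from, to, label); enumerate all simple paths source ->
# target by plain recursion over outgoing edges (parallel edges distinct).
brute_paths <- function(edges, source, target) {
  out <- list()
  rec <- function(node, visited, nodes_acc, labels_acc) {
    if (node == target) {
      out[[length(out) + 1L]] <<- list(species = nodes_acc, enzymes = labels_acc)
      return()
    }
    idx <- which(edges$from == node)
    for (i in idx) {
      nxt <- edges$to[i]
      if (nxt %in% visited) next
      rec(nxt, c(visited, nxt), c(nodes_acc, nxt), c(labels_acc, edges$label[i]))
    }
  }
  if (source == target) return(list(list(species = source, enzymes = character(0))))
  rec(source, source, source, character(0))
  out
}

path_signature <- function(paths) {
  sort(vapply(paths, function(p) {
    paste(paste(p$species, collapse = ">"), paste(p$enzymes, collapse = ","), sep = "|")
  }, ""))
}

# random pathway over distinct random glycans with random edges
random_pathway <- function(n_nodes, n_edges, acyclic = TRUE) {
  gl <- list()
  while (length(gl) < n_nodes) {
    g <- random_glycan(n_residues = sample(2:5, 1))
    gl[[canonical_string(g)]] <- g
  }
  gl <- gl[seq_len(n_nodes)]
  rxns <- list()
  for (i in seq_len(n_edges)) {
    ab <- sample.int(n_nodes, 2)
    if (acyclic) ab <- sort(ab)
    rxns[[i]] <- glyconet:::new_rxn(gl[[ab[1]]], gl[[ab[2]]],
                                    sample(c("enzA", "enzB", "enzC"), 1), "transfer")
  }
  pathway(unname(gl), rxns)
}

# ---- independent composition-mass oracle -----------------------------------

# atomic monoisotopic masses
.AT <- c(C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
         Na = 22.9897692809, e = 0.00054857991)

formula_mass <- function(counts) sum(.AT[names(counts)] * counts)

# residue formulas (in-chain), native
.RES_FORMULA <- list(
  Hex = c(C = 6, H = 10, O = 5, N = 0),
  HexNAc = c(C = 8, H = 13, O = 5, N = 1),
  dHex = c(C = 6, H = 10, O = 4, N = 0),
  NeuAc = c(C = 11, H = 17, O = 8, N = 1))
# methylation sites per residue class
.RES_NME <- c(Hex = 3, HexNAc = 3, dHex = 2, NeuAc = 5)

oracle_perm_sodiated_mz <- function(counts) {
  m <- 0
  for (cls in names(counts)) {
    f <- .RES_FORMULA[[cls]]
    f["C"] <- f["C"] + .RES_NME[[cls]]          # CH2 per methylation site
    f["H"] <- f["H"] + 2 * .RES_NME[[cls]]
    m <- m + formula_mass(f) * counts[[cls]]
  }
  # water + two reducing-end methyls + sodium cation
  m + formula_mass(c(H = 2, O = 1)) + 2 * formula_mass(c(C = 1, H = 2)) +
    .AT[["Na"]] - .AT[["e"]]
}
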