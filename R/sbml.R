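# SBML export/import. Each glycan species carries its structure inside the
# SBML <annotation> element as a <glycoct> element in the
# http://www.eurocarbdb.org/recommendations/encoding namespace, with
# <sugar><residues>/<linkages> children mirroring the RES/LIN sections of
# the condensed encoding. Enzymes are declared as boundary species (ids
# prefixed "enz_") and attached to reactions as modifiers.

SBML_NS <- "http://www.sbml.org/sbml/level2/version4"
GLYCOCT_NS <- "http://www.eurocarbdb.org/recommendations/encoding"

# djb2 string hash reduced mod 2^31 (exact in doubles) -> 8 hex chars;
# deterministic species ids without an external digest dependency.
str_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483648
  sprintf("%08x", h)
}

species_ids <- function(p) {
  keys <- species_keys(p)
  ids <- vapply(keys, function(k) paste0("gly_", str_hash(k)), "")
  # disambiguate improbable collisions deterministically
  while (anyDuplicated(ids)) {
    d <- which(duplicated(ids))
    ids[d] <- paste0(ids[d], "x")
  }
  stats::setNames(ids, keys)
}

glycan_annotation_xml <- function(g) {
  # returns list(residue rows, linkage rows) matching write_glycoct numbering
  res <- list(); lin <- list()
  idx <- 0L
  rec <- function(node, parent_idx) {
    idx <<- idx + 1L
    my <- idx
    res[[my]] <<- c(id = as.character(my), name = node$sym,
                    anomer = if (is.null(node$link)) "x" else sub("\\?", "x", node$link$anomer))
    if (!is.null(node$link)) {
      lin[[length(lin) + 1L]] <<- c(
        id = as.character(length(lin) + 1L),
        parent = as.character(parent_idx), child = as.character(my),
        acceptorPosition = as.character(
          if (is.na(node$link$acceptor_pos)) -1L else node$link$acceptor_pos),
        donorPosition = as.character(node$link$donor_pos))
    }
    for (ch in node$ch) rec(ch, my)
  }
  rec(g$root, 0L)
  list(residues = res, linkages = lin)
}

#' Export a pathway to SBML
#'
#' Writes an SBML Level 2 Version 4 document: one species per glycan (id =
#' `gly_` + hash of the canonical string) with the structure embedded as a
#' `glycoct` annotation element, one reaction per pathway reaction with the
#' enzyme as a modifier species (`enz_` prefix) and as the reaction `name`.
#'
#' @param p a `glyco_pathway`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(p, path) {
  stopifnot(inherits(p, "glyco_pathway"))
  ids <- species_ids(p)
  labs <- species_labels(p)
  roles <- species_roles(p)
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, level = "2", version = "4")
  model <- xml2::xml_add_child(doc, "model", id = "glycosylation_pathway")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1")
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (key in species_keys(p)) {
    sp <- xml2::xml_add_child(los, "species", id = ids[[key]],
                              name = labs[[key]], compartment = "cell",
                              initialAmount = "0")
    if (!is.na(roles[[key]])) xml2::xml_set_attr(sp, "sboTerm", "SBO:0000247")
    ann <- xml2::xml_add_child(sp, "annotation")
    gct <- xml2::xml_add_child(ann, "glycoct", xmlns = GLYCOCT_NS)
    if (!is.na(roles[[key]])) xml2::xml_set_attr(gct, "role", roles[[key]])
    sugar <- xml2::xml_add_child(gct, "sugar", version = "1.0")
    parts <- glycan_annotation_xml(p$species[[key]])
    residues <- xml2::xml_add_child(sugar, "residues")
    for (r in parts$residues) {
      do.call(xml2::xml_add_child, c(list(residues, "residue"), as.list(r)))
    }
    linkages <- xml2::xml_add_child(sugar, "linkages")
    for (l in parts$linkages) {
      do.call(xml2::xml_add_child, c(list(linkages, "linkage"), as.list(l)))
    }
  }
  enzymes <- unique(p$reactions$enzyme)
  if (length(enzymes)) {
    for (e in enzymes) {
      xml2::xml_add_child(los, "species", id = paste0("enz_", e), name = e,
                          compartment = "cell", boundaryCondition = "true")
    }
  }
  if (nrow(p$reactions)) {
    lor <- xml2::xml_add_child(model, "listOfReactions")
    for (i in seq_len(nrow(p$reactions))) {
      rx <- p$reactions[i, ]
      rxn <- xml2::xml_add_child(lor, "reaction", id = sprintf("r%03d", i),
                                 name = rx$enzyme, reversible = "false")
      lre <- xml2::xml_add_child(rxn, "listOfReactants")
      xml2::xml_add_child(lre, "speciesReference", species = ids[[rx$substrate]])
      lpr <- xml2::xml_add_child(rxn, "listOfProducts")
      xml2::xml_add_child(lpr, "speciesReference", species = ids[[rx$product]])
      lmo <- xml2::xml_add_child(rxn, "listOfModifiers")
      xml2::xml_add_child(lmo, "modifierSpeciesReference",
                          species = paste0("enz_", rx$enzyme))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

parse_annotation_glycan <- function(gct_node) {
  residues <- xml2::xml_find_all(gct_node, ".//residue")
  linkages <- xml2::xml_find_all(gct_node, ".//linkage")
  nres <- length(residues)
  if (!nres) stop("glycoct annotation has no residues", call. = FALSE)
  syms <- character(nres); anom <- character(nres)
  for (r in residues) {
    i <- as.integer(xml2::xml_attr(r, "id"))
    syms[i] <- xml2::xml_attr(r, "name")
    anom[i] <- xml2::xml_attr(r, "anomer")
  }
  parent <- rep(NA_integer_, nres)
  links <- vector("list", nres)
  for (l in linkages) {
    child <- as.integer(xml2::xml_attr(l, "child"))
    parent[child] <- as.integer(xml2::xml_attr(l, "parent"))
    ap <- as.integer(xml2::xml_attr(l, "acceptorPosition"))
    links[[child]] <- linkage(if (anom[child] == "x") "?" else anom[child],
                              as.integer(xml2::xml_attr(l, "donorPosition")),
                              if (ap < 0L) NA_integer_ else ap)
  }
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("glycoct annotation is not a single tree", call. = FALSE)
  nodes <- lapply(seq_len(nres), function(i) new_node(syms[i], links[[i]]))
  depth <- vapply(seq_len(nres), function(i) {
    d <- 0L; while (!is.na(parent[i])) { i <- parent[i]; d <- d + 1L }; d
  }, 0L)
  for (i in order(depth, decreasing = TRUE)) {
    if (!is.na(parent[i])) {
      nodes[[parent[i]]]$ch[[length(nodes[[parent[i]]]$ch) + 1L]] <- nodes[[i]]
    }
  }
  glycan(nodes[[root]])
}

#' Import a pathway from SBML
#'
#' Reads a document produced by [export_sbml()] (or any SBML whose species
#' carry parseable `glycoct` annotations). A non-enzyme species without a
#' `glycoct` annotation is a schema error naming the species id.
#'
#' @param path SBML file path.
#' @return a `glyco_pathway`.
#' @export
import_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error: ", conditionMessage(e),
                                           call. = FALSE))
  doc <- xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp_nodes)) {
    # distinguish empty-model documents from non-SBML XML
    if (!length(xml2::xml_find_all(doc, ".//model"))) {
      stop("SBML schema error: no model element found", call. = FALSE)
    }
  }
  glycans <- list(); labels <- list(); roles <- list()
  for (sp in sp_nodes) {
    id <- xml2::xml_attr(sp, "id")
    if (startsWith(id, "enz_")) next
    gct <- xml2::xml_find_first(sp, ".//glycoct")
    if (inherits(gct, "xml_missing")) {
      stop("SBML schema error: species '", id, "' lacks a glycoct annotation",
           call. = FALSE)
    }
    g <- parse_annotation_glycan(gct)
    key <- canonical_string(g)
    glycans[[id]] <- g
    labels[[id]] <- xml2::xml_attr(sp, "name")
    role <- xml2::xml_attr(gct, "role")
    roles[[id]] <- role
  }
  p <- new_pathway()
  key_of <- character(0)
  for (id in names(glycans)) {
    g <- glycans[[id]]
    key <- canonical_string(g)
    key_of[[id]] <- key
    p <- pw_add_species(p, g,
                        role = if (is.na(roles[[id]])) NA_character_ else roles[[id]],
                        label = if (is.na(labels[[id]])) NULL else labels[[id]])
  }
  for (rxn in xml2::xml_find_all(doc, ".//listOfReactions/reaction")) {
    sub_id <- xml2::xml_attr(xml2::xml_find_first(rxn, ".//listOfReactants/speciesReference"),
                             "species")
    prod_id <- xml2::xml_attr(xml2::xml_find_first(rxn, ".//listOfProducts/speciesReference"),
                              "species")
    enz <- xml2::xml_attr(xml2::xml_find_first(rxn, ".//listOfModifiers/modifierSpeciesReference"),
                          "species")
    enz <- if (is.na(enz)) xml2::xml_attr(rxn, "name") else sub("^enz_", "", enz)
    if (is.na(sub_id) || is.na(prod_id) ||
        !sub_id %in% names(key_of) || !prod_id %in% names(key_of)) {
      stop("SBML schema error: reaction '", xml2::xml_attr(rxn, "id"),
           "' references undeclared species", call. = FALSE)
    }
    ks <- key_of[[sub_id]]; kp <- key_of[[prod_id]]
    dir <- if (residue_count(p$species[[kp]]) >= residue_count(p$species[[ks]]))
      "transfer" else "hydrolysis"
    r <- new_rxn(p$species[[ks]], p$species[[kp]], enz, dir)
    p <- pw_add_rxn(p, r)
  }
  p
}

# ---- graph file export ------------------------------------------------------

#' Export a pathway graph to DOT or GraphML
#'
#' Nodes are labeled with species display labels and roles; edges with
#' enzyme names.
#'
#' @param p a `glyco_pathway`.
#' @param path output file path.
#' @param format `"DOT"` or `"GraphML"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(p, path, format = c("DOT", "GraphML")) {
  format <- match.arg(format)
  stopifnot(inherits(p, "glyco_pathway"))
  if (format == "DOT") {
    ids <- species_ids(p)
    labs <- species_labels(p)
    roles <- species_roles(p)
    lines <- c("digraph pathway {")
    for (key in species_keys(p)) {
      role <- if (is.na(roles[[key]])) "" else paste0("\\n(", roles[[key]], ")")
      lines <- c(lines, sprintf("  \"%s\" [label=\"%s%s\"];",
                                ids[[key]], labs[[key]], role))
    }
    if (nrow(p$reactions)) {
      for (i in seq_len(nrow(p$reactions))) {
        rx <- p$reactions[i, ]
        lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                                  ids[[rx$substrate]], ids[[rx$product]], rx$enzyme))
      }
    }
    lines <- c(lines, "}")
    writeLines(lines, path)
  } else {
    g <- pathway_graph(p)
    igraph::V(g)$role <- unname(species_roles(p))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
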