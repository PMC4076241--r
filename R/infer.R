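# Single-step reaction inference: the three-step algorithm
#   1. verify the enzyme can act on the candidate substrate (global
#      blocking/requirement constraints + at least one site),
#   2. identify the residues that can be modified (find_sites),
#   3. create the product(s) by applying the resfuncgroup/linkFG rule.
# Reverse (substrate) inference proposes candidate precursors and keeps only
# those the forward step confirms, so it never proposes a substrate the
# enzyme could not actually convert.

new_rxn <- function(substrate, product, enzyme, direction) {
  structure(list(substrate = substrate, product = product,
                 enzyme = enzyme, direction = direction),
            class = "glyco_rxn")
}

#' @export
print.glyco_rxn <- function(x, ...) {
  cat("<reaction [", x$enzyme, "] ", write_linucs(x$substrate), " -> ",
      write_linucs(x$product), ">\n", sep = "")
  invisible(x)
}

# Global (site-independent) constraints of step 1.
global_constraints_ok <- function(e, g) {
  if (!is.null(e$substNAResidue) &&
      any(e$substNAResidue %in% residue_symbols(g))) {
    return(FALSE)
  }
  for (m in e$substNABranch) {
    if (length(match_motif(g, m))) return(FALSE)
  }
  if (!is.null(e$substMinStruct) && e$substMinStruct$anchor != "at_target_residue") {
    if (!length(match_motif(g, e$substMinStruct))) return(FALSE)
  }
  TRUE
}

#' Can an enzyme act on a glycan?
#'
#' Step 1 of the inference algorithm: true exactly when no blocking residue
#' (`substNAResidue`) occurs in the substrate, no blocking branch motif
#' (`substNABranch`) matches, the required minimal structure
#' (`substMinStruct`, when set) is present, and at least one modifiable site
#' exists.
#'
#' @param e a `glyco_enzyme`.
#' @param g a `glycan`.
#' @return logical.
#' @export
can_act <- function(e, g) {
  stopifnot(inherits(e, "glyco_enzyme"), inherits(g, "glycan"))
  global_constraints_ok(e, g) && length(find_sites(e, g)) > 0L
}

#' Find the residues an enzyme can modify
#'
#' Step 2 of the inference algorithm. For a glycosyltransferase: residues
#' equal to `resAtt2FG` whose own parent linkage matches `linkAtt2FG` (when
#' set), whose acceptor carbon (`linkFG`) is unoccupied, whose path to the
#' reducing end matches `targetBranch` (when set) and which carry the
#' site-anchored `substMinStruct` context (when its anchor is
#' `at_target_residue`). For a glycosidase: terminal residues equal to
#' `resfuncgroup` whose parent linkage lies in the `linkFG` set, with parent
#' context matching `resAtt2FG`/`linkAtt2FG` when set. Sites are ordered
#' deterministically by canonical path.
#'
#' @inheritParams can_act
#' @return list of integer node paths.
#' @export
find_sites <- function(e, g) {
  stopifnot(inherits(e, "glyco_enzyme"), inherits(g, "glycan"))
  tb_chain <- if (!is.null(e$targetBranch)) branch_chain(e$targetBranch) else NULL
  site_motif <- if (!is.null(e$substMinStruct) &&
                    e$substMinStruct$anchor == "at_target_residue") {
    e$substMinStruct
  } else NULL
  sites <- list()
  if (e$kind == "GT") {
    ap_new <- e$linkFG$acceptor_pos
    walk_nodes(g, function(node, path) {
      if (node$sym != e$resAtt2FG) return()
      if (!is.null(e$linkAtt2FG)) {
        if (is.null(node$link) || !link_matches(e$linkAtt2FG, node$link)) return()
      }
      if (!is.na(ap_new)) {
        occupied <- any(vapply(node$ch, function(ch) {
          !is.na(ch$link$acceptor_pos) && ch$link$acceptor_pos == ap_new
        }, TRUE))
        if (occupied) return()
      }
      if (!is.null(tb_chain) && !match_branch_to_root(g, path, tb_chain)) return()
      if (!is.null(site_motif) && !length(match_motif(g, site_motif, site = path))) return()
      sites[[length(sites) + 1L]] <<- path
    })
  } else {
    walk_nodes(g, function(node, path) {
      if (length(node$ch) || is.null(node$link)) return()
      if (node$sym != e$resfuncgroup) return()
      if (!any(vapply(e$linkFG, link_matches, TRUE, l = node$link))) return()
      parent_path <- path[-length(path)]
      parent <- get_node(g, parent_path)
      if (!is.null(e$resAtt2FG) && parent$sym != e$resAtt2FG) return()
      if (!is.null(e$linkAtt2FG)) {
        if (is.null(parent$link) || !link_matches(e$linkAtt2FG, parent$link)) return()
      }
      if (!is.null(tb_chain) && !match_branch_to_root(g, path, tb_chain)) return()
      if (!is.null(site_motif) && !length(match_motif(g, site_motif, site = path))) return()
      sites[[length(sites) + 1L]] <<- path
    })
  }
  sites
}

#' Infer the products of a single enzymatic step
#'
#' Step 3 of the inference algorithm: one reaction per modifiable site
#' (glycosyltransferases attach `resfuncgroup` via `linkFG`; glycosidases
#' remove the site residue), deduplicated by product canonical string and
#' ordered by it. Empty when [can_act()] is false.
#'
#' @inheritParams can_act
#' @return list of `glyco_rxn` objects.
#' @export
infer_products <- function(e, g) {
  stopifnot(inherits(e, "glyco_enzyme"), inherits(g, "glycan"))
  if (!global_constraints_ok(e, g)) return(list())
  sites <- find_sites(e, g)
  if (!length(sites)) return(list())
  prods <- list()
  for (s in sites) {
    p <- if (e$kind == "GT") {
      attach_residue(g, s, e$resfuncgroup, e$linkFG)
    } else {
      remove_residue(g, s)
    }
    prods[[canonical_string(p)]] <- p
  }
  prods <- prods[order(names(prods), method = "radix")]
  dir <- if (e$kind == "GT") "transfer" else "hydrolysis"
  lapply(prods, function(p) new_rxn(g, p, e$name, dir))
}

#' Infer the substrates that an enzyme converts into a given product
#'
#' Reverse inference: for a glycosyltransferase, every terminal residue of
#' the product equal to `resfuncgroup` attached via `linkFG` (with matching
#' `resAtt2FG`/`linkAtt2FG` context) is removed to form a candidate
#' substrate; for a glycosidase the cleaved residue is re-attached at every
#' open position. A candidate is kept only if the forward step applied to it
#' regenerates the product, so blocking constraints are honored exactly.
#'
#' @param e a `glyco_enzyme`.
#' @param p a `glycan` (the product).
#' @return list of `glyco_rxn` objects (substrate -> p), deduplicated by
#'   substrate canonical string and ordered by it.
#' @export
infer_substrates <- function(e, p) {
  stopifnot(inherits(e, "glyco_enzyme"), inherits(p, "glycan"))
  key_p <- canonical_string(p)
  cands <- list()
  if (e$kind == "GT") {
    walk_nodes(p, function(node, path) {
      if (length(node$ch) || is.null(node$link)) return()
      if (node$sym != e$resfuncgroup) return()
      if (!link_matches(e$linkFG, node$link)) return()
      parent <- get_node(p, path[-length(path)])
      if (parent$sym != e$resAtt2FG) return()
      if (!is.null(e$linkAtt2FG)) {
        if (is.null(parent$link) || !link_matches(e$linkAtt2FG, parent$link)) return()
      }
      s <- remove_residue(p, path)
      cands[[canonical_string(s)]] <<- s
    })
  } else {
    # re-attach the cleaved residue at every open, concretely-specified link
    concrete <- Filter(function(l) !is.na(l$acceptor_pos) && l$anomer != "?", e$linkFG)
    walk_nodes(p, function(node, path) {
      if (!is.null(e$resAtt2FG) && node$sym != e$resAtt2FG) return()
      for (l in concrete) {
        occupied <- any(vapply(node$ch, function(ch) {
          !is.na(ch$link$acceptor_pos) && ch$link$acceptor_pos == l$acceptor_pos
        }, TRUE))
        if (occupied) next
        s <- attach_residue(p, path, e$resfuncgroup, l)
        cands[[canonical_string(s)]] <<- s
      }
    })
  }
  keep <- Filter(function(s) {
    any(vapply(infer_products(e, s),
               function(r) canonical_string(r$product) == key_p, TRUE))
  }, cands)
  if (!length(keep)) return(list())
  keep <- keep[order(names(keep), method = "radix")]
  dir <- if (e$kind == "GT") "transfer" else "hydrolysis"
  lapply(keep, function(s) new_rxn(s, p, e$name, dir))
}
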