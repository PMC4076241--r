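# Motif matching over glycan trees. A motif is a glycan pattern plus an
# anchor mode:
#   at_reducing_end  - pattern root must align with the glycan root;
#   at_target_residue- pattern root aligns with a candidate node (used for
#                      site-level constraints during reaction inference);
#   floating         - pattern may align with any node.
# In every mode each pattern edge must map to an edge of the glycan with the
# same residue symbols; linkage fields that are undetermined on either side
# match any value. The glycan may always carry extra branches.

#' Construct a glycan motif
#'
#' @param pattern a `glycan` (or LINUCS string) used as an anchored subtree
#'   pattern.
#' @param anchor one of `"at_reducing_end"`, `"at_target_residue"`,
#'   `"floating"`.
#' @return an object of class `glycan_motif`.
#' @export
glycan_motif <- function(pattern,
                         anchor = c("at_reducing_end", "at_target_residue", "floating")) {
  anchor <- match.arg(anchor)
  if (is.character(pattern)) pattern <- parse_linucs(pattern)
  stopifnot(inherits(pattern, "glycan"))
  structure(list(pattern = pattern, anchor = anchor), class = "glycan_motif")
}

#' @export
print.glycan_motif <- function(x, ...) {
  cat("<motif [", x$anchor, "] ", write_linucs(x$pattern), ">\n", sep = "")
  invisible(x)
}

# Downward match of pattern node m at glycan node gn: injective assignment of
# m's children to gn's children with compatible linkages, recursively.
match_down <- function(m, gn) {
  if (m$sym != gn$sym) return(FALSE)
  nm <- length(m$ch)
  if (nm == 0L) return(TRUE)
  ng <- length(gn$ch)
  if (nm > ng) return(FALSE)
  used <- rep(FALSE, ng)
  assign_child <- function(i) {
    if (i > nm) return(TRUE)
    mc <- m$ch[[i]]
    for (j in seq_len(ng)) {
      if (used[j]) next
      gc <- gn$ch[[j]]
      if (link_matches(mc$link, gc$link) && match_down(mc, gc)) {
        used[j] <<- TRUE
        if (assign_child(i + 1L)) return(TRUE)
        used[j] <<- FALSE
      }
    }
    FALSE
  }
  assign_child(1L)
}

#' Match a motif against a glycan
#'
#' Returns every alignment site: for `at_reducing_end` the only candidate
#' site is the root; for `floating` (and `at_target_residue` when no `site`
#' is given) every node is a candidate. A site matches when the motif's
#' root aligns there and every motif edge maps onto an equal edge of the
#' glycan (the glycan may have extra branches). The empty list is a valid
#' result.
#'
#' @param g a `glycan`.
#' @param m a `glycan_motif` (or a `glycan`/LINUCS string, treated as a
#'   floating motif).
#' @param site optional integer node path restricting the candidate site
#'   (used with `at_target_residue` motifs).
#' @return list of integer node paths where the motif matches.
#' @export
match_motif <- function(g, m, site = NULL) {
  stopifnot(inherits(g, "glycan"))
  if (!inherits(m, "glycan_motif")) m <- glycan_motif(m, "floating")
  pat <- m$pattern$root
  if (!is.null(site)) {
    return(if (match_down(pat, get_node(g, site))) list(site) else list())
  }
  if (m$anchor == "at_reducing_end") {
    return(if (match_down(pat, g$root)) list(integer(0)) else list())
  }
  hits <- list()
  walk_nodes(g, function(node, path) {
    if (match_down(pat, node)) hits[[length(hits) + 1L]] <<- path
  })
  hits
}

# ---- path-to-root (branch context) matching --------------------------------
#
# targetBranch constraints describe the linear residue/linkage chain from the
# acted-upon residue toward the reducing end. The pattern is written as a
# linear glycan whose *leaf* corresponds to the target residue and whose root
# lies toward (possibly at) the reducing end; matching walks upward from the
# site and may stop before reaching the glycan root (prefix semantics), but a
# pattern whose root is reached while the glycan still has deeper ancestors
# only matches if the pattern ends exactly at a residue: i.e. the chain match
# consumes the whole pattern.

# Extract the linear chain (leaf -> root) from a linear pattern glycan.
chain_of <- function(pattern) {
  chain <- list()
  node <- pattern$root
  repeat {
    chain[[length(chain) + 1L]] <- list(sym = node$sym, link = node$link)
    if (!length(node$ch)) break
    if (length(node$ch) > 1L) {
      stop("targetBranch pattern must be a linear chain", call. = FALSE)
    }
    node <- node$ch[[1L]]
  }
  rev(chain) # leaf first
}

# Does the chain from `site` toward the root of g match the pattern chain?
# pattern_chain[[1]] is the target residue itself; pattern_chain[[k]]$link is
# the linkage of element k to element k+1 (its parent in the glycan).
match_branch_to_root <- function(g, site, pattern_chain) {
  path <- site
  node <- get_node(g, path)
  for (k in seq_along(pattern_chain)) {
    el <- pattern_chain[[k]]
    if (el$sym != node$sym) return(FALSE)
    if (k == length(pattern_chain)) return(TRUE)
    # need a parent whose linkage matches el$link
    if (length(path) == 0L) return(FALSE) # ran past the reducing end
    if (!link_matches(el$link_up, node$link)) return(FALSE)
    path <- path[-length(path)]
    node <- get_node(g, path)
  }
  TRUE
}

# Precompute chains with the upward linkage attached to the lower element:
# in the pattern glycan, the *child* carries the linkage to its parent, and
# the child is the element closer to the target. chain_of() returns leaf
# first with each element's own parent-linkage in $link; rename for clarity.
branch_chain <- function(pattern) {
  ch <- chain_of(pattern)
  lapply(ch, function(el) list(sym = el$sym, link_up = el$link))
}
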