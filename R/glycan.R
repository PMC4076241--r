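# Glycan trees: rooted ordered trees of monosaccharide residues. The root is
# the reducing-end residue; every other node carries the linkage to its
# parent. All exported constructors normalize sibling order canonically so
# that integer child-index paths are deterministic node references.

new_node <- function(symbol, link = NULL, children = list()) {
  check_residue(symbol)
  list(sym = symbol, link = link, ch = children)
}

#' Construct a glycan from a nested node description
#'
#' `glycan_node()` builds one residue node; nodes nest through `children`.
#' `glycan()` wraps a root node into a glycan object and canonicalizes
#' sibling order.
#'
#' @param symbol residue symbol (see [GLYCO_RESIDUES]).
#' @param link a `glyco_link` attaching this node to its parent (omit for the
#'   root), or a linkage string such as `"b1-4"`.
#' @param children list of child nodes built with `glycan_node()`.
#' @return `glycan_node()` an internal node list; `glycan()` a `glycan`.
#' @examples
#' core2 <- glycan(glycan_node("GalNAc", children = list(
#'   glycan_node("Gal", "b1-3"),
#'   glycan_node("GlcNAc", "b1-6")
#' )))
#' core2
#' @export
glycan_node <- function(symbol, link = NULL, children = list()) {
  if (is.character(link)) link <- parse_linkage(link)
  new_node(symbol, link, children)
}

#' @rdname glycan_node
#' @param root a node built with `glycan_node()` (without a `link`).
#' @param reducing_end `"free"` or `"attachment-point"`.
#' @export
glycan <- function(root, reducing_end = c("free", "attachment-point")) {
  reducing_end <- match.arg(reducing_end)
  if (!is.null(root$link)) stop("root node must not carry a parent linkage", call. = FALSE)
  g <- structure(list(root = canonical_order(root), reducing_end = reducing_end),
                 class = "glycan")
  g
}

# Recursively sort children into canonical order so index paths are stable.
canonical_order <- function(node) {
  if (length(node$ch)) {
    node$ch <- lapply(node$ch, canonical_order)
    keys <- vapply(node$ch, node_key, "")
    node$ch <- node$ch[order(keys, method = "radix")]
  }
  node
}

link_key <- function(l) {
  if (is.null(l)) return("")
  ap <- if (is.na(l$acceptor_pos)) "z" else sprintf("%02d", l$acceptor_pos)
  paste0(ap, l$anomer, l$donor_pos)
}

node_key <- function(node) {
  inner <- if (length(node$ch)) {
    keys <- sort(vapply(node$ch, node_key, ""), method = "radix")
    paste0("[", paste(keys, collapse = ","), "]")
  } else ""
  paste0(link_key(node$link), node$sym, inner)
}

#' Canonical string of a glycan
#'
#' A total order over sibling subtrees (acceptor position, then anomer, then
#' the recursive canonical string) yields one unique string per isomorphism
#' class of the rooted tree. Two glycans are the same species exactly when
#' their canonical strings are equal; all deduplication in pathway
#' construction goes through this key. Undetermined linkage fields sort last
#' and are equal only to each other.
#'
#' @param g a `glycan`.
#' @return a single string.
#' @examples
#' a <- glycan(glycan_node("GlcNAc", children = list(
#'   glycan_node("Gal", "b1-4"), glycan_node("Fuc", "a1-3"))))
#' b <- glycan(glycan_node("GlcNAc", children = list(
#'   glycan_node("Fuc", "a1-3"), glycan_node("Gal", "b1-4"))))
#' identical(canonical_string(a), canonical_string(b))
#' @export
canonical_string <- function(g) {
  stopifnot(inherits(g, "glycan"))
  node_key(g$root)
}

glycan_equal <- function(a, b) canonical_string(a) == canonical_string(b)

# ---- traversal --------------------------------------------------------------

# Apply f(node, path) over all nodes in preorder; path is an integer vector of
# child indices from the root (length 0 at the root).
walk_nodes <- function(g, f) {
  rec <- function(node, path) {
    f(node, path)
    if (length(node$ch)) {
      for (i in seq_along(node$ch)) rec(node$ch[[i]], c(path, i))
    }
  }
  rec(g$root, integer(0))
  invisible(NULL)
}

node_paths <- function(g) {
  out <- list()
  walk_nodes(g, function(node, path) out[[length(out) + 1L]] <<- path)
  out
}

get_node <- function(g, path) {
  node <- g$root
  for (i in path) {
    if (i > length(node$ch)) stop("invalid node path", call. = FALSE)
    node <- node$ch[[i]]
  }
  node
}

set_node <- function(g, path, node) {
  rec <- function(cur, depth) {
    if (depth > length(path)) return(node)
    i <- path[[depth]]
    cur$ch[[i]] <- rec(cur$ch[[i]], depth + 1L)
    cur
  }
  g$root <- rec(g$root, 1L)
  g
}

#' Number of residues in a glycan
#' @param g a `glycan`.
#' @return integer residue count.
#' @export
residue_count <- function(g) {
  n <- 0L
  walk_nodes(g, function(node, path) n <<- n + 1L)
  n
}

# All residue symbols present (with repeats), preorder.
residue_symbols <- function(g) {
  out <- character(0)
  walk_nodes(g, function(node, path) out[length(out) + 1L] <<- node$sym)
  out
}

#' Composition of a glycan
#'
#' Counts residues by generic class (Hex, HexNAc, dHex, NeuAc, Pen).
#'
#' @param g a `glycan`.
#' @return named integer vector of per-class counts (classes with zero count
#'   are dropped); of class `glycan_composition`.
#' @examples
#' slex <- parse_linucs("[][GlcNAc]{[(3+1)a-Fuc][(4+1)b-Gal]{[(3+2)a-Neu5Ac]}}")
#' composition(slex)
#' @export
composition <- function(g) {
  cls <- residue_class(residue_symbols(g))
  tab <- table(factor(cls, levels = c("Hex", "HexNAc", "dHex", "NeuAc", "Pen")))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out <- out[out > 0L]
  structure(out, class = "glycan_composition")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(paste0(names(x), unclass(x), collapse = " "), "\n")
  invisible(x)
}

# ---- structural edits (value semantics) -------------------------------------

#' Attach a residue to a glycan
#'
#' Returns a new glycan with one residue added at `site`; the input is never
#' modified. A site position (acceptor carbon) can carry at most one
#' substituent: attaching to an occupied carbon is an error.
#'
#' @param g a `glycan`.
#' @param site integer node path (as returned by [find_sites()] or
#'   [match_motif()]); `integer(0)` is the root.
#' @param res residue symbol to attach.
#' @param link a `glyco_link` (or string) for the new bond.
#' @return a new `glycan`.
#' @export
attach_residue <- function(g, site, res, link) {
  stopifnot(inherits(g, "glycan"))
  if (is.character(link)) link <- parse_linkage(link)
  node <- get_node(g, site)
  if (!is.na(link$acceptor_pos)) {
    occ <- vapply(node$ch, function(ch) {
      !is.na(ch$link$acceptor_pos) && ch$link$acceptor_pos == link$acceptor_pos
    }, TRUE)
    if (any(occ)) {
      stop("position ", link$acceptor_pos, " of ", node$sym,
           " is already occupied", call. = FALSE)
    }
  }
  node$ch[[length(node$ch) + 1L]] <- new_node(res, link)
  g <- set_node(g, site, node)
  g$root <- canonical_order(g$root)
  g
}

#' Remove a terminal residue from a glycan
#'
#' The site must be a non-reducing terminal residue (no children, not the
#' root). Returns a new glycan; the input is never modified.
#'
#' @inheritParams attach_residue
#' @return a new `glycan`.
#' @export
remove_residue <- function(g, site) {
  stopifnot(inherits(g, "glycan"))
  if (length(site) == 0L) stop("cannot remove the reducing-end residue", call. = FALSE)
  node <- get_node(g, site)
  if (length(node$ch)) {
    stop("cannot remove internal residue ", node$sym,
         ": it carries substituents", call. = FALSE)
  }
  parent_path <- site[-length(site)]
  parent <- get_node(g, parent_path)
  parent$ch[[site[[length(site)]]]] <- NULL
  g <- set_node(g, parent_path, parent)
  g$root <- canonical_order(g$root)
  g
}

# ---- display ----------------------------------------------------------------

#' @export
print.glycan <- function(x, ...) {
  cat("<glycan ", residue_count(x), " residues: ", write_linucs(x), ">\n", sep = "")
  invisible(x)
}

#' @export
format.glycan <- function(x, ...) write_linucs(x)

# ---- random generation ------------------------------------------------------

#' Generate a random glycan tree
#'
#' Draws a random rooted tree over the residue vocabulary: useful for
#' round-trip and canonicalization property testing. Uses the current RNG
#' stream; seed it with [set.seed()] for reproducibility.
#'
#' @param n_residues number of residues (>= 1).
#' @param max_children maximum substituents per residue.
#' @param p_undetermined probability that a linkage field is undetermined.
#' @return a `glycan`.
#' @export
random_glycan <- function(n_residues = 6L, max_children = 3L, p_undetermined = 0) {
  n_residues <- as.integer(n_residues)
  stopifnot(n_residues >= 1L)
  nodes <- vector("list", n_residues)
  parent <- integer(n_residues)
  kidpos <- vector("list", n_residues) # positions used per node
  nodes[[1L]] <- new_node(sample(GLYCO_RESIDUES, 1L))
  kidpos[[1L]] <- integer(0)
  if (n_residues > 1L) {
    for (i in 2:n_residues) {
      repeat {
        p <- sample.int(i - 1L, 1L)
        if (length(kidpos[[p]]) < max_children) break
      }
      avail <- setdiff(c(2L, 3L, 4L, 6L, 8L), kidpos[[p]])
      pos <- if (length(avail) == 1L) avail else sample(avail, 1L)
      und_ap <- stats::runif(1) < p_undetermined
      und_an <- stats::runif(1) < p_undetermined
      kidpos[[p]] <- c(kidpos[[p]], pos) # carbon reserved even if written as '?'
      sym <- sample(GLYCO_RESIDUES, 1L)
      lk <- linkage(if (und_an) "?" else sample(c("a", "b"), 1L),
                    if (sym == "Neu5Ac") 2L else 1L,
                    if (und_ap) NA_integer_ else pos)
      nodes[[i]] <- new_node(sym, lk)
      parent[[i]] <- p
    }
    # assemble bottom-up
    for (i in n_residues:2) {
      p <- parent[[i]]
      nodes[[p]]$ch[[length(nodes[[p]]$ch) + 1L]] <- nodes[[i]]
    }
  }
  glycan(nodes[[1L]])
}
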