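# Whole-network reconstruction.
#
# Forward inference: starting from each seed, single-step product inference
# is applied to every known species with every enzyme, repeated until no new
# product is formed; the per-seed pathways are merged and deduplicated.
#
# Reverse inference: the same fixed-point loop over substrate inference,
# followed by pruning to species that can reach at least one input product.
#
# Connection inference: for each of the m*(m-1)/2 unordered input pairs, one
# member is designated initial substrate and the other final product (with
# pure transferase pools this is the residue-count-smaller member; in
# general both orientations are attempted and the ones yielding chains are
# kept). Stepwise substrate inference from the product enumerates every
# reaction chain reaching the substrate, with intermediates bounded in size
# between the pair; all chains are consolidated into one deduplicated
# pathway.

as_enzyme_list <- function(enzymes) {
  if (inherits(enzymes, "enzyme_db")) return(enzymes$records)
  if (inherits(enzymes, "glyco_enzyme")) return(list(enzymes))
  if (is.character(enzymes)) return(db_get(builtin_database(), enzymes))
  stopifnot(is.list(enzymes))
  enzymes
}

as_glycan_list <- function(glycans) {
  if (inherits(glycans, "glycan")) glycans <- list(glycans)
  stopifnot(all(vapply(glycans, inherits, TRUE, "glycan")))
  glycans
}

#' Forward network inference
#'
#' Builds the reaction network reachable from a set of starting glycans:
#' repeated single-step product inference with every enzyme until no new
#' product is formed (or `max_iter` rounds per seed, in which case the
#' returned pathway carries a truncation warning flag, e.g. for open-ended
#' poly-LacNAc extension).
#'
#' @param seeds a `glycan` or list of glycans.
#' @param enzymes an `enzyme_db`, list of enzyme records, or character
#'   vector of built-in short names.
#' @param max_iter maximum inference rounds per seed.
#' @param labels optional display labels for the seeds.
#' @return a `glyco_pathway`.
#' @examples
#' m5gn <- case2_inputs()$glycans[[1]]
#' net <- forward_network(m5gn, c("GnTII", "GnTIII", "GnTIV", "GnTV", "ManII"))
#' net
#' @export
forward_network <- function(seeds, enzymes, max_iter = 50L, labels = NULL) {
  seeds <- as_glycan_list(seeds)
  enzymes <- as_enzyme_list(enzymes)
  out <- new_pathway()
  seed_keys <- vapply(seeds, canonical_string, "")
  for (i in seq_along(seeds)) {
    p <- new_pathway()
    p <- pw_add_species(p, seeds[[i]],
                        label = if (!is.null(labels)) labels[[i]] else NULL)
    frontier <- species_keys(p)
    iter <- 0L
    while (length(frontier)) {
      iter <- iter + 1L
      if (iter > max_iter) { p$truncated <- TRUE; break }
      new_keys <- character(0)
      for (key in frontier) {
        g <- p$species[[key]]
        for (e in enzymes) {
          for (r in infer_products(e, g)) {
            kp <- canonical_string(r$product)
            known <- !is.null(p$species[[kp]])
            p <- pw_add_rxn(p, r)
            if (!known) new_keys <- c(new_keys, kp)
          }
        }
      }
      frontier <- unique(new_keys)
    }
    out <- merge_pathways(out, p)
  }
  assign_roles(out, inputs = seed_keys)
}

#' Reverse network inference
#'
#' Infers starting materials and intermediate reactions given a set of
#' products: the fixed point of single-step substrate inference, pruned to
#' species that reach at least one of the input products.
#'
#' Substrate inference for a glycosidase proposes *larger* precursors, so a
#' reverse search containing hydrolases is open-ended upward; candidate
#' precursors are therefore capped at `max_size` residues (default: the
#' largest input product plus 4).
#'
#' @param products a `glycan` or list of glycans.
#' @inheritParams forward_network
#' @param max_size largest precursor (residue count) considered.
#' @return a `glyco_pathway`.
#' @export
reverse_network <- function(products, enzymes, max_iter = 50L, labels = NULL,
                            max_size = NULL) {
  products <- as_glycan_list(products)
  enzymes <- as_enzyme_list(enzymes)
  if (is.null(max_size)) max_size <- max(vapply(products, residue_count, 0L)) + 4L
  prod_keys <- vapply(products, canonical_string, "")
  p <- new_pathway()
  for (i in seq_along(products)) {
    p <- pw_add_species(p, products[[i]],
                        label = if (!is.null(labels)) labels[[i]] else NULL)
  }
  frontier <- species_keys(p)
  iter <- 0L
  while (length(frontier)) {
    iter <- iter + 1L
    if (iter > max_iter) { p$truncated <- TRUE; break }
    new_keys <- character(0)
    for (key in frontier) {
      g <- p$species[[key]]
      for (e in enzymes) {
        for (r in infer_substrates(e, g)) {
          if (residue_count(r$substrate) > max_size) next
          ks <- canonical_string(r$substrate)
          known <- !is.null(p$species[[ks]])
          p <- pw_add_rxn(p, r)
          if (!known) new_keys <- c(new_keys, ks)
        }
      }
    }
    frontier <- unique(new_keys)
  }
  # keep only species that reach >= 1 input product
  keep <- reachable_to(p, prod_keys)
  p <- restrict_pathway(p, keep)
  assign_roles(p, inputs = prod_keys)
}

# species keys from which any of `targets` is reachable (including targets)
reachable_to <- function(p, targets) {
  keys <- species_keys(p)
  keep <- stats::setNames(keys %in% targets, keys)
  repeat {
    add <- unique(p$reactions$substrate[p$reactions$product %in% names(keep)[keep]])
    add <- add[!keep[add]]
    if (!length(add)) break
    keep[add] <- TRUE
  }
  names(keep)[keep]
}

restrict_pathway <- function(p, keys) {
  p$species <- p$species[intersect(species_keys(p), keys)]
  rx <- p$reactions
  p$reactions <- rx[rx$substrate %in% keys & rx$product %in% keys, , drop = FALSE]
  rownames(p$reactions) <- NULL
  p$roles <- p$roles[intersect(names(p$roles), keys)]
  p$labels <- p$labels[intersect(names(p$labels), keys)]
  p
}

#' Connection network inference
#'
#' Joins two or more glycans through every enzyme-consistent reaction chain.
#' Each unordered pair is analyzed once (`m*(m-1)/2` pair analyses; the
#' count is recorded on the returned pathway); candidate intermediates are
#' bounded in residue count between the pair's substrate and product.
#'
#' @param glycans list of >= 2 glycans (or a `glycan` list with labels).
#' @inheritParams forward_network
#' @param verbose log per-pair progress.
#' @return a `glyco_pathway` with `pairs_analyzed` set.
#' @export
connection_network <- function(glycans, enzymes, max_iter = 50L,
                               labels = NULL, verbose = FALSE) {
  glycans <- as_glycan_list(glycans)
  if (length(glycans) < 2L) stop("connection inference needs >= 2 glycans", call. = FALSE)
  enzymes <- as_enzyme_list(enzymes)
  m <- length(glycans)
  keys <- vapply(glycans, canonical_string, "")
  sizes <- vapply(glycans, residue_count, 0L)
  kinds <- vapply(enzymes, `[[`, "", "kind")

  out <- new_pathway()
  for (i in seq_len(m)) {
    out <- pw_add_species(out, glycans[[i]],
                          label = if (!is.null(labels)) labels[[i]] else NULL)
  }

  # memoized substrate expansion shared across pairs
  cache <- new.env(parent = emptyenv())
  expand <- function(g) {
    key <- canonical_string(g)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- list()
    for (e in enzymes) res <- c(res, infer_substrates(e, g))
    cache[[key]] <- res
    res
  }

  pairs <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in seq((i + 1L), m)) {
      pairs <- pairs + 1L
      if (keys[i] == keys[j]) next
      orientations <- if (all(kinds == "GT")) {
        # pure transferase pool: the smaller glycan must be the substrate
        if (sizes[i] == sizes[j]) list() else
          if (sizes[i] < sizes[j]) list(c(i, j)) else list(c(j, i))
      } else if (all(kinds == "GH")) {
        if (sizes[i] == sizes[j]) list() else
          if (sizes[i] > sizes[j]) list(c(i, j)) else list(c(j, i))
      } else {
        list(c(i, j), c(j, i))
      }
      for (o in orientations) {
        sub <- glycans[[o[1]]]; prod <- glycans[[o[2]]]
        chain <- connect_pair(sub, prod, expand, max_iter = max_iter)
        if (!is.null(chain)) out <- merge_pathways(out, chain)
        if (verbose) {
          message(sprintf("pair %d/%d: %s -> %s: %s", pairs, m * (m - 1L) / 2L,
                          substr(keys[o[1]], 1, 24), substr(keys[o[2]], 1, 24),
                          if (is.null(chain)) "no chain" else
                            sprintf("%d species", n_species(chain))))
        }
      }
    }
  }
  out$pairs_analyzed <- m * (m - 1L) %/% 2L
  assign_roles(out, inputs = keys)
}

# All reaction chains sub -> ... -> prod; returns NULL when none exists.
connect_pair <- function(sub, prod, expand, max_iter = 50L) {
  key_sub <- canonical_string(sub)
  key_prod <- canonical_string(prod)
  lo <- min(residue_count(sub), residue_count(prod))
  hi <- max(residue_count(sub), residue_count(prod))
  # backward exploration from the product within the size bounds
  glycans <- list()
  glycans[[key_prod]] <- prod
  edges_sub <- character(0); edges_prod <- character(0)
  edges_enz <- character(0); edges_dir <- character(0)
  frontier <- key_prod
  depth <- 0L
  truncated <- FALSE
  while (length(frontier)) {
    depth <- depth + 1L
    if (depth > max_iter) { truncated <- TRUE; break }
    nxt <- character(0)
    for (key in frontier) {
      for (r in expand(glycans[[key]])) {
        n <- residue_count(r$substrate)
        if (n < lo || n > hi) next
        ks <- canonical_string(r$substrate)
        edges_sub <- c(edges_sub, ks)
        edges_prod <- c(edges_prod, key)
        edges_enz <- c(edges_enz, r$enzyme)
        edges_dir <- c(edges_dir, r$direction)
        if (is.null(glycans[[ks]])) {
          glycans[[ks]] <- r$substrate
          nxt <- c(nxt, ks)
        }
      }
    }
    frontier <- unique(nxt)
  }
  if (is.null(glycans[[key_sub]])) return(NULL)
  # prune to nodes forward-reachable from the substrate; every surviving
  # edge then lies on a sub -> prod chain
  keep <- stats::setNames(logical(length(glycans)), names(glycans))
  keep[key_sub] <- TRUE
  repeat {
    add <- unique(edges_prod[keep[edges_sub] & !keep[edges_prod]])
    if (!length(add)) break
    keep[add] <- TRUE
  }
  if (!keep[key_prod]) return(NULL)
  sel <- keep[edges_sub] & keep[edges_prod]
  p <- new_pathway()
  for (key in names(keep)[keep]) p <- pw_add_species(p, glycans[[key]])
  if (any(sel)) {
    rx <- data.frame(substrate = edges_sub[sel], product = edges_prod[sel],
                     enzyme = edges_enz[sel], direction = edges_dir[sel],
                     stringsAsFactors = FALSE)
    rx <- rx[!duplicated(rx[c("substrate", "product", "enzyme")]), , drop = FALSE]
    rownames(rx) <- NULL
    p$reactions <- rx
  }
  p$truncated <- truncated
  p
}
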