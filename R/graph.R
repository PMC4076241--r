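# Graph view of a pathway and graph-theoretic analyses: exhaustive simple-
# path finding, subset-network generation by counted or named deletion, and
# isolated-species handling. Species are nodes; reactions are directed,
# enzyme-labeled edges (parallel edges allowed).

#' Graph view of a pathway
#'
#' @param p a `glyco_pathway`.
#' @return an `igraph` directed (multi)graph; vertex attribute `label`
#'   carries display labels, edge attribute `enzyme` the catalyst.
#' @export
pathway_graph <- function(p) {
  stopifnot(inherits(p, "glyco_pathway"))
  keys <- species_keys(p)
  g <- igraph::make_empty_graph(n = length(keys), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = keys)
  g <- igraph::set_vertex_attr(g, "label", value = unname(species_labels(p)))
  if (nrow(p$reactions)) {
    idx <- rbind(match(p$reactions$substrate, keys),
                 match(p$reactions$product, keys))
    g <- igraph::add_edges(g, as.vector(idx), enzyme = p$reactions$enzyme)
  }
  g
}

resolve_key <- function(p, key) {
  if (key %in% species_keys(p)) return(key)
  labs <- species_labels(p)
  hit <- names(labs)[!is.na(labs) & labs == key]
  if (length(hit) == 1L) return(hit)
  stop("species not found in pathway: ", key, call. = FALSE)
}

#' Find all simple reaction paths between two species
#'
#' Depth-first enumeration of every simple directed path from `source` to
#' `target`. Each path is returned as the alternating species/reaction
#' sequence; parallel enzyme-labeled edges between the same species pair are
#' expanded into distinct paths.
#'
#' @param p a `glyco_pathway`.
#' @param source,target species canonical keys or display labels.
#' @return list of paths; each path is a list with `species` (character
#'   vector of keys) and `enzymes` (character vector, one per step).
#'   `source == target` yields one zero-length path.
#' @export
path_finding <- function(p, source, target) {
  stopifnot(inherits(p, "glyco_pathway"))
  source <- resolve_key(p, source)
  target <- resolve_key(p, target)
  if (source == target) {
    return(list(list(species = source, enzymes = character(0))))
  }
  g <- pathway_graph(p)
  vp <- igraph::all_simple_paths(g, from = source, to = target, mode = "out")
  rx <- p$reactions
  out <- list()
  for (path in vp) {
    keys <- igraph::V(g)$name[as.integer(path)]
    # enzyme alternatives per step -> cartesian expansion
    alts <- vector("list", length(keys) - 1L)
    for (s in seq_len(length(keys) - 1L)) {
      alts[[s]] <- rx$enzyme[rx$substrate == keys[s] & rx$product == keys[s + 1L]]
    }
    combos <- expand.grid(alts, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos))) {
      out[[length(out) + 1L]] <- list(species = keys,
                                      enzymes = unlist(combos[r, ], use.names = FALSE))
    }
  }
  out
}

#' Union of all paths between two species, as a pathway
#'
#' Convenience wrapper: the sub-network formed by every species and reaction
#' lying on some simple path from `source` to `target`.
#'
#' @inheritParams path_finding
#' @return a `glyco_pathway` (empty species set if no path exists).
#' @export
path_subnetwork <- function(p, source, target) {
  paths <- path_finding(p, source, target)
  keys <- unique(unlist(lapply(paths, `[[`, "species")))
  q <- restrict_pathway(p, keys)
  if (length(paths)) {
    # keep only reactions used by some path
    used <- unique(do.call(rbind, lapply(paths, function(pt) {
      k <- pt$species
      if (length(k) < 2L) return(NULL)
      data.frame(substrate = k[-length(k)], product = k[-1L],
                 enzyme = pt$enzymes, stringsAsFactors = FALSE)
    })))
    q$reactions <- merge(q$reactions, used,
                         by = c("substrate", "product", "enzyme"))[,
                         c("substrate", "product", "enzyme", "direction")]
  }
  q
}

#' Isolated species
#'
#' A species is isolated when it participates in no reaction (only defined
#' when the pathway has at least one reaction). `remove_isolated_species()`
#' is idempotent.
#'
#' @param p a `glyco_pathway`.
#' @return `detect_isolated_species()`: character vector of species keys;
#'   `remove_isolated_species()`: a `glyco_pathway`.
#' @export
detect_isolated_species <- function(p) {
  stopifnot(inherits(p, "glyco_pathway"))
  if (!nrow(p$reactions)) return(character(0))
  keys <- species_keys(p)
  keys[!(keys %in% p$reactions$substrate | keys %in% p$reactions$product)]
}

#' @rdname detect_isolated_species
#' @export
remove_isolated_species <- function(p) {
  iso <- detect_isolated_species(p)
  if (!length(iso)) return(p)
  restrict_pathway(p, setdiff(species_keys(p), iso))
}

#' Subset networks by deleting named species
#'
#' `subnet_by_spec_del()` removes the named species plus incident reactions,
#' then removes species left isolated. `subnet_by_spec_keep()` retains
#' exactly the named species and the reactions among them.
#'
#' @param p a `glyco_pathway`.
#' @param species character vector of canonical keys or display labels.
#' @return a `glyco_pathway`.
#' @export
subnet_by_spec_del <- function(p, species) {
  species <- vapply(species, resolve_key, "", p = p)
  remove_isolated_species(restrict_pathway(p, setdiff(species_keys(p), species)))
}

#' @rdname subnet_by_spec_del
#' @export
subnet_by_spec_keep <- function(p, species) {
  species <- vapply(species, resolve_key, "", p = p)
  restrict_pathway(p, species)
}

# ---- subset generation by counted deletion ---------------------------------

# Integer scaffold shared by subnet_by_num_del() and subset_sweep().
subset_scaffold <- function(p, protected, require_any) {
  keys <- species_keys(p)
  n <- length(keys)
  protected <- vapply(protected, resolve_key, "", p = p)
  require_any <- vapply(require_any, resolve_key, "", p = p)
  roles <- species_roles(p)
  list(
    keys = keys, n = n,
    sub = match(p$reactions$substrate, keys),
    prod = match(p$reactions$product, keys),
    protected_idx = match(protected, keys),
    require_idx = match(require_any, keys),
    intermediate = !is.na(roles) & roles == "inferred_intermediate",
    deletable = setdiff(seq_len(n), match(protected, keys))
  )
}

# Evaluate one deletion set: cascade cleanup, then validity flags.
# Cleanup removes, until stable, (i) species incident to no surviving
# reaction (isolated) and (ii) inferred intermediates that are no longer
# both the substrate and the product of a surviving reaction - in-silico
# structures have no experimental support, so a subset model may not leave
# them dangling. The generated subset pathway therefore always has flowing
# intermediates; validity only checks that the protected start species and
# at least one required end product survive the cascade.
eval_deletion <- function(sc, del_idx) {
  alive <- rep(TRUE, sc$n)
  alive[del_idx] <- FALSE
  repeat {
    e_alive <- alive[sc$sub] & alive[sc$prod]
    indeg <- tabulate(sc$prod[e_alive], sc$n)
    outdeg <- tabulate(sc$sub[e_alive], sc$n)
    drop <- alive & sc$intermediate & (indeg == 0L | outdeg == 0L)
    if (any(e_alive)) drop <- drop | (alive & (indeg + outdeg == 0L))
    if (!any(drop)) break
    alive <- alive & !drop
  }
  reason <- character(0)
  if (length(sc$protected_idx) && !all(alive[sc$protected_idx])) {
    reason <- c(reason, "missing_start")
  }
  if (length(sc$require_idx) && !any(alive[sc$require_idx])) {
    reason <- c(reason, "missing_required_end")
  }
  list(alive = alive, valid = !length(reason), reason = reason)
}

#' Subset networks by deleting a fixed number of species
#'
#' Enumerates deletions of `k` non-protected species from the master
#' pathway (exhaustively by default, or as a seeded random sample). For
#' each deletion, incident reactions are dropped and the pathway is cleaned
#' up until stable: species incident to no reaction are removed (isolated),
#' as are inferred intermediates no longer both consumed and produced -
#' in-silico structures may not dangle in a subset model. A generated
#' subset pathway is valid when the protected (start) species and at least
#' one of `require_any` survive the cleanup.
#'
#' @param p the master `glyco_pathway`.
#' @param k number of species to delete.
#' @param protected species keys/labels that are never deleted (and must
#'   survive isolation removal).
#' @param require_any keys/labels of which at least one must survive.
#' @param include_invalid return failing subsets too (with reason codes).
#' @param sample_n if non-NULL, examine a random sample of this many
#'   deletion sets instead of all `choose(n_deletable, k)`.
#' @param keep_pathways materialize the surviving sub-pathway for each
#'   returned result (disable when only counting).
#' @return list of results: each has `deleted` (keys), `valid`, `reason`,
#'   and (when requested) `pathway`.
#' @export
subnet_by_num_del <- function(p, k, protected = character(0),
                              require_any = character(0),
                              include_invalid = FALSE,
                              sample_n = NULL, keep_pathways = TRUE) {
  stopifnot(inherits(p, "glyco_pathway"))
  sc <- subset_scaffold(p, protected, require_any)
  k <- as.integer(k)
  if (k < 1L || k > length(sc$deletable)) {
    stop("k must lie between 1 and the number of deletable species (",
         length(sc$deletable), ")", call. = FALSE)
  }
  combos <- if (is.null(sample_n)) {
    utils::combn(sc$deletable, k)
  } else {
    replicate(sample_n, sort(sample(sc$deletable, k)))
  }
  if (is.null(dim(combos))) combos <- matrix(combos, nrow = k)
  out <- list()
  for (ci in seq_len(ncol(combos))) {
    del <- combos[, ci]
    ev <- eval_deletion(sc, del)
    if (!ev$valid && !include_invalid) next
    res <- list(deleted = sc$keys[del], valid = ev$valid, reason = ev$reason)
    if (keep_pathways) {
      res$pathway <- restrict_pathway(p, sc$keys[ev$alive])
    }
    out[[length(out) + 1L]] <- res
  }
  out
}

#' Count distinct valid subset pathways over a range of deletion sizes
#'
#' Exhaustive sweep of [subnet_by_num_del()] for `k = ks` without
#' materializing pathway objects, counting the *distinct* valid subset
#' pathways generated at each deletion depth (different deletion sets often
#' collapse, after cleanup, to the same surviving pathway; the profile of
#' generated subset models counts each surviving pathway once per `k`).
#' Used to locate the knockout depth that maximizes subset-model diversity.
#'
#' @inheritParams subnet_by_num_del
#' @param ks integer vector of deletion counts.
#' @param distinct count distinct surviving pathways (default); set to
#'   `FALSE` to count valid deletion sets instead.
#' @return named integer vector of counts, one per `k`.
#' @export
subset_sweep <- function(p, ks, protected = character(0),
                         require_any = character(0), distinct = TRUE) {
  sc <- subset_scaffold(p, protected, require_any)
  n <- sc$n
  nsub <- sc$sub; nprod <- sc$prod
  intermediate <- sc$intermediate
  prot <- sc$protected_idx; req <- sc$require_idx
  counts <- stats::setNames(integer(length(ks)), as.character(ks))
  pow2 <- 2^(seq_len(n) - 1L) # n <= ~50 species: exact in doubles
  for (t in seq_along(ks)) {
    k <- ks[[t]]
    if (k > length(sc$deletable)) next
    combos <- utils::combn(sc$deletable, k)
    cnt <- 0L
    seen <- numeric(0)
    for (ci in seq_len(ncol(combos))) {
      alive <- rep(TRUE, n)
      alive[combos[, ci]] <- FALSE
      repeat {
        e_alive <- alive[nsub] & alive[nprod]
        indeg <- tabulate(nprod[e_alive], n)
        outdeg <- tabulate(nsub[e_alive], n)
        drop <- alive & intermediate & (indeg == 0L | outdeg == 0L)
        if (any(e_alive)) drop <- drop | (alive & (indeg + outdeg == 0L))
        if (!any(drop)) break
        alive <- alive & !drop
      }
      if (length(prot) && !all(alive[prot])) next
      if (length(req) && !any(alive[req])) next
      if (distinct) seen[length(seen) + 1L] <- sum(pow2[alive]) else cnt <- cnt + 1L
    }
    counts[[t]] <- if (distinct) length(unique(seen)) else cnt
  }
  counts
}
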