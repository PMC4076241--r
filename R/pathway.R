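# Pathway: deduplicated species set (keyed by canonical string) plus a
# directed reaction set. Duplicate reaction identity is the triple
# (substrate key, product key, enzyme name): two enzymes catalyzing the same
# conversion are two distinct reactions.

empty_reactions <- function() {
  data.frame(substrate = character(0), product = character(0),
             enzyme = character(0), direction = character(0),
             stringsAsFactors = FALSE)
}

new_pathway <- function(species = list(), reactions = empty_reactions(),
                        roles = list(), labels = character(0)) {
  structure(list(species = species, reactions = reactions,
                 roles = roles, labels = labels,
                 truncated = FALSE, pairs_analyzed = NA_integer_),
            class = "glyco_pathway")
}

#' Build a pathway from species and reactions
#'
#' Normally produced by [forward_network()], [reverse_network()] or
#' [connection_network()]; exposed for tests and for assembling pathways by
#' hand.
#'
#' @param glycans list of `glycan` objects (duplicates collapse).
#' @param reactions optional list of `glyco_rxn` objects.
#' @param labels optional character vector of display labels, parallel to
#'   `glycans`.
#' @return a `glyco_pathway`.
#' @export
pathway <- function(glycans = list(), reactions = list(), labels = NULL) {
  p <- new_pathway()
  for (i in seq_along(glycans)) {
    p <- pw_add_species(p, glycans[[i]],
                        label = if (!is.null(labels)) labels[[i]] else NULL)
  }
  for (r in reactions) p <- pw_add_rxn(p, r)
  p
}

pw_add_species <- function(p, g, role = NA_character_, label = NULL) {
  key <- canonical_string(g)
  if (is.null(p$species[[key]])) {
    p$species[[key]] <- g
    if (!is.na(role)) p$roles[[key]] <- role
  } else if (!is.na(role) && is.null(p$roles[[key]])) {
    p$roles[[key]] <- role
  }
  if (!is.null(label) && is.na(p$labels[key])) p$labels[[key]] <- label
  p
}

pw_add_rxn <- function(p, r) {
  ks <- canonical_string(r$substrate)
  kp <- canonical_string(r$product)
  p <- pw_add_species(p, r$substrate)
  p <- pw_add_species(p, r$product)
  dup <- p$reactions$substrate == ks & p$reactions$product == kp &
    p$reactions$enzyme == r$enzyme
  if (!any(dup)) {
    p$reactions <- rbind(p$reactions, data.frame(
      substrate = ks, product = kp, enzyme = r$enzyme,
      direction = r$direction, stringsAsFactors = FALSE))
  }
  p
}

#' @export
print.glyco_pathway <- function(x, ...) {
  cat("<pathway: ", length(x$species), " species, ", nrow(x$reactions),
      " reactions>\n", sep = "")
  if (!is.na(x$pairs_analyzed)) {
    cat("  connection inference over ", x$pairs_analyzed, " glycan pairs\n", sep = "")
  }
  if (isTRUE(x$truncated)) {
    cat("  WARNING: iteration cap reached before a fixed point;",
        "the network may be open-ended\n")
  }
  rl <- species_roles(x)
  if (length(rl)) {
    tb <- table(rl)
    cat("  roles: ", paste(names(tb), as.integer(tb), sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Species keys, roles and labels of a pathway
#'
#' `species_keys()` returns the canonical-string keys; `species_roles()` a
#' named character vector (seed, end_product or inferred_intermediate);
#' `species_labels()` display labels (auto-generated for unlabeled species).
#'
#' @param p a `glyco_pathway`.
#' @return see above.
#' @export
species_keys <- function(p) names(p$species)

#' @rdname species_keys
#' @export
species_roles <- function(p) {
  keys <- species_keys(p)
  out <- stats::setNames(rep(NA_character_, length(keys)), keys)
  common <- intersect(names(p$roles), keys)
  out[common] <- unlist(p$roles[common])
  out
}

#' @rdname species_keys
#' @export
species_labels <- function(p) {
  keys <- species_keys(p)
  out <- stats::setNames(rep(NA_character_, length(keys)), keys)
  common <- intersect(names(p$labels), keys)
  if (length(common)) out[common] <- unlist(p$labels[common])
  auto <- which(is.na(out))
  if (length(auto)) out[auto] <- sprintf("G%02d", auto)
  out
}

#' Number of species / reactions in a pathway
#' @param p a `glyco_pathway`.
#' @return integer.
#' @export
n_species <- function(p) length(p$species)

#' @rdname n_species
#' @export
n_reactions <- function(p) nrow(p$reactions)

# recompute end_product / intermediate roles from connectivity; keeps any
# existing "seed"/"input" assignment.
assign_roles <- function(p, inputs = character(0)) {
  keys <- species_keys(p)
  outdeg <- table(factor(p$reactions$substrate, levels = keys))
  roles <- character(length(keys))
  names(roles) <- keys
  for (k in keys) {
    roles[[k]] <- if (k %in% inputs) {
      if (outdeg[[k]] == 0L) "end_product" else "seed"
    } else if (outdeg[[k]] == 0L) "end_product" else "inferred_intermediate"
  }
  p$roles <- as.list(roles)
  p
}

#' Merge two pathways
#'
#' Union of species and reactions, deduplicated by canonical keys.
#'
#' @param a,b `glyco_pathway` objects.
#' @return a `glyco_pathway`.
#' @export
merge_pathways <- function(a, b) {
  for (key in names(b$species)) {
    a <- pw_add_species(a, b$species[[key]],
                        role = if (!is.null(b$roles[[key]])) b$roles[[key]] else NA_character_,
                        label = if (!is.na(b$labels[key])) b$labels[[key]] else NULL)
  }
  if (nrow(b$reactions)) {
    comb <- rbind(a$reactions, b$reactions)
    a$reactions <- comb[!duplicated(comb[c("substrate", "product", "enzyme")]), ,
                        drop = FALSE]
    rownames(a$reactions) <- NULL
  }
  a$truncated <- isTRUE(a$truncated) || isTRUE(b$truncated)
  a
}
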