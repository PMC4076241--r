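# GlycoCT condensed-style encoding, RES/LIN sections only (no REP/ALT).
# One RES entry per residue:
#   <index>b:<anomer>-<code>         e.g.  2b:b-dgal
# where the anomer prefix is the residue's own anomeric configuration in its
# linkage to the parent ('x' for the reducing-end root), and <code> names the
# monosaccharide (dglc, dgal, dman, dglcnac, dgalnac, lfuc, dneu5ac, dxyl).
# LIN entries follow the condensed form
#   <index>:<parent>o(<acceptor>+<donor>)<child>d
# with -1 for an undetermined acceptor position. Lines beginning with '#' are
# comments (used by fixture files for provenance notes).

#' Write a glycan in GlycoCT condensed form
#'
#' Emits a RES section (one entry per residue, preorder over the canonical
#' tree) followed by a LIN section (one entry per parent-child bond;
#' always residues - 1 entries).
#'
#' @param g a `glycan`.
#' @return a single string (embedded newlines).
#' @seealso [parse_glycoct()], [read_glycoct()]
#' @export
write_glycoct <- function(g) {
  stopifnot(inherits(g, "glycan"))
  res <- character(0)
  lin <- character(0)
  idx <- 0L
  rec <- function(node, parent_idx) {
    idx <<- idx + 1L
    my <- idx
    an <- if (is.null(node$link)) "x" else sub("\\?", "x", node$link$anomer)
    res[my] <<- paste0(my, "b:", an, "-", .RESIDUE_CODE[[node$sym]])
    if (!is.null(node$link)) {
      ap <- if (is.na(node$link$acceptor_pos)) -1L else node$link$acceptor_pos
      lin[length(lin) + 1L] <<- paste0(length(lin) + 1L, ":", parent_idx,
                                       "o(", ap, "+", node$link$donor_pos, ")", my, "d")
    }
    for (ch in node$ch) rec(ch, my)
  }
  rec(g$root, 0L)
  paste(c("RES", res, "LIN", lin), collapse = "\n")
}

#' Parse GlycoCT condensed text into a glycan
#'
#' Inverse of [write_glycoct()]. A LIN entry referencing an undeclared
#' residue index is an error.
#'
#' @param text GlycoCT condensed text (single string or character vector of
#'   lines).
#' @return a `glycan`.
#' @export
parse_glycoct <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines) || lines[[1L]] != "RES") {
    stop("GlycoCT parse error: text must begin with a RES section", call. = FALSE)
  }
  lin_at <- match("LIN", lines)
  res_lines <- lines[seq(2L, if (is.na(lin_at)) length(lines) else lin_at - 1L)]
  lin_lines <- if (is.na(lin_at) || lin_at == length(lines)) character(0) else
    lines[seq(lin_at + 1L, length(lines))]

  n <- length(res_lines)
  syms <- character(n)
  anomers <- character(n)
  for (ln in res_lines) {
    m <- regmatches(ln, regexec("^([0-9]+)b:([abx])-([a-z0-9]+)$", ln))[[1]]
    if (length(m) != 4L) stop("GlycoCT parse error: bad RES entry '", ln, "'", call. = FALSE)
    i <- as.integer(m[2])
    if (i < 1L || i > n) stop("GlycoCT parse error: RES index ", i, " out of range", call. = FALSE)
    code <- m[4]
    if (!code %in% names(.CODE_RESIDUE)) {
      stop("GlycoCT parse error: unknown residue code '", code, "'", call. = FALSE)
    }
    syms[i] <- .CODE_RESIDUE[[code]]
    anomers[i] <- m[3]
  }
  if (any(!nzchar(syms))) stop("GlycoCT parse error: missing RES indices", call. = FALSE)

  parent <- rep(NA_integer_, n)
  links <- vector("list", n)
  for (ln in lin_lines) {
    m <- regmatches(ln, regexec("^([0-9]+):([0-9]+)o\\((-?[0-9]+)\\+([0-9]+)\\)([0-9]+)d$", ln))[[1]]
    if (length(m) != 6L) stop("GlycoCT parse error: bad LIN entry '", ln, "'", call. = FALSE)
    p <- as.integer(m[3]); ap <- as.integer(m[4]); dp <- as.integer(m[5])
    child <- as.integer(m[6])
    if (p < 1L || p > n || child < 1L || child > n) {
      stop("GlycoCT parse error: LIN entry '", ln, "' references undeclared residue",
           call. = FALSE)
    }
    if (!is.na(parent[child])) {
      stop("GlycoCT parse error: residue ", child, " has two parents", call. = FALSE)
    }
    parent[child] <- p
    an <- if (anomers[child] == "x") "?" else anomers[child]
    links[[child]] <- linkage(an, dp, if (ap < 0L) NA_integer_ else ap)
  }
  roots <- which(is.na(parent))
  if (length(roots) != 1L) {
    stop("GlycoCT parse error: expected exactly one root residue, found ",
         length(roots), call. = FALSE)
  }
  nodes <- lapply(seq_len(n), function(i) new_node(syms[i], links[[i]]))
  # attach children to parents, deepest-first (children indices may be in any order)
  order_depth <- integer(n)
  depth_of <- function(i) {
    d <- 0L
    while (!is.na(parent[i])) { i <- parent[i]; d <- d + 1L }
    d
  }
  for (i in seq_len(n)) order_depth[i] <- depth_of(i)
  for (i in order(order_depth, decreasing = TRUE)) {
    p <- parent[i]
    if (!is.na(p)) nodes[[p]]$ch[[length(nodes[[p]]$ch) + 1L]] <- nodes[[i]]
  }
  glycan(nodes[[roots]])
}

#' Read or write a glycan file in GlycoCT condensed form
#'
#' @param path file path.
#' @return `read_glycoct()` a `glycan`; `write_glycoct_file()` the path,
#'   invisibly.
#' @export
read_glycoct <- function(path) {
  parse_glycoct(readLines(path, warn = FALSE))
}

#' @rdname read_glycoct
#' @param g a `glycan`.
#' @param header optional comment lines (without `#`) written at the top.
#' @export
write_glycoct_file <- function(g, path, header = NULL) {
  txt <- write_glycoct(g)
  if (!is.null(header)) txt <- paste(c(paste0("# ", header), txt), collapse = "\n")
  writeLines(txt, path)
  invisible(path)
}
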