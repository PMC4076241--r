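# LINUCS-style linear notation. The dialect follows the LINUCS layout
# (reducing end first, children depth-first in braces, linkage codes as
# "(acceptor+donor)" pairs) restricted to the package's residue vocabulary:
#
#   [][GalNAc]{[(3+1)b-Gal][(6+1)b-GlcNAc]}
#
# Root residue carries no linkage; each child element is
# [(<acceptor>+<donor>)<anomer>-<Symbol>] optionally followed by {children}.
# "?" encodes an undetermined acceptor position or anomer. The writer emits
# children in canonical order and omits empty braces, so output is a stable
# golden form.

#' Write a glycan in LINUCS notation
#'
#' @param g a `glycan`.
#' @return a single LINUCS string.
#' @seealso [parse_linucs()]
#' @export
write_linucs <- function(g) {
  stopifnot(inherits(g, "glycan"))
  fmt_children <- function(node) {
    if (!length(node$ch)) return("")
    parts <- vapply(node$ch, function(ch) {
      ap <- if (is.na(ch$link$acceptor_pos)) "?" else as.character(ch$link$acceptor_pos)
      paste0("[(", ap, "+", ch$link$donor_pos, ")", ch$link$anomer, "-", ch$sym, "]",
             fmt_children(ch))
    }, "")
    paste0("{", paste(parts, collapse = ""), "}")
  }
  paste0("[][", g$root$sym, "]", fmt_children(g$root))
}

#' Parse a LINUCS string into a glycan
#'
#' Inverse of [write_linucs()]. Malformed bracket nesting or an unknown
#' residue name raises an error naming the offending token and its character
#' position.
#'
#' @param text a single LINUCS string.
#' @return a `glycan`.
#' @examples
#' g <- parse_linucs("[][GalNAc]{[(3+1)b-Gal][(6+1)b-GlcNAc]}")
#' residue_count(g)
#' @export
parse_linucs <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  pos <- 1L
  n <- nchar(s)
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  fail <- function(msg) {
    stop("LINUCS parse error at position ", pos, ": ", msg, call. = FALSE)
  }
  expect <- function(tok) {
    take <- substr(s, pos, pos + nchar(tok) - 1L)
    if (take != tok) fail(paste0("expected '", tok, "', found '", take, "'"))
    pos <<- pos + nchar(tok)
  }
  read_until <- function(stop_chars) {
    start <- pos
    while (pos <= n && !(substr(s, pos, pos) %in% stop_chars)) pos <<- pos + 1L
    substr(s, start, pos - 1L)
  }
  read_name <- function() {
    nm <- read_until(c("]"))
    if (!nm %in% GLYCO_RESIDUES) {
      pos <<- pos - nchar(nm)
      fail(paste0("unknown residue name '", nm, "'"))
    }
    nm
  }
  parse_children <- function() {
    kids <- list()
    expect("{")
    while (peek() == "[") {
      expect("[")
      expect("(")
      ap_tok <- read_until(c("+"))
      ap <- if (ap_tok == "?") NA_integer_ else suppressWarnings(as.integer(ap_tok))
      if (ap_tok != "?" && is.na(ap)) fail(paste0("bad acceptor position '", ap_tok, "'"))
      expect("+")
      dp_tok <- read_until(c(")"))
      dp <- suppressWarnings(as.integer(dp_tok))
      if (is.na(dp)) fail(paste0("bad donor position '", dp_tok, "'"))
      expect(")")
      an <- peek()
      if (!an %in% c("a", "b", "?")) fail(paste0("bad anomer '", an, "'"))
      pos <<- pos + 1L
      expect("-")
      nm <- read_name()
      expect("]")
      node <- new_node(nm, linkage(an, dp, ap))
      if (peek() == "{") node$ch <- parse_children()
      kids[[length(kids) + 1L]] <- node
    }
    expect("}")
    kids
  }
  expect("[]")
  expect("[")
  root_name <- read_name()
  expect("]")
  root <- new_node(root_name)
  if (peek() == "{") root$ch <- parse_children()
  if (pos <= n) fail("trailing characters after glycan")
  glycan(root)
}
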