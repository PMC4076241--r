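#' Monosaccharide vocabulary
#'
#' The toolbox models glycans over eight common monosaccharides. Each symbol
#' maps to exactly one generic composition class: Hex (Glc, Gal, Man),
#' HexNAc (GlcNAc, GalNAc), dHex (Fuc), NeuAc (Neu5Ac) and Pen (Xyl).
#'
#' @format A character vector of valid residue symbols.
#' @export
GLYCO_RESIDUES <- c("Glc", "Gal", "Man", "GlcNAc", "GalNAc", "Fuc", "Neu5Ac", "Xyl")

.RESIDUE_CLASS <- c(
  Glc = "Hex", Gal = "Hex", Man = "Hex",
  GlcNAc = "HexNAc", GalNAc = "HexNAc",
  Fuc = "dHex", Neu5Ac = "NeuAc", Xyl = "Pen"
)

# GlycoCT-style residue codes used by the RES section of the condensed writer
.RESIDUE_CODE <- c(
  Glc = "dglc", Gal = "dgal", Man = "dman",
  GlcNAc = "dglcnac", GalNAc = "dgalnac",
  Fuc = "lfuc", Neu5Ac = "dneu5ac", Xyl = "dxyl"
)
.CODE_RESIDUE <- stats::setNames(names(.RESIDUE_CODE), unname(.RESIDUE_CODE))

#' Generic composition class of a residue symbol
#'
#' @param symbol character vector of residue symbols (e.g. `"GlcNAc"`).
#' @return character vector of classes among Hex, HexNAc, dHex, NeuAc, Pen.
#' @examples
#' residue_class(c("Gal", "Fuc"))
#' @export
residue_class <- function(symbol) {
  check_residue(symbol)
  unname(.RESIDUE_CLASS[symbol])
}

check_residue <- function(symbol) {
  bad <- setdiff(symbol, GLYCO_RESIDUES)
  if (length(bad)) {
    stop("unknown residue symbol(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(GLYCO_RESIDUES, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(symbol)
}

# ---- linkages ---------------------------------------------------------------

#' Construct a glycosidic linkage
#'
#' A linkage joins a child (donor) residue to its parent (acceptor) residue.
#' `anomer` is `"a"`, `"b"` or `"?"` (undetermined); `donor_pos` is the
#' anomeric carbon of the child (1, or 2 for sialic acids); `acceptor_pos` is
#' the carbon of the parent that is substituted, or `NA` when undetermined.
#'
#' @param anomer one of `"a"`, `"b"`, `"?"` (Greek alpha/beta also accepted).
#' @param donor_pos integer, 1 or 2.
#' @param acceptor_pos integer carbon position on the parent, or `NA`.
#' @return an object of class `glyco_link`.
#' @examples
#' linkage("b", 1, 4)
#' parse_linkage("β1,4")
#' @export
linkage <- function(anomer, donor_pos = 1L, acceptor_pos = NA_integer_) {
  anomer <- switch(as.character(anomer),
    "a" = "a", "b" = "b", "?" = "?", "x" = "?",
    "α" = "a", "β" = "b",
    stop("invalid anomer: ", anomer, call. = FALSE)
  )
  donor_pos <- as.integer(donor_pos)
  if (!donor_pos %in% c(1L, 2L)) {
    stop("donor_pos must be 1 or 2, got ", donor_pos, call. = FALSE)
  }
  acceptor_pos <- suppressWarnings(as.integer(acceptor_pos))
  structure(list(anomer = anomer, donor_pos = donor_pos,
                 acceptor_pos = acceptor_pos),
            class = "glyco_link")
}

#' Parse a linkage from text
#'
#' Accepts the compact form `"b1-4"`, the literature form `"β1,4"` and
#' `"?"` placeholders (`"?1-?"`).
#'
#' @param text a single linkage string.
#' @return a `glyco_link`.
#' @export
parse_linkage <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- gsub("α", "a", gsub("β", "b", trimws(text)))
  m <- regmatches(txt, regexec("^([ab?])([12])[,-](\\?|[0-9])$", txt))[[1]]
  if (length(m) != 4L) {
    stop("cannot parse linkage: '", text, "'", call. = FALSE)
  }
  ap <- if (m[4] == "?") NA_integer_ else as.integer(m[4])
  linkage(m[2], as.integer(m[3]), ap)
}

#' Format a linkage as text
#'
#' @param l a `glyco_link`.
#' @param style `"compact"` for `"b1-4"`, `"greek"` for `"β1,4"`.
#' @return a single string.
#' @export
format_linkage <- function(l, style = c("compact", "greek")) {
  style <- match.arg(style)
  ap <- if (is.na(l$acceptor_pos)) "?" else as.character(l$acceptor_pos)
  if (style == "compact") {
    paste0(l$anomer, l$donor_pos, "-", ap)
  } else {
    an <- c(a = "α", b = "β", "?" = "?")[[l$anomer]]
    paste0(an, l$donor_pos, ",", ap)
  }
}

#' @export
print.glyco_link <- function(x, ...) {
  cat("<linkage ", format_linkage(x), ">\n", sep = "")
  invisible(x)
}

# Does a concrete linkage satisfy a (possibly wildcarded) pattern linkage?
# Undetermined fields on either side match anything.
link_matches <- function(pattern, l) {
  if (is.null(pattern)) return(TRUE)
  ok_an <- pattern$anomer == "?" || l$anomer == "?" || pattern$anomer == l$anomer
  ok_dp <- pattern$donor_pos == l$donor_pos
  ok_ap <- is.na(pattern$acceptor_pos) || is.na(l$acceptor_pos) ||
    pattern$acceptor_pos == l$acceptor_pos
  ok_an && ok_dp && ok_ap
}

link_equal <- function(a, b) {
  identical(a$anomer, b$anomer) &&
    identical(a$donor_pos, b$donor_pos) &&
    identical(a$acceptor_pos, b$acceptor_pos)
}
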