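# Enzyme class hierarchy. The generic enzyme record (Enz) carries EC number,
# names and a reaction description. Transferases add donor/acceptor fields;
# hydrolases the two product fields. The glycosyltransferase (GTEnz) and
# glycosidase (GHEnz) subclasses add the machine-readable specificity fields
# that drive reaction inference:
#
#   resfuncgroup  residue transferred (GT) or cleaved (GH)        [required]
#   linkFG        linkage formed (GT) / broken (GH; may be a set) [required]
#   resAtt2FG     residue to which the bond attaches              [GT required]
#   linkAtt2FG    linkage of that attachment residue to its own parent
#   targetBranch  linear chain from the acted-upon residue toward the
#                 reducing end that the substrate must present
#   substNAResidue residues whose presence anywhere blocks the enzyme
#   substNABranch  reducing-end-anchored motifs whose match blocks action
#   substMinStruct motif the substrate must contain (anchor respected;
#                  at_target_residue anchors the motif at the reaction site)

gt_classes <- c("gt_enzyme", "tf_enzyme", "glyco_enzyme")
gh_classes <- c("gh_enzyme", "hl_enzyme", "glyco_enzyme")

as_motif_list <- function(x, anchor) {
  if (is.null(x)) return(list())
  if (inherits(x, "glycan_motif") || inherits(x, "glycan") || is.character(x)) x <- list(x)
  lapply(x, function(m) if (inherits(m, "glycan_motif")) m else glycan_motif(m, anchor))
}

as_link_list <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "glyco_link")) x <- list(x)
  if (is.character(x)) x <- as.list(x)
  lapply(x, function(l) if (is.character(l)) parse_linkage(l) else l)
}

validate_ecno <- function(ecno, kind) {
  ecno <- as.integer(ecno)
  if (length(ecno) != 4L || anyNA(ecno)) {
    stop("ecno must have exactly 4 integer fields", call. = FALSE)
  }
  want <- if (kind == "GT") 2L else 3L
  if (ecno[1L] != want) {
    stop("EC class ", ecno[1L], " inconsistent with a ",
         if (kind == "GT") "transferase (EC 2.-)" else "hydrolase (EC 3.-)",
         call. = FALSE)
  }
  ecno
}

#' Define a glycosyltransferase (GTEnz)
#'
#' @param name short name used as the database key (e.g. `"GnTII"`).
#' @param ecno EC number as a 4-integer vector or `"2.4.1.143"` string.
#' @param resfuncgroup residue symbol transferred.
#' @param linkFG linkage formed, as `glyco_link` or string (`"b1-2"`).
#' @param resAtt2FG residue symbol the new bond attaches to.
#' @param linkAtt2FG optional linkage of the attachment residue to its own
#'   parent.
#' @param targetBranch optional linear glycan/LINUCS chain (acted-upon
#'   residue written as the deepest element) the site's path to the reducing
#'   end must match.
#' @param substNAResidue optional character vector of residues whose
#'   presence anywhere in the substrate blocks the enzyme.
#' @param substNABranch optional motif(s), anchored at the reducing end,
#'   whose match blocks the enzyme.
#' @param substMinStruct optional motif the substrate must contain.
#' @param donor sugar-nucleotide donor identifier (e.g. `"UDP-GlcNAc"`).
#' @param acceptor,donorprod,acceptorprod descriptive reaction fields.
#' @param name_systematic,name_recommended,names_alternative,reaction_description
#'   descriptive metadata fields.
#' @return an object of classes `gt_enzyme`, `tf_enzyme`, `glyco_enzyme`.
#' @export
gt_enzyme <- function(name, ecno, resfuncgroup, linkFG, resAtt2FG,
                      linkAtt2FG = NULL, targetBranch = NULL,
                      substNAResidue = NULL, substNABranch = NULL,
                      substMinStruct = NULL,
                      donor = "unspecified", acceptor = "", donorprod = "",
                      acceptorprod = "",
                      name_systematic = "", name_recommended = "",
                      names_alternative = character(0),
                      reaction_description = "") {
  if (is.character(ecno) && length(ecno) == 1L) {
    ecno <- strsplit(ecno, ".", fixed = TRUE)[[1L]]
  }
  ecno <- validate_ecno(ecno, "GT")
  check_residue(resfuncgroup)
  check_residue(resAtt2FG)
  if (is.character(linkFG)) linkFG <- parse_linkage(linkFG)
  if (is.character(linkAtt2FG)) linkAtt2FG <- parse_linkage(linkAtt2FG)
  if (!is.null(targetBranch) && !inherits(targetBranch, "glycan")) {
    targetBranch <- parse_linucs(targetBranch)
  }
  if (!is.null(donor) && !nzchar(donor)) {
    stop("donor must be non-empty for a glycosyltransferase", call. = FALSE)
  }
  if (!is.null(substNAResidue)) check_residue(substNAResidue)
  e <- list(
    kind = "GT", name = name, ecno = ecno,
    name_systematic = name_systematic, name_recommended = name_recommended,
    names_alternative = names_alternative,
    reaction_description = reaction_description,
    donor = donor, acceptor = acceptor, donorprod = donorprod,
    acceptorprod = acceptorprod,
    resfuncgroup = resfuncgroup, linkFG = linkFG,
    resAtt2FG = resAtt2FG, linkAtt2FG = linkAtt2FG,
    targetBranch = targetBranch,
    substNAResidue = substNAResidue,
    substNABranch = as_motif_list(substNABranch, "at_reducing_end"),
    substMinStruct = if (is.null(substMinStruct)) NULL else
      as_motif_list(substMinStruct, "at_reducing_end")[[1L]]
  )
  structure(e, class = gt_classes)
}

#' Define a glycosidase (GHEnz)
#'
#' @inheritParams gt_enzyme
#' @param resfuncgroup residue symbol cleaved.
#' @param linkFG linkage(s) broken; a list/vector encodes disjunctive
#'   specificity (e.g. `c("a1-3", "a1-6")` for Golgi alpha-mannosidase II).
#' @param resAtt2FG,linkAtt2FG optional attachment context (both optional
#'   for a glycosidase).
#' @param prod_h,prod_oh descriptive hydrolysis product fields.
#' @return an object of classes `gh_enzyme`, `hl_enzyme`, `glyco_enzyme`.
#' @export
gh_enzyme <- function(name, ecno, resfuncgroup, linkFG,
                      resAtt2FG = NULL, linkAtt2FG = NULL,
                      targetBranch = NULL, substNAResidue = NULL,
                      substNABranch = NULL, substMinStruct = NULL,
                      prod_h = "", prod_oh = "",
                      name_systematic = "", name_recommended = "",
                      names_alternative = character(0),
                      reaction_description = "") {
  if (is.character(ecno) && length(ecno) == 1L) {
    ecno <- strsplit(ecno, ".", fixed = TRUE)[[1L]]
  }
  ecno <- validate_ecno(ecno, "GH")
  check_residue(resfuncgroup)
  if (!is.null(resAtt2FG)) check_residue(resAtt2FG)
  linkFG <- as_link_list(linkFG)
  if (!length(linkFG)) stop("linkFG is required", call. = FALSE)
  if (is.character(linkAtt2FG)) linkAtt2FG <- parse_linkage(linkAtt2FG)
  if (!is.null(targetBranch) && !inherits(targetBranch, "glycan")) {
    targetBranch <- parse_linucs(targetBranch)
  }
  if (!is.null(substNAResidue)) check_residue(substNAResidue)
  e <- list(
    kind = "GH", name = name, ecno = ecno,
    name_systematic = name_systematic, name_recommended = name_recommended,
    names_alternative = names_alternative,
    reaction_description = reaction_description,
    prod_h = prod_h, prod_oh = prod_oh,
    resfuncgroup = resfuncgroup, linkFG = linkFG,
    resAtt2FG = resAtt2FG, linkAtt2FG = linkAtt2FG,
    targetBranch = targetBranch,
    substNAResidue = substNAResidue,
    substNABranch = as_motif_list(substNABranch, "at_reducing_end"),
    substMinStruct = if (is.null(substMinStruct)) NULL else
      as_motif_list(substMinStruct, "at_reducing_end")[[1L]]
  )
  structure(e, class = gh_classes)
}

#' @export
print.glyco_enzyme <- function(x, ...) {
  cat("<", if (x$kind == "GT") "glycosyltransferase" else "glycosidase",
      " ", x$name, "  EC ", paste(x$ecno, collapse = "."), ">\n", sep = "")
  lfg <- if (x$kind == "GH") {
    paste(vapply(x$linkFG, format_linkage, ""), collapse = " | ")
  } else format_linkage(x$linkFG)
  cat("  ", if (x$kind == "GT") "adds " else "removes ", x$resfuncgroup,
      " (", lfg, ")", sep = "")
  if (!is.null(x$resAtt2FG)) {
    cat(" at ", x$resAtt2FG, sep = "")
    if (!is.null(x$linkAtt2FG)) cat(" (", format_linkage(x$linkAtt2FG), ")", sep = "")
  }
  cat("\n")
  if (!is.null(x$targetBranch)) {
    cat("  targetBranch:   ", write_linucs(x$targetBranch), "\n", sep = "")
  }
  if (!is.null(x$substNAResidue)) {
    cat("  substNAResidue: ", paste(x$substNAResidue, collapse = ", "), "\n", sep = "")
  }
  for (m in x$substNABranch) {
    cat("  substNABranch:  ", write_linucs(m$pattern), "\n", sep = "")
  }
  if (!is.null(x$substMinStruct)) {
    cat("  substMinStruct: ", write_linucs(x$substMinStruct$pattern),
        " [", x$substMinStruct$anchor, "]\n", sep = "")
  }
  invisible(x)
}

#' Enzyme database
#'
#' A named collection of enzyme records keyed by short name.
#'
#' @param records named list of `glyco_enzyme` objects (names default to the
#'   records' own short names).
#' @return an `enzyme_db`.
#' @seealso [builtin_database()], [load_db()], [save_db()]
#' @export
enzyme_db <- function(records = list()) {
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    names(records) <- vapply(records, `[[`, "", "name")
  }
  if (anyDuplicated(names(records))) {
    stop("duplicate enzyme short names in database", call. = FALSE)
  }
  structure(list(records = records), class = "enzyme_db")
}

#' @export
print.enzyme_db <- function(x, ...) {
  kinds <- vapply(x$records, `[[`, "", "kind")
  cat("<enzyme_db: ", length(x$records), " records (",
      sum(kinds == "GT"), " GT, ", sum(kinds == "GH"), " GH)>\n", sep = "")
  cat(" ", paste(names(x$records), collapse = ", "), "\n")
  invisible(x)
}

#' Look up enzymes by short name
#'
#' @param db an `enzyme_db`.
#' @param names character vector of short names.
#' @return a list of enzyme records.
#' @export
db_get <- function(db, names) {
  stopifnot(inherits(db, "enzyme_db"))
  miss <- setdiff(names, names(db$records))
  if (length(miss)) {
    stop("enzyme(s) not in database: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  db$records[names]
}
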