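# Structured-text persistence for enzyme databases: one stanza per enzyme,
# `[ShortName]` header then `field: value` lines. Glycan-valued fields
# (targetBranch, substNABranch, substMinStruct) are LINUCS strings;
# list-valued fields separate entries with " | ". Lines starting with '#'
# are comments.
#
#   [GnTII]
#   kind: GT
#   ec: 2.4.1.143
#   donor: UDP-GlcNAc
#   resfuncgroup: GlcNAc
#   linkFG: b1-2
#   resAtt2FG: Man
#   linkAtt2FG: a1-6
#   targetBranch: [][GlcNAc]{[(4+1)b-GlcNAc]{[(4+1)b-Man]{[(6+1)a-Man]}}}
#   substNAResidue: Gal

#' Save an enzyme database as structured text
#'
#' @param db an `enzyme_db`.
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [load_db()]
#' @export
save_db <- function(db, path) {
  stopifnot(inherits(db, "enzyme_db"))
  lines <- character(0)
  put <- function(field, value) {
    if (is.null(value) || !length(value) || identical(value, "")) return()
    lines <<- c(lines, paste0(field, ": ", paste(value, collapse = " | ")))
  }
  for (e in db$records) {
    lines <- c(lines, paste0("[", e$name, "]"))
    put("kind", e$kind)
    put("ec", paste(e$ecno, collapse = "."))
    put("name_systematic", e$name_systematic)
    put("name_recommended", e$name_recommended)
    put("names_alternative", e$names_alternative)
    put("reaction", e$reaction_description)
    if (e$kind == "GT") {
      put("donor", e$donor); put("acceptor", e$acceptor)
      put("donorprod", e$donorprod); put("acceptorprod", e$acceptorprod)
    } else {
      put("prod_h", e$prod_h); put("prod_oh", e$prod_oh)
    }
    put("resfuncgroup", e$resfuncgroup)
    lf <- if (e$kind == "GH") vapply(e$linkFG, format_linkage, "") else format_linkage(e$linkFG)
    put("linkFG", lf)
    put("resAtt2FG", e$resAtt2FG)
    if (!is.null(e$linkAtt2FG)) put("linkAtt2FG", format_linkage(e$linkAtt2FG))
    if (!is.null(e$targetBranch)) put("targetBranch", write_linucs(e$targetBranch))
    put("substNAResidue", e$substNAResidue)
    if (length(e$substNABranch)) {
      put("substNABranch", vapply(e$substNABranch, function(m) write_linucs(m$pattern), ""))
    }
    if (!is.null(e$substMinStruct)) {
      put("substMinStruct", write_linucs(e$substMinStruct$pattern))
      put("substMinStructAnchor", e$substMinStruct$anchor)
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load an enzyme database from structured text
#'
#' Inverse of [save_db()]. A stanza missing an obligatory field
#' (`resfuncgroup`, `linkFG`, or `resAtt2FG` for a glycosyltransferase) is
#' a schema error naming the field; a malformed glycan-valued field is a
#' parse error naming the enzyme.
#'
#' @param path input file.
#' @return an `enzyme_db`.
#' @export
load_db <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  heads <- grep("^\\[.+\\]\\s*$", lines)
  if (!length(heads)) stop("enzyme DB schema error: no [Name] stanza found", call. = FALSE)
  recs <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (h in seq_along(heads)) {
    name <- sub("^\\[(.+)\\]\\s*$", "\\1", lines[heads[h]])
    body <- lines[seq(heads[h] + 1L, bounds[h + 1L] - 1L)]
    body <- body[grepl(":", body, fixed = TRUE)]
    fields <- list()
    for (ln in body) {
      key <- trimws(sub(":.*$", "", ln))
      val <- trimws(sub("^[^:]*:", "", ln))
      fields[[key]] <- trimws(strsplit(val, " | ", fixed = TRUE)[[1]])
    }
    need <- function(field) {
      if (is.null(fields[[field]])) {
        stop("enzyme DB schema error in [", name, "]: missing obligatory field '",
             field, "'", call. = FALSE)
      }
      fields[[field]]
    }
    opt1 <- function(field) if (is.null(fields[[field]])) NULL else fields[[field]][1]
    kind <- toupper(need("kind")[1])
    parse_motifs <- function(field) {
      if (is.null(fields[[field]])) return(NULL)
      tryCatch(lapply(fields[[field]], parse_linucs),
               error = function(err) {
                 stop("enzyme DB parse error in [", name, "] field '", field,
                      "': ", conditionMessage(err), call. = FALSE)
               })
    }
    common <- list(
      name = name, ecno = need("ec")[1],
      resfuncgroup = need("resfuncgroup")[1],
      linkAtt2FG = opt1("linkAtt2FG"),
      targetBranch = if (is.null(fields$targetBranch)) NULL else parse_motifs("targetBranch")[[1]],
      substNAResidue = fields$substNAResidue,
      substNABranch = parse_motifs("substNABranch"),
      name_systematic = if (is.null(opt1("name_systematic"))) "" else opt1("name_systematic"),
      name_recommended = if (is.null(opt1("name_recommended"))) "" else opt1("name_recommended"),
      names_alternative = if (is.null(fields$names_alternative)) character(0) else fields$names_alternative,
      reaction_description = if (is.null(opt1("reaction"))) "" else opt1("reaction"))
    mstruct <- if (is.null(fields$substMinStruct)) NULL else {
      glycan_motif(parse_motifs("substMinStruct")[[1]],
                   if (is.null(opt1("substMinStructAnchor"))) "at_reducing_end"
                   else opt1("substMinStructAnchor"))
    }
    recs[[name]] <- if (kind == "GT") {
      do.call(gt_enzyme, c(common, list(
        linkFG = need("linkFG")[1], resAtt2FG = need("resAtt2FG")[1],
        substMinStruct = mstruct,
        donor = if (is.null(opt1("donor"))) "unspecified" else opt1("donor"),
        acceptor = if (is.null(opt1("acceptor"))) "" else opt1("acceptor"),
        donorprod = if (is.null(opt1("donorprod"))) "" else opt1("donorprod"),
        acceptorprod = if (is.null(opt1("acceptorprod"))) "" else opt1("acceptorprod"))))
    } else {
      do.call(gh_enzyme, c(common, list(
        linkFG = need("linkFG"), resAtt2FG = opt1("resAtt2FG"),
        substMinStruct = mstruct,
        prod_h = if (is.null(opt1("prod_h"))) "" else opt1("prod_h"),
        prod_oh = if (is.null(opt1("prod_oh"))) "" else opt1("prod_oh"))))
    }
  }
  enzyme_db(recs)
}
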