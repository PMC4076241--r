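# Shipped case-study fixtures. Each case directory under extdata holds one
# GlycoCT file per input glycan plus a YAML manifest naming the glycans (in
# figure order), the enzyme activities, and the expected network metrics.
# Case-1/2 metrics are binding (asserted exactly by the tests); Case-3 is a
# synthetic stand-in for an MS-annotated structure roster and its metrics
# are smoke-level only.

fixture_dir <- function(case) {
  d <- system.file("extdata", case, package = "glyconet")
  if (!nzchar(d)) stop("fixture directory not found: ", case, call. = FALSE)
  d
}

load_case <- function(case) {
  d <- fixture_dir(case)
  man <- yaml::read_yaml(file.path(d, "manifest.yaml"))
  glycans <- lapply(man$glycans, function(entry) read_glycoct(file.path(d, entry$file)))
  labels <- vapply(man$glycans, `[[`, "", "id")
  structure(list(
    name = man$name,
    description = man$description,
    glycans = glycans,
    labels = labels,
    enzymes = man$enzymes,
    enzyme_sets = man$enzyme_sets,
    expected = man$expected,
    binding = isTRUE(man$binding)
  ), class = "glyco_case")
}

#' @export
print.glyco_case <- function(x, ...) {
  cat("<case study: ", x$name, ">\n  ", length(x$glycans), " glycans; enzymes: ",
      paste(unlist(x$enzymes), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Case-study input fixtures
#'
#' `case1_inputs()`: the O-linked selectin-ligand study - the core-2
#' trisaccharide starting glycan plus 12 observed PSGL-1 O-glycans and five
#' enzyme activities (GalT-IV, b3GnT, ST3Gal-I/II, ST3Gal-IV, FT-VII);
#' expected connection-network metrics: 20 species, 28 reactions, 7
#' inferred intermediates, with sialyl-Lewis-X products `glycan05` and
#' `glycan09`.
#'
#' `case2_inputs()`: N-linked forward inference from GlcNAcMan5GlcNAc2 with
#' the five-enzyme set (GnT II-V + ManII; expected 14 species/14 reactions)
#' and the six-enzyme set adding GalT (expected 28/28).
#'
#' `case3_inputs()`: a synthetic stand-in for an MS-derived structure
#' roster (12 N-glycan structures, 9 enzymes); metrics non-binding.
#'
#' @return a `glyco_case` with elements `glycans`, `labels`, `enzymes` (or
#'   `enzyme_sets`), and `expected`.
#' @export
case1_inputs <- function() load_case("case1")

#' @rdname case1_inputs
#' @export
case2_inputs <- function() load_case("case2")

#' @rdname case1_inputs
#' @export
case3_inputs <- function() load_case("case3")
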