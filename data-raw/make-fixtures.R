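# Regenerates the GlycoCT fixture files and YAML manifests under inst/extdata.
# Run from the repo root: Rscript data-raw/make-fixtures.R
suppressMessages(library(glyconet))

hdr_case1 <- c(
  "Synthetic reconstruction of a PSGL-1 O-glycan (core-2 scaffold).",
  "Reconstruction on the core-2 scaffold; structural ambiguities",
  "resolved toward reproducing the reference 20-species / 28-reaction",
  "connection network (see fixture manifest).")

# ---- case 1: core-2 O-glycans ----------------------------------------------
# Arm A (beta1,3 on GalNAc): Gal, optionally alpha2,3-sialylated.
# Arm B (beta1,6 on GalNAc): GlcNAc extended by LacNAc repeats, optionally
# alpha2,3-sialylated on the distal Gal, optionally alpha1,3-fucosylated on
# the distal (sialylated-LacNAc) GlcNAc.
armA <- function(sia) {
  kids <- list()
  if (sia) kids <- list(glycan_node("Neu5Ac", "a2-3"))
  glycan_node("Gal", "b1-3", kids)
}
# B-arm chain states b0..b9 (see manifest notes)
armB <- function(state) {
  gn <- function(link, kids = list()) glycan_node("GlcNAc", link, kids)
  gal <- function(kids = list()) glycan_node("Gal", "b1-4", kids)
  sia <- glycan_node("Neu5Ac", "a2-3")
  fuc <- glycan_node("Fuc", "a1-3")
  switch(state,
    b0 = gn("b1-6"),
    b1 = gn("b1-6", list(gal())),
    b2 = gn("b1-6", list(gal(list(sia)))),
    b3 = gn("b1-6", list(fuc, gal(list(sia)))),
    b4 = gn("b1-6", list(gal(list(gn("b1-3"))))),
    b5 = gn("b1-6", list(gal(list(gn("b1-3", list(gal())))))),
    b6 = gn("b1-6", list(gal(list(gn("b1-3", list(gal(list(sia)))))))),
    b7 = gn("b1-6", list(gal(list(gn("b1-3", list(fuc, gal(list(sia)))))))),
    b8 = gn("b1-6", list(gal(list(gn("b1-3", list(gal(list(gn("b1-3"))))))))),
    b9 = gn("b1-6", list(gal(list(gn("b1-3", list(gal(list(gn("b1-3", list(gal())))))))))),
    stop("bad state ", state))
}
o_glycan <- function(a_sia, b_state) {
  glycan(glycan_node("GalNAc", children = list(armA(a_sia), armB(b_state))))
}

case1 <- list(
  glycan00 = o_glycan(FALSE, "b0"),  # core-2 trisaccharide (starting glycan)
  glycan01 = o_glycan(TRUE,  "b0"),
  glycan02 = o_glycan(FALSE, "b1"),
  glycan03 = o_glycan(TRUE,  "b1"),
  glycan04 = o_glycan(TRUE,  "b2"),
  glycan05 = o_glycan(TRUE,  "b3"),  # sLeX
  glycan06 = o_glycan(FALSE, "b2"),
  glycan07 = o_glycan(FALSE, "b3"),  # sLeX arm, asialo core-1
  glycan08 = o_glycan(FALSE, "b5"),
  glycan09 = o_glycan(TRUE,  "b7"),  # distal sLeX on 2 LacNAc
  glycan10 = o_glycan(TRUE,  "b5"),
  glycan11 = o_glycan(FALSE, "b6"),
  glycan12 = o_glycan(TRUE,  "b9")   # 3 LacNAc poly-N-acetyllactosamine
)

dir.create("inst/extdata/case1", recursive = TRUE, showWarnings = FALSE)
for (id in names(case1)) {
  write_glycoct_file(case1[[id]], file.path("inst/extdata/case1", paste0(id, ".glycoct")),
                     header = hdr_case1)
}
writeLines(write_yaml_manifest <- yaml::as.yaml(list(
  name = "case1-O-linked-PSGL1",
  description = paste(
    "Core-2 trisaccharide starting glycan plus 12 observed PSGL-1 O-glycans",
    "(synthetic reconstruction on the core-2 scaffold: LacNAc extension,",
    "poly-LacNAc to 3 repeats, core-1 and LacNAc alpha2,3-sialylation,",
    "distal alpha1,3-fucosylation). glycan05/glycan09 carry sialyl-Lewis-X."),
  binding = TRUE,
  glycans = lapply(names(case1), function(id) list(id = id, file = paste0(id, ".glycoct"))),
  enzymes = list("GalT-IV", "b3GnT", "ST3Gal-I/II", "ST3Gal-IV", "FT-VII"),
  expected = list(species = 20L, reactions = 28L, intermediates = 7L,
                  start = "glycan00", slex_products = list("glycan05", "glycan09"),
                  subset_sweep_argmax = 6L)
)), "inst/extdata/case1/manifest.yaml")

# ---- case 2: N-linked forward inference ------------------------------------
a3_arm <- glycan_node("Man", "a1-3", list(glycan_node("GlcNAc", "b1-2")))
a6_arm <- glycan_node("Man", "a1-6", list(glycan_node("Man", "a1-3"),
                                          glycan_node("Man", "a1-6")))
core_man <- glycan_node("Man", "b1-4", list(a3_arm, a6_arm))
m5gn <- glycan(glycan_node("GlcNAc", children = list(
  glycan_node("GlcNAc", "b1-4", list(core_man)))))
dir.create("inst/extdata/case2", recursive = TRUE, showWarnings = FALSE)
write_glycoct_file(m5gn, "inst/extdata/case2/m5gn.glycoct",
                   header = "GlcNAcMan5GlcNAc2 (M5Gn): hybrid N-glycan, GnT I product of Man5GlcNAc2.")
writeLines(yaml::as.yaml(list(
  name = "case2-N-linked-forward",
  description = "Forward network inference from GlcNAcMan5GlcNAc2 (M5Gn).",
  binding = TRUE,
  glycans = list(list(id = "m5gn", file = "m5gn.glycoct")),
  enzyme_sets = list(
    five = list("GnTII", "GnTIII", "GnTIV", "GnTV", "ManII"),
    six  = list("GnTII", "GnTIII", "GnTIV", "GnTV", "ManII", "GalT")),
  expected = list(five = list(species = 14L, reactions = 14L),
                  six  = list(species = 28L, reactions = 28L))
)), "inst/extdata/case2/manifest.yaml")

# ---- case 3: synthetic MS-annotated roster ---------------------------------
ncore <- function(a3_kids = list(), a6_kids = list(), bisect = FALSE, fuc = FALSE,
                  root_extra = list()) {
  core_man_kids <- list(
    glycan_node("Man", "a1-3", a3_kids),
    glycan_node("Man", "a1-6", a6_kids))
  if (bisect) core_man_kids <- c(core_man_kids, list(glycan_node("GlcNAc", "b1-4")))
  root_kids <- list(glycan_node("GlcNAc", "b1-4", list(
    glycan_node("Man", "b1-4", core_man_kids))))
  if (fuc) root_kids <- c(root_kids, list(glycan_node("Fuc", "a1-6")))
  glycan(glycan_node("GlcNAc", children = c(root_kids, root_extra)))
}
gn2 <- function(kids = list()) glycan_node("GlcNAc", "b1-2", kids)
gal4 <- function(kids = list()) glycan_node("Gal", "b1-4", kids)
sia3 <- glycan_node("Neu5Ac", "a2-3")

case3 <- list(
  man5      = ncore(a3_kids = list(),
                    a6_kids = list(glycan_node("Man", "a1-3"), glycan_node("Man", "a1-6"))),
  m5gn      = ncore(a3_kids = list(gn2()),
                    a6_kids = list(glycan_node("Man", "a1-3"), glycan_node("Man", "a1-6"))),
  m3gn      = ncore(a3_kids = list(gn2())),
  gngn      = ncore(a3_kids = list(gn2()), a6_kids = list(gn2())),
  gngn_bis  = ncore(a3_kids = list(gn2()), a6_kids = list(gn2()), bisect = TRUE),
  gngn_f    = ncore(a3_kids = list(gn2()), a6_kids = list(gn2()), fuc = TRUE),
  g1gn_f    = ncore(a3_kids = list(gn2(list(gal4()))), a6_kids = list(gn2()), fuc = TRUE),
  g2_f      = ncore(a3_kids = list(gn2(list(gal4()))), a6_kids = list(gn2(list(gal4()))), fuc = TRUE),
  s1g2_f    = ncore(a3_kids = list(gn2(list(gal4(list(sia3))))),
                    a6_kids = list(gn2(list(gal4()))), fuc = TRUE),
  s2g2_f    = ncore(a3_kids = list(gn2(list(gal4(list(sia3))))),
                    a6_kids = list(gn2(list(gal4(list(sia3))))), fuc = TRUE),
  tri_g3_f  = ncore(a3_kids = list(gn2(list(gal4())), glycan_node("GlcNAc", "b1-4", list(gal4()))),
                    a6_kids = list(gn2(list(gal4()))), fuc = TRUE),
  tri_bis_f = ncore(a3_kids = list(gn2(list(gal4())), glycan_node("GlcNAc", "b1-4", list(gal4()))),
                    a6_kids = list(gn2(list(gal4()))), bisect = TRUE, fuc = TRUE)
)
dir.create("inst/extdata/case3", recursive = TRUE, showWarnings = FALSE)
for (id in names(case3)) {
  write_glycoct_file(case3[[id]], file.path("inst/extdata/case3", paste0(id, ".glycoct")),
                     header = c("Synthetic stand-in for an MS-annotated CHO N-glycan structure",
                                "(illustrative; not an annotated experimental roster)."))
}
writeLines(yaml::as.yaml(list(
  name = "case3-MS-synthetic",
  description = paste(
    "Synthetic stand-in roster of 12 N-glycan structures emulating a",
    "MALDI-TOF-annotated CHO-cell N-glycan list; real rosters come from",
    "external annotation pipelines and are supplied by the user."),
  binding = FALSE,
  glycans = lapply(names(case3), function(id) list(id = id, file = paste0(id, ".glycoct"))),
  enzymes = list("GnTI", "GnTII", "GnTIII", "GnTIV", "GnTV", "ManII",
                 "FucT", "ST3Gal-IV", "GalT-IV"),
  expected = list(mz_window = list(1400, 3300),
                  path_source = "m3gn", path_target = "tri_bis_f")
)), "inst/extdata/case3/manifest.yaml")

cat("fixtures written\n")
# quick readback check
for (f in list.files("inst/extdata", recursive = TRUE, pattern = "glycoct$", full.names = TRUE)) {
  invisible(read_glycoct(f))
}
cat("all fixtures re-parse\n")
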