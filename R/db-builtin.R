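# Built-in enzyme database: 12 glycosyltransferases and 2 glycosidases
# covering O-linked core-2 elaboration (GalT-IV, b3GnT, ST3Gal-I/II,
# ST3Gal-IV, FT-VII) and N-linked branching (GnT I-V, ManI, ManII, GalT,
# FucT). Specificity encodings follow standard Golgi biochemistry
# (Krambeck-style rule tables): GnT ordering I -> II -> IV -> V enforced via
# substMinStruct; the bisecting GlcNAc chain blocks ManII and GnT II/IV/V;
# galactosylation caps further GnT and mannosidase action (substNAResidue).

# Shared chain/motif strings (LINUCS dialect). The chain patterns are linear
# glycans whose deepest residue is the site the enzyme acts on.
.NCORE        <- "[][GlcNAc]{[(4+1)b-GlcNAc]{[(4+1)b-Man]}}"
.TB_A3MAN     <- "[][GlcNAc]{[(4+1)b-GlcNAc]{[(4+1)b-Man]{[(3+1)a-Man]}}}"
.TB_A6MAN     <- "[][GlcNAc]{[(4+1)b-GlcNAc]{[(4+1)b-Man]{[(6+1)a-Man]}}}"
.TB_GNTI_GN   <- "[][GlcNAc]{[(4+1)b-GlcNAc]{[(4+1)b-Man]{[(3+1)a-Man]{[(2+1)b-GlcNAc]}}}}"
.TB_CORE1GAL  <- "[][GalNAc]{[(3+1)b-Gal]}"
.TB_ROOT_GN   <- "[][GlcNAc]"
.NB_BISECT    <- "[][GlcNAc]{[(4+1)b-GlcNAc]{[(4+1)b-Man]{[(4+1)b-GlcNAc]}}}"
.NB_A6_UNTRIMMED <- "[][GlcNAc]{[(4+1)b-GlcNAc]{[(4+1)b-Man]{[(6+1)a-Man]{[(?+1)?-Man]}}}}"
.MS_GNTI      <- .TB_GNTI_GN
.MS_GNTII     <- "[][GlcNAc]{[(4+1)b-GlcNAc]{[(4+1)b-Man]{[(6+1)a-Man]{[(2+1)b-GlcNAc]}}}}"
.MS_GNTV <- paste0("[][GlcNAc]{[(4+1)b-GlcNAc]{[(4+1)b-Man]",
                   "{[(3+1)a-Man]{[(4+1)b-GlcNAc]}[(6+1)a-Man]{[(2+1)b-GlcNAc]}}}}")
.MS_SLEX_SITE <- "[][GlcNAc]{[(4+1)b-Gal]{[(3+2)a-Neu5Ac]}}"

#' The built-in enzyme database
#'
#' Returns the 14-record database (12 glycosyltransferases, 2 glycosidases)
#' used by the shipped case studies: GnT I-V, ManI, ManII, GalT, GalT-IV,
#' b3GnT, ST3Gal-I/II, ST3Gal-IV, FT-VII and FucT.
#'
#' @return an `enzyme_db` with 14 records.
#' @examples
#' db <- builtin_database()
#' db_get(db, "GnTII")[[1]]
#' @export
builtin_database <- function() {
  recs <- list(
    gt_enzyme("GnTI", "2.4.1.101",
      resfuncgroup = "GlcNAc", linkFG = "b1-2",
      resAtt2FG = "Man", linkAtt2FG = "a1-3",
      targetBranch = .TB_A3MAN,
      substNAResidue = "Gal",
      substNABranch = .NB_BISECT,
      donor = "UDP-GlcNAc",
      name_recommended = "alpha-1,3-mannosyl-glycoprotein 2-beta-N-acetylglucosaminyltransferase",
      names_alternative = "MGAT1",
      reaction_description = "UDP-GlcNAc + Man5GlcNAc2-protein -> UDP + GlcNAcMan5GlcNAc2-protein"),

    gt_enzyme("GnTII", "2.4.1.143",
      resfuncgroup = "GlcNAc", linkFG = "b1-2",
      resAtt2FG = "Man", linkAtt2FG = "a1-6",
      targetBranch = .TB_A6MAN,
      substNAResidue = "Gal",
      substNABranch = list(.NB_BISECT, .NB_A6_UNTRIMMED),
      substMinStruct = .MS_GNTI,
      donor = "UDP-GlcNAc",
      name_recommended = "alpha-1,6-mannosyl-glycoprotein 2-beta-N-acetylglucosaminyltransferase",
      names_alternative = "MGAT2",
      reaction_description = "adds the beta1,2 GlcNAc of the alpha1,6 antenna after mannosidase II trimming"),

    gt_enzyme("GnTIII", "2.4.1.144",
      resfuncgroup = "GlcNAc", linkFG = "b1-4",
      resAtt2FG = "Man", linkAtt2FG = "b1-4",
      targetBranch = .NCORE,
      substNAResidue = "Gal",
      substMinStruct = .MS_GNTI,
      donor = "UDP-GlcNAc",
      name_recommended = "beta-1,4-mannosyl-glycoprotein 4-beta-N-acetylglucosaminyltransferase",
      names_alternative = c("MGAT3", "bisecting GlcNAcT"),
      reaction_description = "adds the bisecting beta1,4 GlcNAc to the core mannose"),

    gt_enzyme("GnTIV", "2.4.1.145",
      resfuncgroup = "GlcNAc", linkFG = "b1-4",
      resAtt2FG = "Man", linkAtt2FG = "a1-3",
      targetBranch = .TB_A3MAN,
      substNAResidue = "Gal",
      substNABranch = .NB_BISECT,
      substMinStruct = .MS_GNTII,
      donor = "UDP-GlcNAc",
      name_recommended = "alpha-1,3-mannosyl-glycoprotein 4-beta-N-acetylglucosaminyltransferase",
      names_alternative = "MGAT4",
      reaction_description = "branches the alpha1,3 antenna of complex N-glycans"),

    gt_enzyme("GnTV", "2.4.1.155",
      resfuncgroup = "GlcNAc", linkFG = "b1-6",
      resAtt2FG = "Man", linkAtt2FG = "a1-6",
      targetBranch = .TB_A6MAN,
      substNAResidue = "Gal",
      substNABranch = .NB_BISECT,
      substMinStruct = .MS_GNTV,
      donor = "UDP-GlcNAc",
      name_recommended = "alpha-1,6-mannosyl-glycoprotein 6-beta-N-acetylglucosaminyltransferase",
      names_alternative = "MGAT5",
      reaction_description = "branches the alpha1,6 antenna, forming tetraantennary N-glycans"),

    gt_enzyme("GalT", "2.4.1.38",
      resfuncgroup = "Gal", linkFG = "b1-4",
      resAtt2FG = "GlcNAc", linkAtt2FG = "b1-2",
      targetBranch = .TB_GNTI_GN,
      donor = "UDP-Gal",
      name_recommended = "beta-N-acetylglucosaminylglycopeptide beta-1,4-galactosyltransferase",
      reaction_description = "galactosylates the beta1,2 GlcNAc of the alpha1,3 (lower) antenna"),

    gt_enzyme("GalT-IV", "2.4.1.38",
      resfuncgroup = "Gal", linkFG = "b1-4",
      resAtt2FG = "GlcNAc",
      donor = "UDP-Gal",
      name_recommended = "beta-1,4-galactosyltransferase IV",
      reaction_description = "caps terminal GlcNAc with beta1,4 galactose (LacNAc synthesis)"),

    gt_enzyme("b3GnT", "2.4.1.149",
      resfuncgroup = "GlcNAc", linkFG = "b1-3",
      resAtt2FG = "Gal", linkAtt2FG = "b1-4",
      donor = "UDP-GlcNAc",
      name_recommended = "N-acetyllactosaminide beta-1,3-N-acetylglucosaminyltransferase",
      names_alternative = "beta1,3GlcNAc-T",
      reaction_description = "extends poly-N-acetyllactosamine on beta1,4-linked galactose"),

    gt_enzyme("ST3Gal-I/II", "2.4.99.4",
      resfuncgroup = "Neu5Ac", linkFG = "a2-3",
      resAtt2FG = "Gal", linkAtt2FG = "b1-3",
      targetBranch = .TB_CORE1GAL,
      donor = "CMP-Neu5Ac",
      name_recommended = "beta-galactoside alpha-2,3-sialyltransferase 1/2",
      reaction_description = "sialylates the core-1 (beta1,3) galactose of O-glycans"),

    gt_enzyme("ST3Gal-IV", "2.4.99.6",
      resfuncgroup = "Neu5Ac", linkFG = "a2-3",
      resAtt2FG = "Gal", linkAtt2FG = "b1-4",
      donor = "CMP-Neu5Ac",
      name_recommended = "beta-galactoside alpha-2,3-sialyltransferase 4",
      reaction_description = "sialylates beta1,4-linked (LacNAc) galactose"),

    gt_enzyme("FT-VII", "2.4.1.152",
      resfuncgroup = "Fuc", linkFG = "a1-3",
      resAtt2FG = "GlcNAc",
      substMinStruct = glycan_motif(.MS_SLEX_SITE, "at_target_residue"),
      donor = "GDP-Fuc",
      name_recommended = "alpha-1,3-fucosyltransferase VII",
      reaction_description = "fucosylates the GlcNAc of an alpha2,3-sialylated LacNAc (sLeX synthesis)"),

    gt_enzyme("FucT", "2.4.1.68",
      resfuncgroup = "Fuc", linkFG = "a1-6",
      resAtt2FG = "GlcNAc",
      targetBranch = .TB_ROOT_GN,
      substMinStruct = .MS_GNTI,
      donor = "GDP-Fuc",
      name_recommended = "glycoprotein 6-alpha-L-fucosyltransferase",
      names_alternative = "FUT8",
      reaction_description = "adds the alpha1,6 core fucose to the reducing-end GlcNAc"),

    gh_enzyme("ManI", "3.2.1.113",
      resfuncgroup = "Man", linkFG = "a1-2",
      resAtt2FG = "Man",
      name_recommended = "mannosyl-oligosaccharide 1,2-alpha-mannosidase",
      reaction_description = "trims alpha1,2 mannoses from oligomannose N-glycans"),

    gh_enzyme("ManII", "3.2.1.114",
      resfuncgroup = "Man", linkFG = c("a1-3", "a1-6"),
      resAtt2FG = "Man", linkAtt2FG = "a1-6",
      substNAResidue = "Gal",
      substNABranch = .NB_BISECT,
      substMinStruct = .MS_GNTI,
      name_recommended = "mannosyl-oligosaccharide 1,3-1,6-alpha-mannosidase",
      names_alternative = "Golgi alpha-mannosidase II",
      reaction_description = "releases the alpha1,3 and alpha1,6 mannoses of the upper antenna after GnT I action")
  )
  enzyme_db(recs)
}
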