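# glyconet

Automated construction and analysis of glycosylation reaction networks in R.

Cellular glycosylation is carried out by families of glycosyltransferases
(which add one monosaccharide from a sugar-nucleotide donor per reaction)
and glycosidases (which remove one terminal residue). Because these enzymes
recognize structural context rather than a template, the set of glycans a
cell can make is defined implicitly by the enzymes it expresses — and
assembling the implied reaction network by hand is tedious and error-prone.
`glyconet` makes the enzymology machine-readable and derives the networks
automatically. It is aimed at systems-glycobiology work: building pathway
models for selectin-ligand O-glycans, N-glycan branching, or MS-profiled
cell lines, and exporting them to SBML for downstream kinetic modeling.

## What it does

* **Glycan structures** are rooted trees of residues (reducing end at the
  root) with typed linkages (anomer, donor and acceptor carbons), read and
  written as LINUCS-style and GlycoCT-condensed-style text. A canonical
  string gives every structure a unique identity regardless of branch
  order.
* **Enzymes** are records in the Enz/TfEnz/HlEnz → GTEnz/GHEnz hierarchy:
  the bond formed or broken (`resfuncgroup`, `linkFG`), its attachment
  context (`resAtt2FG`, `linkAtt2FG`), and optional constraints — the
  branch the enzyme works on (`targetBranch`), residues or reducing-end
  motifs that block it (`substNAResidue`, `substNABranch`), and required
  minimal structure (`substMinStruct`). A built-in database ships 14
  curated enzymes (GnT I–V, ManI, ManII, GalT, GalT-IV, b3GnT,
  ST3Gal-I/II, ST3Gal-IV, FT-VII, FucT); your own databases load from a
  plain-text stanza format.
* **Single-step inference**: `infer_products(enzyme, glycan)` and its
  inverse `infer_substrates()` apply the three-step algorithm (verify the
  enzyme can act; locate modifiable residues; build products by rule).
* **Network inference**: `forward_network()` (fixed point of product
  inference from seed glycans), `reverse_network()` (starting materials
  from products), and `connection_network()` (all enzyme-consistent chains
  linking each of the m(m−1)/2 pairs of observed glycans, with
  size-bounded intermediates).
* **Graph analysis**: exhaustive simple-path enumeration
  (`path_finding()`), subset-network generation by counted or named
  deletion (`subnet_by_num_del()`, `subnet_by_spec_del()`,
  `subnet_by_spec_keep()`), isolated-species handling, and a knockout
  sweep (`subset_sweep()`).
* **I/O**: SBML Level 2 export/import with each glycan's structure
  embedded in the species annotation (`glycoct` element in the eurocarbdb
  encoding namespace); DOT and GraphML graph export.
* **MS glycomics**: `read_ms()` for raw m/z–intensity traces,
  `ms_process()` (background adjustment → normalization → noise removal →
  peak finding), `annotate_compositions()` (permethylated/native
  monoisotopic masses, sodiated or protonated), and `synth_spectrum()` for
  seeded synthetic spectra with ground truth.

## Worked example

The N-linked case study: forward inference from GlcNAcMan5GlcNAc2 (M5Gn)
under five Golgi enzymes, then six.

```r
library(glyconet)

c2 <- case2_inputs()
m5gn <- c2$glycans[[1]]
write_linucs(m5gn)
#> [1] "[][GlcNAc]{[(4+1)b-GlcNAc]{[(4+1)b-Man]{[(3+1)a-Man]{[(2+1)b-GlcNAc]}[(6+1)a-Man]{[(3+1)a-Man][(6+1)a-Man]}}}}"

net5 <- forward_network(m5gn, c("GnTII", "GnTIII", "GnTIV", "GnTV", "ManII"))
net5
#> <pathway: 14 species, 14 reactions>
#>   roles: end_product=7, inferred_intermediate=6, seed=1

net6 <- forward_network(m5gn, c("GnTII", "GnTIII", "GnTIV", "GnTV", "ManII", "GalT"))
net6
#> <pathway: 28 species, 28 reactions>
#>   roles: end_product=14, inferred_intermediate=13, seed=1
```

The five-enzyme system closes at 14 species and 14 reactions: mannosidase
II trims the two upper-arm mannoses (two orders, one diamond), GnT II–V
then branch in order, and the bisecting GlcNAc added by GnT III freezes
each intermediate because it blocks ManII and the other GnTs. Adding GalT
doubles the system to 28/28 — every species gains exactly one
galactosylated, terminally capped counterpart, because galactose blocks
all further GnT and mannosidase action.

The O-linked case study connects a core-2 trisaccharide with 12 observed
PSGL-1 O-glycans:

```r
c1 <- case1_inputs()
net <- connection_network(c1$glycans, unlist(c1$enzymes), labels = c1$labels)
net
#> <pathway: 20 species, 28 reactions>
#>   connection inference over 78 glycan pairs
#>   roles: end_product=3, inferred_intermediate=7, seed=10

length(path_finding(net, "glycan00", "glycan09"))
#> [1] 6
```

The 13 inputs plus 7 in-silico intermediates form a 20-species,
28-reaction pathway; six distinct reaction routes lead from the core-2
seed (`glycan00`) to the large sialyl-Lewis-X glycan (`glycan09`).

## Command line

A thin CLI over the same functions lives at `inst/cli/glyconet`
(`glyconet network forward --enzymes GnTII,ManII --glycans m5gn.glycoct
--out net.sbml`, `glyconet ms process --in raw.msd`, ...). Run it without
arguments for the sub-command summary.

## Scope notes

Kinetic rate constants, sugar-nucleotide pools and compartmentalized
(ER/Golgi-ordered) inference are out of scope: the package constructs and
analyzes network topology; exported SBML is the hand-off point to kinetic
tooling. The shipped Case-3 roster is a documented synthetic stand-in for
an externally annotated cell-glycomics structure list.
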