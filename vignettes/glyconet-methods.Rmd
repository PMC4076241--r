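---
title: "Rule-based reconstruction of glycosylation reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based reconstruction of glycosylation reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyconet)
```

# The modeling problem

Glycan biosynthesis is not template-driven: the glycoforms a cell produces
are determined by which glycosyltransferases and glycosidases it expresses
and by the structural context each enzyme requires. `glyconet` encodes that
enzymology as data and derives reaction networks mechanically. This
vignette records the model, its assumptions, the parameters that matter,
and the design decisions that were genuinely open.

# Glycans as rooted trees

A glycan is a rooted ordered tree: the reducing-end residue is the root,
every other residue carries the linkage (anomer, donor carbon, acceptor
carbon) to its parent. Eight residue symbols are supported (Glc, Gal, Man,
GlcNAc, GalNAc, Fuc, Neu5Ac, Xyl), each mapping to one composition class
(Hex, HexNAc, dHex, NeuAc; Xyl is kept in a fifth class, Pen, rather than
being misfiled as a hexose). The protein or peptide is never modeled: O-
glycan trees root at GalNAc and N-glycan trees at the innermost GlcNAc,
matching how released-glycan data are reported.

Identity is defined by `canonical_string()`: siblings are ordered by
acceptor position, then anomer, then recursive canonical string, so any
two trees differing only in branch order map to one key. All species
deduplication — in pathways, product lists, SBML round trips — goes
through this key. Two undetermined linkage fields are equal only to each
other in the canonical form, but during motif matching an undetermined
field is a wildcard: mass-spectrometry-annotated structures carry
unresolved linkages, and a rule written with `?` must still engage them.

Two further structural conventions:

* **Occupancy is per carbon.** A residue can carry at most one substituent
  on a given acceptor carbon, whatever the anomer. This is the chemistry
  (one hydroxyl per carbon) and it is load-bearing: it is what makes an
  internal poly-LacNAc galactose — whose C3 already bears the next GlcNAc
  — unavailable for α2,3-sialylation.
* **Node references are paths, not indices into a mutable array.** Edits
  (`attach_residue()`, `remove_residue()`) are value-semantic: the input
  glycan is never modified, and trees are re-canonicalized after each
  edit so integer child-index paths stay deterministic.

Text encodings are a LINUCS-style linear form (reducing end first,
children depth-first, `(acceptor+donor)` linkage codes) and a
GlycoCT-condensed-style form restricted to RES/LIN sections, one entry
per residue — sufficient for every structure handled here (no repeating
units, no underdetermined topology). Both writers emit canonical sibling
order, so output is byte-stable and golden-testable.

# Machine-readable enzymes

A glycosyltransferase (GTEnz) or glycosidase (GHEnz) record holds, beyond
EC number and names:

* `resfuncgroup`, `linkFG` — the residue and linkage formed (GT) or broken
  (GH). For a glycosidase `linkFG` may be a *set*, matched disjunctively:
  Golgi α-mannosidase II releases both α1,3- and α1,6-linked mannose from
  one record.
* `resAtt2FG`, `linkAtt2FG` — the residue the bond attaches to and that
  residue's own linkage to its parent.
* `targetBranch` — the linear residue/linkage chain from the acted-upon
  residue *toward the reducing end*. It is matched as a prefix of the
  site's path to the root and is how isoenzymes are pinned to specific
  antennae (e.g. GalT restricted to the β1,2 GlcNAc of the α1,3 arm, or
  the core-fucosyltransferase pinned to the reducing-end GlcNAc by a
  single-residue chain).
* `substNAResidue` — residues whose presence *anywhere* in the substrate
  blocks action (galactose capping the GnTs and mannosidase II).
* `substNABranch` — reducing-end-anchored motifs whose match blocks action
  (the bisecting-GlcNAc chain GlcNAcβ1,4Manβ1,4GlcNAcβ1,4GlcNAc).
* `substMinStruct` — a motif the substrate must contain. Its anchor is
  respected: anchored at the reducing end it is a global prerequisite
  (GnT II requiring the GnT I product); anchored `at_target_residue` it
  constrains the *site's own subtree*, which is how FT-VII is limited to
  the GlcNAc of an α2,3-sialylated LacNAc — a child-side condition that
  `targetBranch`, a root-side chain, cannot express.

The two scopes of the blocking fields are deliberate and minimal: the two
uses the biology requires are a residue blocking globally (Gal) and a
reducing-end chain blocking structurally (bisection). `substMinStruct` is
also accepted on glycosidase records — mannosidase II acts only after
GnT I, a positive prerequisite the original field list for hydrolases
lacks; the schema treats it as optional there.

## The built-in database

Fourteen records ship with the package (12 GT, 2 GH): GnT I–V, ManI,
ManII, GalT (antenna-restricted), GalT-IV (generic LacNAc synthesis),
b3GnT, ST3Gal-I/II, ST3Gal-IV, FT-VII and FucT (core α1,6). The N-glycan
branching rules follow the standard ordered model: GnT I → (ManII
trimming) → GnT II → GnT IV → GnT V, with bisection by GnT III freezing
trimming and further branching, and galactosylation capping everything.
The ordering constraints (GnT IV requires the GnT II product; GnT V
requires GnT II and GnT IV products) are encoded as `substMinStruct`
chains; they are what closes the five-enzyme network at exactly 14
species rather than an order-scrambled superset. User databases load and
save through a plain-text stanza format (`load_db()`/`save_db()`), with
obligatory-field validation and parse errors that name the enzyme.

# Single-step inference

`infer_products(e, g)` follows three steps: verify the enzyme can act
(global blockers, global prerequisites, at least one site); locate sites
(attachment residue, context linkage, free acceptor carbon, branch chain,
site-anchored motif — or for a glycosidase, terminal residue, linkage in
the cleavage set, parent context); build one product per site and
deduplicate by canonical key. Output is sorted by product key, so
inference is deterministic.

`infer_substrates(e, p)` inverts the step: candidate precursors are
formed by removing a matching terminal residue (GT) or re-attaching the
cleaved residue at every open position (GH), and a candidate is kept only
if the forward step on it regenerates `p`. This forward check is what
keeps reverse inference sound — a candidate that violates a blocking
constraint can never be proposed, and forward/reverse duality holds by
construction (and is property-tested over the full case-study reaction
space).

# Network construction

* `forward_network()` iterates product inference to a fixed point per
  seed, merges, and deduplicates. Reaction identity is the triple
  (substrate key, product key, enzyme name): two enzymes catalyzing the
  same conversion are two labeled edges.
* `reverse_network()` does the same with substrate inference, then prunes
  to species that reach at least one input product. Because a
  glycosidase's reverse step proposes *larger* precursors, a hydrolase-
  containing reverse search is open-ended upward; candidates are capped
  at `max_size` residues (default: largest input + 4 — enough headroom to
  recover trimming precursors without letting mannose chains grow without
  bound).
* `connection_network()` analyzes each of the m(m−1)/2 unordered input
  pairs once (the count is recorded on the result). Within a pair, the
  substrate/product orientation follows enzyme directionality: with a
  pure transferase pool the residue-count-smaller member must be the
  substrate; with mixed pools both orientations are attempted and those
  yielding chains are kept. From the designated product, substrate
  inference is applied stepwise with every intermediate bounded in size
  between the pair — this both matches the "connection" semantics and
  guarantees termination — and the surviving chains are exactly the
  edges on some substrate→product route. Substrate expansions are
  memoized across pairs.

`max_iter` (default 50) caps the fixed-point rounds; hitting it sets a
truncation flag on the pathway rather than failing, because pools
containing both b3GnT and a β1,4-galactosyltransferase legitimately
generate unbounded poly-LacNAc repeats.

# Graph analysis

The pathway's graph view (species = nodes, enzyme-labeled reactions =
parallel directed edges) is an igraph object. `path_finding()` enumerates
*all* simple directed paths between two species — vertex paths from
igraph's depth-first enumeration, then cartesian expansion of parallel
enzyme-labeled edges, so each labeled route is a distinct path.
`subnet_by_spec_del()`/`subnet_by_spec_keep()` are the named-species
subset operations; `detect_isolated_species()` defines isolation as
participation in zero reactions (only meaningful when the pathway has
any reactions) and its removal is idempotent.

## Counted-deletion subset models

`subnet_by_num_del(p, k, protected, require_any)` enumerates all
`choose(n_deletable, k)` deletions of non-protected species (a seeded
random-sampling mode exists for large networks). After deleting the
chosen species and their incident reactions, cleanup runs to a fixed
point: isolated species are removed, and so are in-silico inferred
intermediates that are no longer both the substrate and the product of
some surviving reaction — a structure with no experimental support may
not dangle in a subset model. The cascade matters: removing a dangling
intermediate can orphan its neighbor. A generated subset pathway is
valid when the protected start species and at least one required end
product survive.

`subset_sweep()` profiles knockout depth by counting, at each k, the
*distinct* valid subset pathways generated. Distinctness is the right
unit here: as k grows, more and more deletion sets collapse after
cleanup to the same surviving pathway, and counting raw deletion sets
simply tracks the binomial growth of the enumeration (on the shipped
O-glycan network it rises monotonically into k ≈ 8–9). The number of
distinct generated subset models instead peaks in the interior — at
k = 6 on that network — which is the quantity that measures how much
model diversity a given knockout depth yields. Both counts are
available (`distinct = FALSE` gives the raw one), and the two are
cross-checked against the explicit generator in the test suite.

# SBML and graph export

Pathways export to SBML Level 2 Version 4 (the most widely consumed
level/version among pathway tools; nothing here needs L3 constructs). Every glycan species embeds
its structure in the species annotation as a `glycoct` element in the
`http://www.eurocarbdb.org/recommendations/encoding` namespace, with
`sugar`/`residues`/`linkages` children mirroring the condensed RES/LIN
encoding — element children rather than an opaque text blob, so foreign
tools can read the structure without a LINUCS parser. Species ids are
`gly_` plus a deterministic 32-bit hash of the canonical key (stable
diffs, stable round trips); enzymes become boundary species (`enz_`
prefix) referenced as reaction modifiers, with the enzyme name
duplicated as the reaction `name` attribute since SBML L2 has no
first-class edge label. Import reverses all of this and rejects, by
species id, any non-enzyme species lacking a structure annotation.
DOT and GraphML exports carry labels and roles on nodes and enzymes on
edges.

# MS glycomics

`ms_process()` implements the four-step peak pipeline with these
parameters (all in `ms_params()`):

| parameter | default | meaning |
|---|---|---|
| `baseline_window_th` | 10 Th | half-window of the moving-minimum + moving-average background estimate; must be ≫ peak width |
| `smooth_window_th` | 0.15 Th | half-window of the pre-detection moving average |
| `snr_threshold` | 3 | multiples of the robust noise scale below which points are zeroed |
| `min_height` | 1 | minimum apex height after normalization to 100 |

One numerical subtlety: a moving-minimum baseline sits systematically
*below* the noise floor (it tracks the window minimum), so after
subtraction the trace keeps a small positive offset. The smoothed trace
is therefore re-centered on its median (peaks are sparse) before
thresholding, and the apex criterion uses the larger of `min_height` and
`snr_threshold` times the raw (unsmoothed) noise scale, both estimated
by the median absolute deviation of the sub-95th-percentile signal.
Centroids are intensity-weighted means over the half-height region and
FWHM is interpolated on the smoothed trace. The pipeline is invariant to
uniform intensity scaling (normalization) and to constant offsets
(baseline subtraction), and an all-zero spectrum yields an empty peak
list, not an error.

`annotate_compositions()` enumerates the bounded composition lattice and
reports every composition within `tol_ppm` of each centroid. Masses are
monoisotopic, singly charged, sodiated and permethylated by default —
the standard MALDI-TOF glycomics workup — with native/protonated
alternatives. Assigning *structures* to compositions is out of scope:
that step depends on external annotation pipelines, so structure rosters
enter the package as fixture files.

## The synthetic-spectrum generator

`synth_spectrum()` emulates a MALDI-TOF profile over m/z 1500–3250 at
0.05 Th grid spacing: Gaussian peaks (σ = 0.15 Th) at the theoretical
permethylated sodiated masses of the requested compositions, a linear
baseline, and seeded Gaussian noise, returning the ground-truth peak
table alongside. It emulates peak position, width, relative intensity
and additive noise; it does **not** emulate isotope envelopes, detector
saturation, chemical (structured) baseline, charge states, or in-source
fragmentation. Pipeline tests against it therefore validate the
centroiding and annotation logic — recall ≥ 0.9 and false discovery
≤ 0.1 at signal-to-noise ≥ 10 over 20 seeded replicates — not
performance on real raw spectra.

# The case-study fixtures

The three shipped case studies are the package's regression surface.
Binding expectations (asserted exactly): the O-linked connection network
(13 inputs — the core-2 trisaccharide seed plus 12 observed PSGL-1
O-glycans — with GalT-IV, b3GnT, ST3Gal-I/II, ST3Gal-IV, FT-VII) has 20
species, 28 reactions and 7 in-silico intermediates, its knockout sweep
peaks at 6 deletions, and paths exist from the seed to both
sialyl-Lewis-X products; the N-linked forward network from
GlcNAcMan5GlcNAc2 has 14 species/14 reactions with five enzymes and
28/28 with GalT added. The O-glycan roster is a documented
reconstruction on the core-2 scaffold (LacNAc extension, poly-LacNAc to
three repeats, core-1 and LacNAc α2,3-sialylation, distal
α1,3-fucosylation); where a published cartoon admits more than one
transcription the choice was resolved once toward reproducing the
published network sizes, and the fixture headers say so. The third case
is a *synthetic stand-in* for an MS-annotated structure roster (12
N-glycan structures, 9 enzymes): its expectations are smoke-level only —
the network builds, exports, connects GlcNAcMan3GlcNAc2 to the largest
structure, and every constructed species' permethylated sodiated mass
stays inside the configured window — because the original roster derives
from an external annotation pipeline and is not recoverable.

Problem sizes throughout (13-glycan connection inference, 28-species
forward networks, k ≤ 10 exhaustive sweeps over 19 deletable species,
200-graph path-finding oracles, 500-tree canonicalization corpus, 20
spectrum replicates) were chosen so the full suite exercises every
exact published count while remaining desk-scale.

# Known limitations

* Kinetics are out of scope by design: no rate constants, no
  simulation; SBML export is the hand-off.
* No compartmentalization (ER/Golgi ordering) — enzyme order emerges
  only from structural prerequisites.
* Single-residue steps only: en-bloc transfer of the dolichol precursor
  and transglycosylation are not modeled.
* The eight-residue vocabulary excludes sulfation, phosphorylation and
  acetylation; repeating-unit and underdetermined-topology glycans are
  not representable.
* Reverse inference with glycosidases depends on the `max_size` cap;
  conclusions about "all possible precursors" are conditional on it.
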