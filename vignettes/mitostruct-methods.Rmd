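---
title: "mitostruct: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitostruct: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitostruct)
```

# The problem

Plant mitochondrial genomes are multipartite: rather than one "master
circle", the mitogenome exists as several autonomous, mostly circular
molecules. Potato mitogenomes carry a handful of large (>1 kb),
near-identical repeat pairs, and homologous recombination at these
repeats is frequent and reversible. A crossover between two *direct*
copies on a circle splits it into two sub-genomic circles whose lengths
sum to the parent's; a crossover between two *inverted* copies produces
an equal-length isoform with the inter-repeat segment
reverse-complemented. Long reads make these events observable: a read
that spans a junction found only in a recombination product — with
enough aligned sequence on both sides — is direct evidence that the
product exists in vivo ("reverse read mapping"). Alongside
recombination, molecules from different clones differ by small
rearrangements: a ~774 bp block carrying *orf210* sits at different
positions in the two main molecule-3 architectures, bracketed on both
sides by a 40 bp direct repeat — the likely recombination substrate —
and the same block is additionally inserted in one clone's molecule 2.
Finally, a marker-PCR locus distinguishes mtDNA types by product size
(~2.4 kb = α, ~1.6 kb = β, no product = γ), which combine with
chloroplast types into cytoplasm labels such as W/γ (associated with
male sterility).

`mitostruct` implements this whole analysis chain — repeat discovery,
product enumeration, junction prediction and read support, pairwise
molecule comparison with breakpoint-flank discovery, in silico PCR
typing, and gene/ORF inventories — together with a synthetic-genome and
long-read simulator that reproduces the published molecule architectures
with machine-readable truth.

# Coordinates and containers

All coordinates are 1-based and closed (the R/Bioconductor convention;
GFF3 is native, FASTA headers and PAF are converted at the boundary).
On circular molecules every position is interpreted modulo the length.
A single convention throughout the package avoids fence-post errors
between modules; the arbitrary assembly origin is handled by requiring
rotation invariance of every structural result (tested property).
`N` bases are allowed in molecules but never participate in matches:
k-mers containing `N` are skipped, which treats `N` as a mismatch — the
simplest conservative rule.

# The synthetic genomes

The generator is first-class, tested code: its profiles *are* the study
conditions, and every test and the acceptance script run against it.

* **Molecule and repeat sizes.** The four named profiles (`groupA`,
  `groupB`, `clone10908`, `oka15`) use the published assembly sizes at
  `scale = 1` (e.g. group A: 297,036 / 229,589 / 112,834 / 49,239 bp;
  group B molecule 2: 113,443 bp) and the published repeat family
  lengths (R1 11,916; R2 7,502; R3 4,513; R4 1,589; OKA15's expanded R1
  13,435 and reduced R2 7,076). Orientation follows the published
  structure: R1 is inverted in group A molecule 1a, everything else is
  direct; OKA15 molecule 2 has no R4.
* **Shared core of group A molecules 1a/1b.** Both molecules are built
  from one shared segment list (length = len(1b) − 9.8 kb ≈ 219.8 kb)
  plus molecule-specific segments (~77.3 kb in 1a, 9.8 kb in 1b). One
  R1 copy and the whole R2 pair live in the shared core; the second,
  inverted R1 copy lives in the 1a-specific segment. This reproduces
  the published repeat occupancy exactly: R2 present in both molecules,
  1b carrying a single unpaired R1 copy.
* **Copy placement.** Repeat coordinates are not published, so spacer
  lengths are a package choice, recorded in the truth. The one
  constraint honoured: molecule-2 R4 copies are separated by 45 kb of
  arc so the two sub-genomic circles come out at ~45 kb and ~67.8 kb,
  matching the published split.
* **Maximality sealing.** After planting, the single background base on
  each side of copy 2 is adjusted, if needed, so the exact repeat match
  cannot extend past the planted boundaries. Without this, a 1-in-4
  chance per side would make the maximal repeat one or two bases longer
  than requested and the planted "truth length" ill-defined. Sealing
  mutates background only (the translocation fixture instead fixes the
  two block end bases, so both molecules stay identical).
* **Scale.** `scale` shrinks only the random spacers (minimum 200 bp),
  never the planted features, so printed repeat lengths survive
  desk-scale runs. Background GC is fixed at 0.45 — no background
  composition model is published, and none of the implemented methods is
  sensitive to it.
* **Reads.** Lengths are lognormal (default mean 10 kb, log-sd 0.4)
  clipped to [2, 40] kb — a PacBio-like profile parameterised only as
  far as junction-spanning capability requires. Starts are uniform on
  the source circle (reads may wrap the origin), strands uniform,
  substitution/indel errors applied after extraction, capped at 20%
  per-base. Provenance of every read is recorded, so expected junction
  support is exactly reconstructible at error rate 0. What the
  simulator does **not** model: chimeric reads, quality-value
  structure, coverage bias, heteroplasmy stoichiometry. Passing tests
  therefore demonstrate the machinery, not robustness to every real
  PacBio artefact.

# Repeat detection

`findRepeats()` is seed-and-extend: exact k-mer seeds (default k = 21)
on the doubled sequence (circularity), runs of consecutive seeds on a
common diagonal (anti-diagonal for inverted matches) collapsed into
maximal exact matches, same-diagonal matches chained across gaps up to
`maxGap` (default 100 bp, which absorbs substitution divergence; the
chains are gap-free in the indel sense), duplicates removed modulo the
length, the trivial self-hit excluded, contained sub-repeats suppressed.
Identity is computed exactly, by columnwise comparison of the two copy
sequences — not estimated from seed coverage — so a pair at 2%
divergence scores 0.98. Defaults: `minLen` 1,000 bp (the published
threshold for the large, recurrently recombining repeat class) and
`minIdentity` 0.98 (such repeats recombine homologously, implying
near-identity). Copy order is canonicalised by rotating the circle so
the origin falls in the largest repeat-free arc and labelling the first
copy encountered as A — a deterministic convention on circles.

The contract is behavioural, verified two ways: equivalence with an
independent exhaustive diagonal-scan oracle on small instances, and
exact recovery of planted pairs (length, orientation, coordinates)
on profile fixtures, under rotation and reverse-complementation.

`findShortRepeats()` is the same engine restricted to a window, with
exact matching only (`maxGap = 0`), for the 20-200 bp breakpoint-flank
class. `matchFamilies()` labels pairs whose length falls within ±10% of
a known family length (including the OKA15 variants); everything else is
`custom`.

# Recombination products and junctions

`enumerateProducts()` implements single-crossover events only: products
of products (chained recombination) are excluded, because single-event
sub-genomic circles and inversion isoforms are the species the long
reads support. For an inverted pair the product is assembled as
copyA + revcomp(arc) + copyB + arc₂: with near-identical copies a
mid-copy crossover leaves both copies intact and inverts only the
inter-copy arc. Deduplication across pairs uses the canonical circular
form — the lexicographically least rotation of the sequence or its
reverse complement (Booth's algorithm) — which is also the equality
relation used by the involution test (inverting twice restores the
parent).

**Junction geometry.** With exact repeat copies, any window centred on
the crossover point itself also occurs in the parent: the parent
contains the same flank-into-repeat context via the other copy. A
window is absent from the parent only if it spans the *entire* repeat
copy plus at least one base of product-specific context on each side.
Junction constructs are therefore centred on the midpoint of the
recombinant repeat copy, and are novel iff `2w` exceeds the repeat
length (`predictJunctions()` verifies novelty against both strands of
the doubled parent and warns when it cannot hold). The same geometry
dictates validation: a spanning read is isoform-specific only when its
anchors clear the repeat copy ends, i.e. `minAnchor` > repeat/2 for a
repeat-centred construct; `countSupport()` warns below that bound. This
is the central ambiguity of repeat-mediated junctions, made explicit
rather than hidden in defaults.

# Reverse read mapping

The internal mapper is deliberately simple and deterministic: exact
15-mer seeds, the dominant seed diagonal per read/target/strand, and a
local alignment (`pairwiseAlignment`, match 2 / mismatch −4 / gap 4+2)
of the seeded read window against the construct; identity is
matches / alignment columns; best hit per read and target. It exists so
the pipeline is testable at desk scale without external binaries; for
real data the PAF import path is the escape hatch, and a test
cross-checks that minimap2 output fed through `readPaf()` reproduces
the internal mapper's support counts on error-free reads. A junction is
`supported` at ≥ 3 spanning reads (`minReads`), the conventional
long-read structural-evidence floor.

# Molecule comparison

`anchorBlocks()` anchors on 31-mers unique in both molecules (counting
both strands — a k-mer that also occurs reverse-complemented anywhere
is ambiguous and skipped), merges consecutive anchors on a common
diagonal into gap-free blocks, and then *bridges* same-diagonal blocks
across non-unique stretches after verifying the intervening sequences
are byte-identical. Bridging is what lets a repeat copy sitting inside
a truly shared region (the R2 pair inside the 1a/1b core) count as
shared rather than fragmenting it; the bridge cap (25 kb) just exceeds
the largest repeat family. Blocks are gap-free by construction, so
shared + unique = length holds exactly, and divergence shows up as
block fragmentation, not as alignment gaps — arrangement claims, not
alignments, are the goal.

`detectRearrangements()` reads events off the cyclic block order: the
consistent backbone is the maximum-weight cyclically increasing
subsequence of B-positions in A-order (weights = block widths; computed
over all rotations, which makes the call rotation invariant); blocks
off the backbone are translocations; strand-flipped blocks (after
normalising a globally flipped B) are inversions; coverage gaps ≥ 200
bp on one side only are insertions/deletions. Event duality under
argument swap (insertion ↔ deletion) is a tested property.

**Flank refinement.** An anchored block around a moved, repeat-flanked
unit systematically overshoots: k-mers reaching from the flank into the
block are unique, so the raw block extends into both flank copies and
over-reports the moved unit by up to 2·(flank − 1) bp, and the
breakpoint position inside the repeat is intrinsically ambiguous.
When a direct short-repeat pair brackets a translocated/inserted block
(searched in ±500 bp windows), the event is refined to the region
*strictly between* the two flank copies — the unit the biology actually
moves — which is how the fixture's 774 bp block and 40 bp flank are
reported exactly. Without a flanking pair the raw anchored boundaries
stand, at anchor (k-mer) resolution.

The Ψcob–rps10-style arrangement comparisons are expressed as an
annotation report, `reportIntergenic()`, returning the distance between
two named features, rather than a bespoke detector.

# In silico PCR and typing

`findPrimerSites()` scans both strands with wrap-around, tolerating
`maxMismatches` (default 2) but requiring the 3′-terminal base to match
exactly — without polymerase extension from the 3′ end there is no
product, and the rule suppresses spurious sites. `amplify()` reports
every convergent site combination up to `maxProduct` (5 kb), product
lengths measured modulo the length. The type rule maps product size to
class with a ±15% tolerance around 2.4 kb (α) and 1.6 kb (β) — wide
enough for "approximately", narrow enough that the classes stay
disjoint; no product at all is γ; two products in different classes is
an honest `unknown`. The marker primer sequences themselves are not
published here, so fixtures plant synthetic sites at the published
distances and the decision grid is property-tested over 0-5,000 bp;
real primers are supplied through the TSV config.

# Gene and ORF inventory

ORFs are ATG-initiated and stop-terminated; `lengthCodons` excludes the
stop (a "100-codon" ORF is 303 bp including its stop), with the
threshold applied as ≥ `minCodons`. Circular molecules are scanned on
the doubled sequence in all six frames and deduplicated modulo the
length, so origin-crossing ORFs are found once; ORFs longer than the
molecule (possible only on nearly stop-free circles) are dropped. The
start-codon set is configurable for mitochondrial alternatives. The
category lexicon is fixed (atp, nad, rps_rpl, ccm, cox, sdh, cob, matR,
mttB, rRNA, tRNA, orf, plastid_derived, pseudo); ids that do not
classify raise an error listing them, rather than being guessed. The
published "50-54 ORFs" per real genome is a property of the real
sequences and is deliberately not asserted on synthetic backgrounds.

# Problem sizes and numerical choices

Tests run the generator at `scale` 0.1-0.2 (molecules of ~20-65 kb with
full-size repeats) except where a published integer depends on the full
molecule: repeat recovery (molecule 1a at 297,036 bp; molecule 2 at
112,834 bp), the molecule-3 translocation pair (49,239 bp), and the
molecule-2 junction-support check (112,834 bp, ~170 reads at 12×
coverage of the two sub-circles, `w` = 1,200, `minAnchor` = 1,000) run
at full size. Read-mixture tests use 3 fixed seeds; conservation and
coordinate properties use 100 randomised cases under one seed. All
randomness flows through explicit seeds; the acceptance script derives
every seed from its `--seed` argument.

# Known limitations

* Single-crossover enumeration only; no recombination-rate model for
  short/intermediate repeats (their events are rare and
  non-reversible), and no isoform stoichiometry estimation.
* The internal mapper is not a general-purpose aligner; it assumes
  targets of at most a few tens of kb (junction constructs, molecules)
  and low-divergence reads. Use an external mapper plus PAF import
  beyond that.
* `anchorBlocks()` reports gap-free blocks; molecules at more than a
  few percent divergence will fragment into many blocks and inflate the
  "unique" totals.
* Inter-molecule fusion (whether molecules 1a/1b also interconvert via
  a single linear form) is not modelled; no operation creates
  cross-molecule products.
* The translocation/insertion caller assumes at most a handful of
  events between structurally similar molecules; it is not a
  whole-genome SV caller.
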