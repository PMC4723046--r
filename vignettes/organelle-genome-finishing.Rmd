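---
title: "Finishing and comparing plant organelle genomes with organellum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finishing and comparing plant organelle genomes with organellum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organellum)
```

## The problem

Plant cells carry two organelle genomes besides the nucleus. The
chloroplast genome (plastome) is a 150–160 kb circle with a conserved
quadripartite architecture: a large and a small single-copy region (LSC,
SSC) separated by two identical inverted repeats (IRa, IRb) of roughly
25–28 kb. The mitochondrial genome is far larger (hundreds of kb), highly
rearranged between species, and typically contains segments of transferred
plastid DNA at high identity. Whole-genome shotgun data of total DNA mixes
reads from all three compartments at very different copy numbers:
chloroplast coverage is typically an order of magnitude above
mitochondrial coverage, which in turn sits well above the nuclear
background.

`organellum` implements the computational steps needed to finish both
organelle genomes from such data and to exploit them comparatively:

1. **Mapping and consensus** — reference mapping with explicit acceptance
   thresholds, per-base pileups, and quality-voting consensus calls.
2. **Plastome finishing** — inverted-repeat detection, expansion of the
   collapsed-IR assembly artifact, and a canonical rotation/strand.
3. **Mitogenome finishing** — chloroplast-read subtraction, scaffold
   merging, read-based end extension, circular closure, and detection of
   chloroplast-like regions.
4. **Variants and statistics** — quality-based variant calling at a 90%
   frequency threshold, the SNP-position counting rule, and SNPs/kb.
5. **Comparative analysis** — variant matrices from whole-plastome
   alignments, species-specific (whole-plastome barcode) filtering,
   10-kb variation-hotspot scans, pairwise identity and GC content.
6. **Phylogeny** — JC69/K80/LogDet/GTR+Γ pairwise distances, UPGMA trees,
   and bootstrap supports.

Every stage can be exercised against simulators (`gen_plastome`,
`evolve_lineage`, `gen_mitogenome`, `simulate_reads`) that produce data
with complete ground truth, so correctness claims in the test suite are
always claims about recovery of planted truth.

## The mapping and consensus model

A read placement is accepted if and only if its **aligned read fraction**
is at least `length_fraction` and its **identity over aligned columns** is
at least `similarity_fraction` (`mapping_params()`). Two presets matter in
practice: `(0.95, 0.99)` for variant mapping between near-identical
genomes, and the stricter `(0.99, 0.99)` for subtracting chloroplast reads
before mitochondrial assembly. With 250 bp reads, the second preset
removes every read within two mismatches of the plastome while retaining
reads from chloroplast-like mitochondrial regions at ~95% identity — the
basis of the subtraction step.

Candidate placements come from exact 21-mer seeds; each candidate is first
scored ungapped on its diagonal and only falls back to a banded
end-space-free alignment (band = 10% of the read length, match +1,
mismatch −2, gap −3) when needed. Identity is matches over aligned
columns, with internal gap columns counting against identity. The best
placement is chosen by identity, ties broken to the leftmost start and
then the forward strand. The tie rule has a visible scientific
consequence: reads from inside the IRs all stack on the leftmost copy, so
a resolved quadripartite reference shows the classic coverage signature —
doubled depth on one IR copy, zero on the other — and consensus claims are
only meaningful on repeat-free references or per-copy.

Because the mapper is seed-anchored, the acceptance contract is verified
in the tests against a brute-force placement oracle on substitution-only
instances; reads whose errors happen to destroy every sampled seed can in
principle be missed, which is the usual trade-off of seed-and-extend
mapping and is why high coverage is assumed throughout.

Consensus calling (`call_consensus`) resolves each column by the base with
the highest summed Phred quality (ties: higher read count, then
alphabetical; a deletion loses a full tie). Columns below `min_cov`
(default 5 — deliberately explicit, since "low coverage" has no canonical
definition) either split the consensus into segments or become `N`,
depending on the policy; split mode never emits `N`, n-fill mode preserves
reference length.

## Plastome finishing

`detect_inverted_repeat` finds the maximal disjoint interval pair related
by reverse complement: exact 25-mer seed matches between the doubled
circle and its reverse complement are grouped on anti-diagonals and
extended outward under an X-drop rule (match +1, mismatch −2, stop 12
below the running maximum, roll back to the best point) with an overall
identity floor. X-drop extension, rather than a pure identity budget, is
what keeps a 27.5 kb repeat at 99% identity from dragging its boundary
into random flanking sequence. The longer single-copy arc is labeled LSC;
the repeat following it in forward orientation is IRa. These labels use
sequence arithmetic only — no gene evidence — which is the main difference
from annotation-driven conventions.

`expand_collapsed_ir` reverses the canonical assembly artifact in which
the two identical IR copies collapse into one contig: a scaffold laid out
as *(IR stub) + LSC + IR + SSC + (IR stub)* is completed by synthesizing
the second copy as the reverse complement of the internal one and joining
it through exact matches of the terminal stubs (at least `min_stub` bp,
default 100). IR boundary placements that differ only by bases shared
between a single-copy end and the repeat are inherently ambiguous from
sequence alone; all such placements produce the identical circle up to
rotation, so the round-trip collapse → expand → standardize is exact, and
the test suite asserts it sequence-identically over 100 seeded plastomes.

`standardize_plastome` rotates position 0 to the first LSC base after IRb
and fixes the strand either by a user anchor (the standard convention
starts the LSC with the reverse complement of a *trnH*-like anchor — gene
annotation being out of scope, the anchor is an explicit sequence
argument) or, deterministically, by the lexicographically smaller LSC.
The result is idempotent and invariant under any rotation or flip of the
input, which is what makes genome-to-genome comparison well defined.

## Mitogenome finishing

`iterative_extend_and_close` alternates two moves until fixpoint: merging
scaffolds whose ends overlap by at least `min_overlap` (100 bp) at ≥99%
identity, and extending ends by quality-voting consensus over overhangs of
reads anchored with at least `min_anchor` (50 bp) inside the end at depth
≥ `min_cov`. A single remaining sequence whose two ends overlap is closed
into a circle with the overlap deduplicated. An end with more than one
merge partner is reported as an error — a deliberate refusal to guess in
the situation (repeat-mediated three-way joins) where mitochondrial
assemblies most often go wrong.

`find_cp_like_regions` screens the finished mitogenome against the
plastome with BlastN (word size 25, e-value 1e−18, both strands) and keeps
hits of at least 100 bp and at least 90% identity, merging overlapping
hits on the mitogenome into regions. The e-value acts only as a guard; the
identity and length filters dominate. On simulated genomes with planted
inserts the recovered boundaries sit within a seed word of truth, and the
region fraction reproduces the planted ~2%.

`flag_cp_coverage_regions` implements the diagnostic that chloroplast-like
regions attract unspecific chloroplast reads when the unsubtracted pool is
mapped: any chloroplast-like region (and any other sufficiently long
interval) whose mean depth is at least `fold` (default 2) times the
genome-wide median is flagged.

## Variant calling and SNP statistics

`call_variants` tallies, per reference column, the bases with quality at
or above `min_base_quality` (20); a non-reference allele is called at
frequency ≥ `min_freq` (0.90) and counted depth ≥ `min_cov` (10). The 90%
frequency threshold encodes organelle biology: each organelle genome is
effectively haploid per individual, so true variants sit near 100% and
anything much lower is noise or compartment cross-talk. Adjacent called
SNV columns merge into a single MNV record; insertion and deletion
evidence passing the same thresholds becomes left-aligned InDel records.

`count_snp_positions` implements the counting rule used for density
statistics: every position covered by an SNV or MNV counts (an MNV of
length L contributes L), InDels do not. `snp_frequency` is
1000·count/length, rounded half-up to three decimals; on the published
organelle comparison counts this yields 0.378 SNPs/kb (chloroplast,
59 SNPs in 156,067 bp) versus 0.065 SNPs/kb (mitochondrion, 51 SNPs in
783,442 bp) — the nearly six-fold density contrast between the two
compartments.

## Comparative analysis

`variant_matrix` turns an aligned plastome set into a table of variable
columns (≥2 distinct symbols; the gap is a symbol, `N` is missing) on
1-based consensus coordinates; the consensus itself takes the most
frequent non-gap base per column with alphabetical tie-break, a documented
stand-in for unpublished tool behavior. Whether a multi-column gap is one
InDel or several is tool-dependent; this implementation counts per
alignment column and says so, which is the main reason exact position
totals from other pipelines are not directly comparable.

`group_specific_positions` is the whole-plastome barcode filter: a
position is retained when **every** allele carried by the target group is
absent from all non-target genomes. This strict reading also retains
positions where the non-targets jointly carry a derived allele — correct,
since the target's allele then still separates it. `window_scan` counts
variable positions in 10-kb windows on 1-based closed intervals
(1–10,000, 10,001–20,000, ...), ranked with ties to the earlier window.

## Phylogeny

`pairwise_distance` offers JC69 and K80 in closed form (checked in the
tests against an independent implementation), the paralinear/LogDet
determinant distance, and a GTR+Γ pairwise maximum-likelihood distance
with empirical exchangeabilities pooled across the alignment and four
discrete gamma categories of shape 1 — the fixed setting used for
whole-plastome trees. Saturated pairs yield flagged `NA` entries rather
than silent infinities.

`upgma_tree` is a deterministic UPGMA: size-weighted arithmetic-mean
linkage, heights halved into branch lengths, ties broken by the
lexicographically smallest pair of cluster labels. On any exactly
ultrametric input the output's cophenetic matrix equals the input; the
tests assert this exhaustively over every rooted topology with up to five
leaves. `bootstrap_support` resamples alignment columns, rebuilds the
tree, and scores each clade of the point tree as the percentage of
replicates containing it; replicates with a saturated pair are dropped and
the denominator adjusted. UPGMA's implicit molecular-clock rooting stands
in for outgroup handling; no separate outgroup option exists.

## What the simulators emulate — and what they do not

`gen_plastome` draws i.i.d. bases at a requested GC (default 36.76%) into
the default architecture LSC 84,367 bp + IRa 27,509 bp + SSC 16,670 bp +
IRb, a 156,055 bp circle. The bases flanking the repeats are adjusted so
the planted repeat pair is exactly maximal, making planted region lengths
a well-defined truth for detection tests. There is no gene structure, no
codon bias, and no compositional heterogeneity — annotation is out of
scope, and detection/standardization never use gene evidence.

`evolve_lineage` evolves an ancestor down a tree under an HKY-like scheme
(transition/transversion ratio 2, a sensible plastome-like bias), with
per-branch expected substitutions per site, indels at a rate expressed
per site per unit branch length (an indel-to-substitution ratio),
an optional hotspot multiplier, and clade-private planted alleles.
Three simplifications keep the truth alignment exact: indels and planted
sites avoid the IRs, inserted sequence does not mutate further down the
tree, and IRa edits are mirrored into IRb after simulation so the repeats
stay identical. The IR substitution rate is scaled down (default 0.25),
matching the several-fold lower substitution rates observed in real
plastome IRs; this is why simulated whole-plastome barcodes are sparse in
the repeats.

`simulate_aspen_panel` packages the comparative study design: nine
genomes, two of them a nearly identical target pair (~0.02% divergence,
the scale of two plastomes of the same species), seven diverged relatives
at 0.5–0.7% divergence, a 5-prime LSC hotspot (rate ×1.65 over the first
10 kb), and a planted barcode of 163 SNP-class plus 69 InDel-class
target-private sites. The stems of the target pair and of the remaining
clade are zero so the planted sites are the only target-specific alleles
by construction — which is what lets tests assert exact recovery. The
resulting panels carry roughly three thousand variable positions, the
scale at which real whole-plastome comparisons of this kind operate.

`simulate_reads` emulates paired 2×250 bp reads from ~550 bp fragments or
single-end reads with indel errors, at label-specific fold coverages over
circular genomes, with uniform substitution errors. Qualities are constant
Q30 with error positions written at Q12, so quality-aware steps have
signal to act on; real quality strings are of course not bimodal, and
passing tests therefore demonstrate threshold logic, not robustness to
realistic quality miscalibration. Other things deliberately not modeled:
GC-dependent coverage bias, chimeric reads, flow-cell artifacts,
heteroplasmy, and mitochondrial isomerization through repeat
recombination.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally (BED
  convention); VCF output and consensus/variant-matrix positions are
  1-based. Circular intervals may run past the sequence end and wrap.
* `snp_frequency` rounds half-up (not banker's rounding) to reproduce
  printed three-decimal densities.
* Coverage classification (`classify_by_coverage`) cuts the sorted log2
  mean coverages at the largest gaps into at most three tiers; boundaries
  are returned so the audit trail is explicit.
* The consensus quality-vote uses a lexicographic (quality sum, count)
  score; deletions lose full ties to bases.
* Mapping ties (identical identity) resolve to the leftmost start, then
  the forward strand — deterministic and documented, since multi-mapped
  IR reads depend on it.
* The scaffold merger requires an exact 31-mer at the overlap start; with
  ≥99%-identity overlaps of ≥100 bp this is essentially always available
  at organelle coverage.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run everything at full plastome
scale where the claim depends on it (156 kb genomes for IR detection,
round trips, and the 59-SNV variant-calling check at 50× / 0.5% error; a
nine-genome panel for the barcode cascade; 96 kb six-taxon alignments ×
100 seeds for topology recovery) and at reduced scale elsewhere (80 kb
mitogenomes — the full ~780 kb molecule is supported but not routinely
simulated; 12–20 kb circles for read-extension unit tests). The UPGMA
oracle check is exhaustive over all 123 rooted topologies with 3–5 leaves.

## Known limitations

* No gene annotation, so LSC/SSC orientation and the canonical start are
  sequence conventions (anchor or lexicographic), not the *trnH*-anchored
  convention of curated records; both are deterministic and
  interconvertible.
* The SSC of real plastid preparations exists in two orientation isomers;
  the package standardizes to one and does not model the mixture.
* `variant_matrix` counts InDels per alignment column, so its totals are
  not numerically interchangeable with pipelines that merge gap runs.
* The mapper is designed for high-coverage organelle data; it makes no
  attempt at mapping-quality modeling or paired-end rescue.
* UPGMA assumes clock-like evolution; for strongly rate-heterogeneous
  panels its topology can differ from likelihood methods, which are out
  of scope here.
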