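---
title: "Methods: tracking gene-family retention across paleopolyploidies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking gene-family retention across paleopolyploidies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`paleofam` reconstructs how a motif-defined super-gene family has been
retained, subfunctionalized and expanded across lineages whose genomes
carry different stacks of ancient whole-genome duplications (WGDs). This
vignette describes each model and procedure, its assumptions, the
parameters that matter, and the numerical choices made where the design
was genuinely open.

## Family identification

Extensins are operationally defined by two or more Ser-Pro₃ / Ser-Pro₄
(SP3/SP4) repeats in the protein sequence. Hydroxyproline is
post-translational, so genomic proteins carry plain proline and the scan
is run on P. `scan_sp_repeats()` counts **maximal** runs matching
`SP{3,}`: `"SPPPPPP"` is one unit, not several overlapping ones. The
rule is deterministic and conservative; since no overlap convention is
established for this motif, maximal-run counting is the one choice that
never double-counts.

Signature domains (e.g. the extensin-2 accession IPR006706) are ingested
from a TSV of pre-computed annotations and attached as metadata. By
default the motif alone decides membership — the field's identification
protocols scan motif hits *and then* label them with domains, leaving the
conjunction ambiguous — but `require_domain = TRUE` switches to the
stricter motif-AND-domain rule.

Tunable parameters: `min_repeats` (default 2 units; the definitional
threshold) and `require_domain` (default `FALSE`).

## Homology

All-against-all nucleotide comparison uses exact dynamic programming
(Smith–Waterman with affine gaps, via Biostrings) rather than heuristic
seeding: the inputs are gene-family scale, not genome scale. Two
conventions matter for reproducibility:

* **Identity** is identical columns divided by all alignment columns,
  *including* gap columns — the conservative reading of a "40% identity"
  threshold.
* **"Aligned over 300 bp"** is read strictly (> 300 columns).

Paralogs are within-species pairs passing both thresholds; paralog
*groups* are connected components of passing pairs. Orthologs are
reciprocal best hits (best hit = highest score, ties broken by identity,
then aligned length, then subject id — determinism matters because RBH is
order-sensitive otherwise) aligned over more than 300 bp.

The default scoring scheme (`scoring_scheme()`: match +1, mismatch −2,
gap open −5, extend −2) emulates a stringent BLASTN-style search. For
deeply diverged families this scheme sits at the edge of detectability:
at ~32% mismatch the expected per-column score turns negative and local
alignments fragment. The package's own simulated-study analyses therefore
use the sensitive scheme **match +1, mismatch −1, gap open −2, extend
−1**, which keeps homologs detectable out to the Ks ≈ 1.5–2 range where
the oldest events of interest live. E-values follow Karlin–Altschul
`E = K·m·n·exp(−λS)`; λ is solved from the ungapped characteristic
equation at uniform base composition (`karlin_lambda_ungapped()`) and
`K = 0.1` by default. These E-values are used as a *relative*
significance cutoff (the tandem-duplication rule), not as calibrated
database-search statistics.

## dN, dS and ω (Nei–Gojobori)

Protein pairs are aligned globally (BLOSUM62, gap open 2.0, gap extend
0.2 — penalties are per the affine rule `open + L·extend`), the alignment
is back-translated onto the CDSs (residue gaps become codon gaps;
translation is verified residue-by-residue and internal stops are
rejected), and dN/dS is estimated with the Nei–Gojobori (1986) counting
method:

* per-codon synonymous site fractions (each of the nine single-base
  changes contributes ⅓ site; stop-creating changes count as
  nonsynonymous), averaged over the two sequences;
* pathway averaging for multi-hit codons: unweighted mean over all
  orders of the differing positions, excluding pathways through stop
  codons unless every pathway is blocked;
* Jukes–Cantor correction `d = −¾·ln(1 − 4p/3)`, with `p ≥ ¾` flagged
  infinite; ω is defined only for finite, positive dS.

This estimator deliberately replaces ML codon models (codeml-style): it
is dependency-free, exactly reproducible, and checkable against a
brute-force pathway-enumeration oracle (which the test suite does on
1000+ random codon pairs). The cost is known bias at deep divergence:
the JC correction assumes a four-state site model, while two-fold
degenerate sites saturate at ½ identity rather than ¾, so NG86 dS
overshoots near saturation. Users comparing against ML estimates should
expect numerical differences, especially above dS ≈ 1.5.

Selection classes use a neutral band around ω = 1 (default half-width
0.1): purifying below, positive above. Purifying calls with ω > 0.9
carry a weak-evidence flag (only reachable with a narrower band).

## Median-Ks clustering and dating

Paralog-group history is reconstructed with the Blanc–Wolfe
agglomeration: every gene starts as a cluster; repeatedly merge the pair
of clusters with the smallest Ks, where the Ks between multi-member
clusters is the **median** over all cross pairs, and record that median
as the height of the merge. Numerical conventions:

* even-sized medians are the mean of the two middle values;
* undefined/infinite Ks entries are excluded from medians, and a step at
  which no cluster pair has any defined cross-Ks is an error (never a
  guess);
* ties for the smallest Ks merge the pair whose lexicographically
  smallest member sorts first (determinism; the procedure itself is
  silent on ties).

Node heights are Ks values; dates follow `T = Ks / (2λ)` with
λ = 1.5 × 10⁻⁸ synonymous substitutions/site/year, the standard
plant nuclear rate. Newick branch lengths are parent height minus child
height with leaves at height zero. Median linkage can invert (a child
higher than its parent); inversions are retained in the node table but
clamped to zero-length branches with a warning in the Newick output,
which keeps the string parseable by standard tree software.

## Collinear blocks and duplication mechanism

Genes duplicated by a WGD stay in conserved order, so within- and
cross-genome collinear ("syntenic") blocks identify WGD-derived
duplicates. The block finder chains homolog anchor pairs into maximal
runs that are strictly monotone in gene rank on both chromosomes (both
orientations tried), with consecutive anchors at most `max_rank_gap`
(default 10) ranks apart, keeps chains of at least `min_anchors`
(default 5), and assigns each anchor to at most one block
(longest-chain-first greedy; among equal-length chains the
lexicographically smallest anchor sequence wins, and the same orientation
beats inverted on length ties). These defaults are stand-ins for the
parameters of public synteny databases, which are not published;
pre-computed anchor or block tables can be ingested instead.

Since all anchors of a block duplicated simultaneously, the block
**median Ks** dates the event. Calibration intervals map medians to
events; the package ships the published Populus ranges (P-WGD
0.2437–0.3345, γ 1.2633–1.7896) and the Arabidopsis α range
(0.783–0.881), all user-overridable. Medians above a saturation
threshold (default 1.9) are labelled as indistinguishable ancient events
(the β/γ regime) rather than assigned.

Tandem duplicates are same-chromosome pairs within a 100-kb
start-to-start window (strand-agnostic — only the window is specified in
the field's rule) whose alignment E-value is ≤ 10⁻²⁵. Mechanism
classification is exhaustive and exclusive with precedence
**SWGD > TD > OTHER**: block membership is stronger positional evidence
than proximity.

## Retention matrix

Ancestral loci are the connected components of genes linked by block
anchors (within plus between species); family members in no block form
singleton loci. For each locus and species, slots are scored `E`
(retained member), `N` (present but classifier-negative:
subfunctionalized), `L` (a chromosome is covered by a block spanning the
locus but carries no gene of it: gene lost, block retained) or `B` (no
block evidence: block lost). The number of slots is the expected copy
multiplicity (product of 2 per duplication, 3 per triplication since the
common baseline), extended when extra genes (tandem copies) are present.

Loss evidence uses expected-slot interpolation: a block's span on each
side is the rank interval of its anchors, extended by `span_slack`
(default: the chaining `max_rank_gap`) — a gene within that distance of
the block terminus would have been chained had it survived, so its
absence is evidence of loss rather than of a missing block. How the
original analyses separated "gene lost, block retained" from annotation
gaps is not described anywhere; this interpolation is the package's
explicit, testable answer.

## The simulator

`simulate_dataset()` is a forward simulator of a gene family along a
lineage tree, built so that every pipeline stage has a ground truth:

* **Events.** At each WGD (triplication), every chromosome is copied
  wholesale — so true collinear blocks exist by construction — and each
  new duplicate is independently retained (`p_retain`), subfunctionalized
  (`p_subfun`; the serine of every repeat unit is substituted, taking the
  motif count to zero) or lost. Tandem duplications arrive per gene at
  rate `td_rate`/year and insert a copy within `td_offset` bp; ongoing
  loss at `loss_rate`/year. Triplication adds two simultaneous copies,
  mirroring paleohexaploidy's 3:1 multiplicity.
* **Sequences.** Substitutions run as a continuous-time (Gillespie)
  process per gene: synonymous changes at rate λ per synonymous site,
  nonsynonymous at ωλ (defaults λ = 1.5 × 10⁻⁸/site/year, ω = 0.15, the
  family-wide purifying-selection average). Synonymous sites are
  recomputed per current codon after every substitution, matching NG86's
  assumptions. Stop-creating changes are treated as lethal and excluded.
  The defining motif of retained genes evolves only synonymously —
  strong site-specific purifying selection on the family-defining
  residues — which makes subfunctionalization the only motif-destroying
  process and keeps the truth log's member/non-member states exact.
* **Founder codons** are drawn from four-fold degenerate codon boxes
  (filler amino acids A, G, T, V, L, S, R; the motif uses TCN serine and
  CCN proline). This matters: with uniformly drawn codons, two-fold
  degenerate sites saturate at ½ identity while the Jukes–Cantor
  correction assumes ¾, and NG86 dS overshoots badly at deep divergence
  (at true Ks 1.5, estimates approach 2.2). Four-fold founder sites
  satisfy the JC site model, so the estimator the simulator is meant to
  validate is approximately unbiased over the simulated range.
* **Truth log.** Every gene ever created gets a row (parent, birth
  event, birth time, fate); divergence times and true mechanisms for all
  surviving same-locus pairs are derived from the genealogy, and the
  anchor table carries true Ks = 2λt.

**Default study conditions.** Three lineages: the stem begins 60 My ago
with 24 ancestral loci; a shared WGD at 50 My on the stem; lineage C
splits at 45 My; A and B split at 30 My; an A-specific WGD at 10 My
(expected multiplicities 4:2:2). Genes are 300 codons with 4 motif
units, spaced 20 kb apart. Fate probabilities at each duplication are
0.55 retained / 0.25 subfunctionalized / 0.20 lost — no published loss
rates exist for this family, so these are chosen once for test power
(enough losses to exercise the `L`/`B` states, enough retention that
blocks stay detectable); `td_rate` = 10⁻⁹/gene/year yields a handful of
tandem events per run; `loss_rate` defaults to 0 so all loss is tied to
duplications and the truth states stay crisp. The splits are kept inside
60 My because beyond Ks ≈ 2.4 synonymous saturation defeats *any*
nucleotide-level homology search, which is the search the pipeline (like
the field's BLASTN protocol) performs.

**What the simulator does not emulate**: no indels (alignments are
structurally trivial; the aligner is exercised separately against DP
oracles), no rate heterogeneity among sites or lineages, no gene
conversion, no transposable elements, no chromosome fission/fusion, and
no expression-level subfunctionalization — motif destruction is the only
observable the classifier can see, which is exactly what the pipeline
measures. Passing the recovery tests therefore shows the pipeline is
correct *under its own model assumptions*; on real genomes, annotation
error, rate variation and rearrangement will add noise these tests do
not probe.

## Problem sizes and reproducibility

The test suite and worked examples run at desk scale: the default
simulation tracks ~160 surviving genes across three lineages
(~13,000 pairwise local alignments, a few hundred NG86 estimates),
which completes in minutes on one core. Oracle comparisons use
1000+ random codon pairs (NG86), dozens of random ≤ 20-anchor instances
(chaining) and random 8-gene matrices (clustering). Every stochastic
stage takes an explicit seed; pipeline runs are pure functions of inputs
and settings, verified by byte-identical double runs.

## Known limitations

* NG86 + JC is biased upward near synonymous saturation; the β/γ regime
  (Ks ≳ 1.9) is labelled, not resolved.
* E-values are approximate (ungapped λ, nominal K) and should only be
  used as relative cutoffs, as the tandem rule does.
* The collinearity defaults are stand-ins for undocumented database
  parameters; block inventories on real genomes will differ from
  published ones.
* One sequence per gene is assumed throughout: callers must pre-select a
  representative isoform.
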