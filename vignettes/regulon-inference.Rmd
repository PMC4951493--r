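---
title: "Comparative inference of bacterial transcription-factor regulons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative inference of bacterial transcription-factor regulons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonscout)
```

# The problem

A bacterial transcription factor (TF) such as the SOS-response repressor
LexA recognizes a short, often palindromic DNA motif in the promoters of
the genes it controls. The motif itself diverges between phyla: LexA binds
`GAAC-N4-GTTC` in Firmicutes and Actinobacteria, `CTGT-N8-ACAG` in
Gammaproteobacteria, the direct repeat `GTTC-N7-GTTC` in
Alphaproteobacteria, and the 14 bp dyad `TGTTC-N4-GAACA` in
Verrucomicrobia. Given annotated genome assemblies, a TF protein and a
binding motif (known, or discovered de novo from ortholog promoters),
`regulonscout` reconstructs the TF's regulon across a set of species:
which operons carry credible binding sites, in which genomes, and how the
pattern of conservation distributes over the TF's own phylogeny. A
synthetic-community generator with full ground truth makes every stage of
the pipeline testable end-to-end without touching external databases.

# The motif model and Ri scoring

A motif is estimated from `N` aligned sites of width `W`. With background
`q(b)` and pseudocount `c`, column frequencies are

    f(b, l) = (n(b, l) + c * q(b)) / (N + c)

and the per-position weights are individual-information weights

    Riw(b, l) = 2 + log2 f(b, l)   [bits],

so a candidate site scores `Ri = sum_l Riw(seq_l, l)`. The consensus
sequence attains the maximum achievable score; an uninformative column
contributes 0 bits for every base. Scanning evaluates every window on both
strands; for a palindromic motif (count matrix equal to its own reverse
complement) the two strands score identically at each position and a
physical site is reported once, with the plus strand as representative.
Ambiguous bases (`N`) in scanned sequences take the column-average weight,
so draft assemblies degrade scores gracefully instead of erroring.

Schneider's small-sample correction `e(n)` is not applied: the pseudocount
already regularizes small site collections, and the downstream comparisons
(matrix normalization, thresholds expressed as fractions of the maximum
score) are invariant to a constant per-column offset.

`motif_from_consensus()` builds an exact-frequency model from an IUPAC
consensus: a fully specified column receives the consensus base frequency
that yields a requested information content (`2 + sum f log2 f` under a
uniform background), and `N` columns are exactly uniform. Throughout this
package "bits per column" means this column information content — the
quantity a sequence logo draws — not the consensus weight `Riw`.

# De novo discovery: palindromic ZOOPS EM

The discovery stage replaces an external motif finder with an
expectation–maximization algorithm over the ZOOPS model (zero or one
occurrence per sequence). Each sequence carries a site with probability
`gamma` at a position and strand uniform over its windows; non-site
positions follow a 0-order background estimated from the input. The E-step
computes posterior window responsibilities; the M-step re-estimates
frequencies from expected counts (with a small Dirichlet pseudocount,
0.25 by default) and updates `gamma`. The palindromic constraint is the
maximum-likelihood M-step under `f(b, l) = f(comp(b), W+1-l)`: the expected
count matrix is averaged with its own reverse complement after every
update. The observed-data log-likelihood ratio against the
background-only model is therefore non-decreasing across iterations, which
the test suite asserts per iteration.

Width selection scans `w_min..w_max` (8–20 by default, the conventional
range for palindromic dyad motifs). For each width the EM is started from
seed W-mers — the most frequent words in the input (pooling reverse
complements) plus random restarts drawn under the caller's RNG seed; short
runs (15 iterations) rank the starts and the best three are refined to
convergence (`tol` 1e-6, `max_iter` 200). Models are compared by a
BIC-penalized log-likelihood ratio,

    significance = -2 * LLR + k * ln(total windows),

with `k = 3*ceil(W/2) + 1` free parameters for a palindromic motif
(`3W + 1` otherwise); lower is better, and a fit is flagged significant
only when the penalized score is negative. The BIC penalty is what stops a
wider window that merely appends background columns from beating the true
width: the extra columns add almost no likelihood but cost
`3 ln(T)` each. An E-value in the style of dedicated motif suites is not
computed; BIC gives the same ranking between separated and random signals
and is directly checkable against a control run.

# Operons and the regulon pipeline

Operon prediction uses the intergenic-distance rule: directons (maximal
runs of same-strand consecutive genes) are split wherever the distance to
the next gene, `start(next) - end(prev)`, is not strictly below the
genome's mean intergenic distance. The mean is taken over **all** adjacent
gene pairs, overlaps (negative distances) included — the simplest
self-contained calibration, recomputed per genome. Promoter windows are
`[-250, +50)` around the translational start site (TLS) for the regulon
search and `[-250, 0)` for discovery; both windows are parameters because
the two conventions serve different purposes (discovery wants no coding
sequence, scoring wants to catch sites that straddle the start). On the
minus strand the window mirrors the plus-strand definition in reading
orientation; windows clamp at contig edges.

Sites are searched in the promoter of each operon's lead gene and assigned
to all members. Revision then corrects over-merged operons: a non-lead
member whose own `[-250, +50)` window contains a site scoring at least
0.75 of the motif's maximum becomes the lead of a new operon (splits are
applied left-to-right, one per operon per pass, to a fixpoint). The 0.75
fraction is a declared default — comparative-regulon pipelines leave
"high-scoring" unquantified — and sits above the membership-calling
threshold so that revision demands stronger evidence than membership.
Merging operons across large gaps on comparative evidence (the
*lexA-imuA-imuB-dnaE2* situation, where a conserved arrangement argues for
an operon despite an above-average gap) is deliberately manual: the matrix
is built from the automatic predictions, and a user can supply
pre-assembled operon sets instead.

The comparative matrix anchors one ortholog group per reference gene:
members are reciprocal best hits (RBH) of the anchor, a star topology with
no transitive closure, which keeps group membership unambiguous. Cells
hold the best raw promoter score of the operon containing the ortholog
(`NA` when the species lacks an ortholog; the scan threshold only gates
exported site lists, never the matrix). Scores are normalized to `[0, 1]`
over all non-absent cells of the whole analysis, so the best cell of the
analysis is exactly 1 and the worst exactly 0. Species columns follow the
leaf order of a distance-based TF tree: pairwise local-alignment
identities of the TF proteins converted to distances `1 - id/100` and
joined by neighbor joining (negative branches clamped to 0). Building the
tree from pairwise identities rather than a multiple alignment is a
declared simplification: it preserves the "distance-based clustering"
semantics without an MSA engine. Species whose genome lacks a TF ortholog
are excluded from the tree and flagged, mirroring lineages that have lost
the regulator.

Regulon membership calls use a threshold of 0.6 x the maximum achievable
motif score. For a sharply conserved 10-informative-position dyad this
accepts a site with one substituted arm position while rejecting
essentially all chance matches in a 300 bp window; it sits between the
0-bit site-listing floor and the 0.75 revision fraction.

# Protein comparison

Orthology uses optimal local alignment (Smith–Waterman, BLOSUM62, gap
open 11 / extend 1) with Karlin–Altschul expect values
`E = K m n exp(-lambda S)` using the standard gapped constants
`lambda = 0.267`, `K = 0.041` on the raw search space `m*n` (no effective
length correction, no composition-based statistics — declared
simplifications relative to a full search engine). RBH pairs require both
partners to be each other's unique best hit at `E <= 1e-20`, the
conservative threshold conventional for cross-species ortholog calls; ties
on the best score yield no pair.

# Tandem sites and junction motifs

Dyad-binding repressors frequently occupy two closely spaced (1–10 bp)
tandem sites in their own promoter. `find_tandem_sites()` reports
same-orientation hit pairs with gaps up to 10 bp, with a deliberately
permissive secondary-score threshold because the downstream site is often
degenerate. The junction of two tandem sites can itself constitute an
instance of a *different* known dyad motif: for two `TGTTC-N4-GAACA`
consensus sites separated by `g` bp, the downstream arm of the first site
(`GAAC`) and the upstream arm of the second (`GTTC`) form
`GAAC-Nk-GTTC` with `k = g + 2` (one trailing base of the first site's
arm, the `g` gap bases and one leading base of the second site). Junction
matching uses guaranteed-instance semantics: a degenerate junction
position matches a pattern position only if the pattern covers all its
realizations, so a reported instance follows from the conserved positions
alone and not from luck in the spacer. The evolutionary dynamics built on
this observation (duplication, divergence, takeover of the regulon by a
second TF copy) are not simulated; only the combinatorial site-generation
fact is implemented, and it is checked exhaustively over gaps 0–10 and
spacers 0–12.

# The synthetic community generator

`generate_community()` is the test substrate for everything else. What it
emulates, and the defaults it fixes:

* **Species**: 3 genomes diverged along a random tree with exponential
  branch lengths (mean 0.05 substitutions/site). Proteins evolve by
  independent per-site substitution (probability `1 - exp(-rate)`,
  replacements drawn from BLOSUM62-conditional frequencies), which is
  adequate because only alignment identity, RBH behaviour and tree shape
  are consumed downstream.
* **Genomes**: 45 gene families per genome on one contig; shared gene
  order across species (gaps redrawn per species); coding sequences are
  uniform-synonymous reverse translations of the family proteins.
* **Operons**: unregulated families grouped into operons of size 1–4
  (probabilities 0.30/0.30/0.25/0.15); the regulon contributes *lexA*,
  *recA* and the three-gene *imuA-imuB-dnaE2* cassette — the minimal
  shared SOS core — as three more operons, in every species.
* **Intergenic model**: within-operon gaps Geom(mean 20) bp;
  between-operon gaps `150 + Geom(mean 50)` bp (mean 200). The offset
  makes the intergenic distribution genuinely bimodal — between-operon
  regions must at least house a promoter and a terminator — and keeps the
  between-operon mode separated from the genome mean so that the
  mean-threshold operon rule is testable; the margin matters because the
  enlarged regulated-promoter gaps themselves inflate the genome mean to
  roughly 120 bp. Two plain geometric components would both peak at zero
  and systematically contradict the bimodality the pipeline assumes.
* **Sites**: sampled column-wise from the motif model (default
  `TGTTC-N4-GAACA` at 1.8 bits per arm column, uniform spacer) and planted
  uniformly in `[-200, -20]` of the lead gene's TLS, so sites always fall
  inside both the discovery and the search windows. The gap 5' of a
  regulated operon is drawn large enough (>= 220 bp) that the placement
  window is fully intergenic and planted sites never overwrite coding
  sequence; when the neighbour across that gap transcribes divergently —
  so that its own promoter window shares the gap — the gap is enlarged
  (>= 470 bp) so the planted site cannot sit inside the neighbour's
  window. A palindromic operator in a shared divergent intergenic region
  is genuinely visible from both promoters; the generator keeps regulated
  and unregulated promoters physically separated so that the planted
  truth stays unambiguous.
  A configurable fraction of regulated promoters (default 0.25) receives a
  second site in tandem at a 1–2 bp gap.
* **Background**: i.i.d. DNA at configurable GC (default 0.5). No
  repeats, rearrangements or horizontal transfer — the pipeline under
  test assumes none, so passing tests say nothing about such genomes.

Everything is deterministic given the seed, and the truth tables record
every planted site, operon membership, family assignment and regulon
membership.

What passing end-to-end tests on this substrate shows: the pipeline's
logic (windows, operon rule, revision, orthology plumbing, normalization)
recovers what was planted under the stated statistical assumptions. What
it does not show: robustness to misannotation, pseudogenes, repeats,
skewed codon usage, assembly fragmentation, or motif models whose
information lies outside the arms — real-data behaviour must be judged
separately.

# Numerical choices and degenerate inputs

* Ties in scan hits resolve to the 5'-most position (reading
  orientation); ties for the best alignment hit void an RBH pair; ties in
  consensus columns produce IUPAC degeneracy codes.
* A promoter window fully clamped away (gene at a contig edge) yields no
  best hit, and such cells stay `NA`-like rather than 0.
* Normalization with a single distinct score maps everything to 1.
* `uniroot` solves consensus-column frequencies to 1e-12; palindromy and
  frequency-sum invariants are checked at 1e-9.
* EM stops on an expected-log-likelihood improvement below 1e-6 or 200
  iterations; `gamma` is clamped to `[1e-6, 1-1e-6]`.
* Geometric draws use `p = 1/(1+mean)` so the stated means are exact.

# Problem sizes used by the shipped tests

The test suite and the acceptance script run entirely on generated data:
30 promoters of 250 bp for the discovery benchmark (full 8–20 width scan,
20 seeds); 20 promoters and a 12–16 scan for the repeated-recovery
property (10 trials, 12 seeds per width); 100 random toy genomes for each
brute-force comparison; and ten 3-species communities of 45 genes per
genome for the end-to-end precision/recall benchmark. These sizes are the
package's own choice of a benchmark that a laptop reruns comfortably while
leaving the planted signal at realistic strength.

# Known limitations

* The Ri model is a 0-order independent-column model; no dinucleotide
  background, no binding-energy calibration.
* One motif per discovery run (ZOOPS); no multiple-motif decomposition.
* BLAST statistics are approximated (fixed gapped constants, raw search
  space); absolute E-values near a threshold may differ from a full
  search engine even though rankings agree.
* Ortholog groups are reference-anchored stars; lineage-specific
  expansions outside the reference are invisible by design.
* Operon revision only splits; it never merges across large gaps (that
  correction is left to explicit user overrides).
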