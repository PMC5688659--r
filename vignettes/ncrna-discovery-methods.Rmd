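---
title: "Methods: hairpin statistics, coding-potential cascades and target scoring in ncRNAscout"
author: "ncRNAscout maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hairpin statistics, coding-potential cascades and target scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncRNAscout)
```

# Scope

ncRNAscout annotates three classes of plant non-coding RNA from sequence
alone: pre-miRNA hairpins (homology to known matures plus folding and
repeat statistics), long non-coding RNAs (a coding-potential filter
cascade), and miRNA target sites on coding transcripts and lncRNAs
(complementarity scoring with site accessibility). Because the real inputs
for a genome-scale study (a draft genome, a mature miRNA database, a
transcriptome assembly, protein databases) are external resources, the
package also ships seeded synthetic generators that emulate their
statistical structure with planted ground truth, so every pipeline can be
run and scored end to end in seconds to minutes.

# The folding engine and its energy model

All folding statistics derive from one engine: a Nussinov-style dynamic
program for the minimum free energy (MFE) structure and a McCaskill-style
inside–outside recursion for the Boltzmann ensemble. The energy model is
deliberately *additive per pair*: G:C = −3.0, A:U = −2.0, G:U = −1.0
kcal/mol, a minimum hairpin loop of 3 unpaired bases, RT = 0.6163 kcal/mol
(310.15 K), no stacking or loop terms. Two considerations drove this
choice over a full nearest-neighbor parameterization:

* **Certifiability.** With an additive model the package can enumerate
  *every* secondary structure of a short RNA (`enumerateStructures()`) and
  check the dynamic programming against direct summation — MFE, the
  partition function `Z`, and every pair probability `p_ij` agree with the
  enumeration to `1e-9` relative error in the test suite. A
  nearest-neighbor oracle of that strictness would itself be a large,
  error-prone artifact.
* **Model-agnostic formulas.** Every downstream statistic — MFEI, AMFE,
  NQ, ND, Npb, UPE — is a functional of (MFE, `p_ij`) only. Swapping in a
  different folding engine changes absolute values but not the formulas,
  which is why all filter thresholds are explicit configuration rather
  than constants.

The ensemble is the standard Boltzmann one: each pseudoknot-free structure
$S_\alpha$ has probability
$P(S_\alpha) = e^{-E_\alpha/RT} / \sum_\beta e^{-E_\beta/RT}$, and
$p_{ij} = \sum_\alpha P(S_\alpha)\,\delta_{ij}$ with $\delta_{ij}$
indicating that $i$ pairs $j$ in $S_\alpha$. Numerically the inside and
outside tables are rescaled per nucleotide by
$s = \exp(-\mathrm{MFE}/(RT\,L)) \times 1.4$, which keeps 400-nt folds
finite in double precision without log-space arithmetic in the inner
loops; probabilities are ratios in which the scale cancels exactly. The
open chain contributes weight 1 at E = 0, so $\log Z \ge 0$ always. MFE
ties are broken deterministically (fewer pairs, then leftmost pairs), so
repeated runs are bit-identical.

Degenerate inputs: ambiguous bases are an error at the folding layer, and
any candidate genome window containing N is discarded before folding —
folding statistics are undefined for ambiguous bases. Sequences shorter
than `minLoop + 2` simply have an empty ensemble (Z = 1).

# Hairpin statistics

For a candidate window of length $L$ with GC percentage on the 0–100
scale:

* $\mathrm{AMFE} = -\mathrm{MFE}/L \times 100$ (positive for stabilizing
  folds),
* $\mathrm{MFEI} = \mathrm{AMFE}/(G+C)\%$,
* $NQ = -(1/L)\sum_{i<j} p_{ij}\log_2 p_{ij}$ (ensemble entropy, bits per
  nucleotide),
* $ND = (1/L)\sum_{i<j} p_{ij}(1-p_{ij})$ (ensemble base-pair diversity),
* $Npb$ = pairs in the MFE structure per nucleotide, bounded by 0.5 and
  computed on the MFE structure — the single structure the pipeline
  produces,
* $R$ = SSR signature occurrences per 100 nt.

The sums in NQ and ND run over $i<j$ and are normalized by $L$, exactly as
their defining formulas state; some of the wider literature
normalizes entropy by the number of pairs instead, and that variant is
deliberately not implemented. MFEI is undefined at GC = 0; such candidates
are flagged and rejected rather than scored.

# SSR signatures

`findSSRs()` reports maximal primitive tandem repeats of period 1–6. A
tract is reported at its leftmost phase; "AUA"-phased and "UAA"-phased
renderings of one tract are therefore a single occurrence, and motif
matching against signature sets reduces both motifs to the
lexicographically smallest rotation. Tabulation (`tabulateFamilySignatures`)
keys motifs as first encountered, because published signature tables list
rotation-distinct triplets. Minimum repeat counts default to 5 (period 1),
3 (period 2) and 2 (periods 3–6) — conventional microsatellite-survey
minima; the defining sources do not state thresholds, so these are
configuration. Signature sets themselves are corpus-derived: the packaged
default is generated from the synthetic corpus (the published per-family
sets live in an inaccessible supplement), and a user-supplied TSV
overrides it. "Window size of three" is read as *signatures are
trinucleotide motifs*, matching the triplet layout of published signature
tables; the alternative reading (longer-period SSRs scanned in 3-nt
windows) was considered and rejected.

# The pre-miRNA pipeline

1. **Homology scan.** Every ungapped occurrence of every known mature on
   both strands with at most 3 substitutions, found exhaustively
   (`Biostrings::matchPattern`); at ~21 nt and ≤3 mismatches a heuristic
   aligner is a lossy surrogate for exactly this computation, so the exact
   scan is the implementation and an external tabular hit list is merely
   an input option. Identical-coordinate hits from different matures
   collapse to one locus keeping the lowest-mismatch query.
2. **Window ladder.** Total lengths 60–300 nt in steps of 20, mature on
   the 5′ or 3′ arm, clipped at chromosome ends; minus-strand hits are
   reverse-complemented into sense. The ladder spans the plant pre-miRNA
   length range and is configuration.
3. **Coding exclusion.** With a protein database: six-frame local
   alignment (BLOSUM62, gap 11/1) with approximate Karlin–Altschul
   E-values; without: an ORF heuristic (default ≥ 80 aa removes the
   window; at that setting the false-removal rate on random 250-nt windows
   is under 5 %).
4. **Filter cascade.** Composition, MFEI, NQ, ND, Npb, R and a hairpin-
   placement check (no base of the mature may pair with another mature
   base, i.e. the mature sits on one helical arm and does not straddle the
   loop). Each filter records a verdict for audit.
5. **Best-candidate retention.** Among passing windows of one hit: maximum
   MFEI, ties by maximum R, then shortest window, then leftmost — the
   first two criteria are the published retention rule, the last two make
   it deterministic.
6. **Naming.** Family inherited from the best-matching mature, letter
   suffixes in genomic order, novelty flagged when no 0-mismatch match to
   the known library exists.

## Threshold calibration

Published cutoff values for these statistics are engine-specific and, for
the family-signature pipelines this package follows, largely unavailable in
reusable form. The shipped defaults
were therefore calibrated **once** on the packaged synthetic corpus under
the built-in model, by inspecting feature distributions of planted
hairpins (0–1 stem mismatches, 8-nt loops, window plus 20 nt of
background) against dinucleotide-shuffled decoys of the same windows:
MFEI ≥ 1.5, NQ ≤ 0.5 bits/nt, ND ≤ 0.16, Npb ∈ [0.30, 0.50], R ≥ 0
(ranking-only by default), broad composition bands. At these values the
single-window cascade separates planted hairpins from shuffled decoys at
≥ 0.9 sensitivity and ≥ 0.9 specificity; `defaultFilterThresholds()`
documents them as calibrated, not published, values. Under a
nearest-neighbor engine the MFEI threshold would sit near the literature's
0.85; under the additive model all energies are larger in magnitude, which
is why the calibrated value is higher.

# The lncRNA pipeline

Stage order is fixed: length > 200 nt (strict), longest ORF < 120 aa
(strict, start-to-stop ORFs over six frames), primary coding score with
class boundaries S ≤ −0.5 (non-coding), S ≥ 1.0 (coding, discarded),
neutral otherwise; neutral transcripts are re-examined by a secondary
score and kept as ncRNA when it is < 0.2; finally transcripts whose six-
frame translation aligns to a protein database at e ≤ 0.001 with more than
40 % identity (strict) are removed. All four boundaries carry
two-sided tests. The strict readings of "greater than 200" and "less than
120" are the literal ones; both are configuration.

The built-in scorer is *a calibrated stand-in, not a reimplementation* of
any external coding-potential program: ORF coverage, in-frame hexamer
log-likelihood ratios and Fickett-style positional asymmetries feed two
logistic models; the primary log-odds are affinely mapped so that training
coding transcripts score ≥ 1.0 and training non-coding ones ≤ −0.5 at
≥ 90 % rate (the mapping anchors the 10th/90th training quantiles to those
boundaries). External program outputs can be supplied instead as two-
column id→score tables wherever a scorer is accepted. The ORF definition
is start-to-stop rather than getorf's stop-to-stop — the conservative and
more common convention; it is configurable via `requireStart`.

# Target prediction

The expectation score sums penalties over the antiparallel duplex of the
mature (5′→3′) against the site: mismatch 1.0, G:U wobble 0.5, bulge 2.0,
all doubled within the core region (mature positions 2–13, rescaled
proportionally below 15 nt). These constants follow the penalty system popularized by the standard
plant target-prediction servers; all are configuration. Sites are every transcript window whose best
gapless-or-one-bulge alignment scores at or below the cutoff (default
2.0); overlapping windows collapse to local minima of the expectation. At
most one bulge per duplex is allowed — it keeps the exhaustive window
oracle exact, and plant duplexes with two or more bulges essentially never
pass an expectation of 2. The cleavage/translation call examines the
central mature positions 9–11, rescaled as `round(9L/21)`…`round(11L/21)`
for other lengths: any non-Watson-Crick pair or adjacent bulge there means
translational inhibition.

Site accessibility is the unpairing energy
$\mathrm{UPE} = E_{\mathrm{constrained}} - E_{\mathrm{unconstrained}}$,
folding the site plus 17 nt upstream and 13 nt downstream (clipped at
transcript ends) with the site forced single-stranded in the constrained
pass. Sites above 25 kcal are discarded. The 25 kcal default is the
published cutoff; absolute energies are engine-dependent, and under the
built-in model planted sites in random 500-nt transcripts fall at
UPE ≈ 12–22, comfortably inside the default.

# Synthetic data: what it emulates and what it does not

The generators define the study conditions for all packaged benchmarks:

* `makeGenome()` — i.i.d. background at GC 0.5, two 10-kb chromosomes, 10
  planted hairpins (mature + 8-nt loop + near-complement arm, 0–1 stem
  mismatches, family SSR motif tiled into the loop, random strand) and 10
  decoys: dinucleotide-shuffled precursors and matures mutated to 4–6
  substitutions, straddling the 3-mismatch scan boundary from the wrong
  side.
* `makeTranscriptome()` — coding transcripts are a codon-biased ORF of
  150–250 aa inside random UTRs (500–1200 nt total) with translated
  proteins emitted as the companion database; non-coding negatives are
  exact-count dinucleotide shuffles (Altschul–Erickson-style Eulerian-path
  shuffle) of the coding set — composition-matched, which is the minimum
  honest difficulty for a coding-potential scorer.
* `plantTargetSites()` — reverse-complement sites mutated to designed
  penalties (0 and 1 as positives, 4 as negatives beyond the 2.0 cutoff).
* Mature libraries draw lengths from 18–24 nt with weights chosen to
  emulate the plant-typical distribution (mode 20–21, ~93 % within 18–22,
  mean ≈ 20).

A planted hairpin exposes **two** genuine loci to a homology scan — the 3′
arm is a near-reverse-complement of the mature, so it matches on the minus
strand. Benchmark scoring therefore counts an accepted locus as true when
its mature anchor falls inside a planted precursor footprint (± 5 nt); the
window-ladder quantization (steps of 20 nt) makes window *endpoints* the
wrong unit for a ± 5 nt criterion, while the mature anchor is exact.

What the synthetic corpus does **not** model: repeat landscapes and
segmental duplications, transcript splice isoforms, sequencing error, GC
heterogeneity along chromosomes, paralogous mature families with near-
identical members, and nearest-neighbor folding energetics. Passing the
packaged benchmarks therefore certifies the pipeline's logic, boundaries
and bookkeeping — not field performance on real genomes, where thresholds
must be recalibrated against a production folding engine.

# Benchmarks and problem sizes

The packaged benchmark conditions (also used by `scripts/acceptance.R`)
are: 2 × 10 kb genome with 10 planted / 10 decoy elements for the
pre-miRNA pipeline; 60 + 60 training and 40 + 40 held-out transcripts for
the lncRNA pipeline; 6 matures × 12 transcripts of 800 nt with 12 designed
edges for targets. These sizes keep a full run in a few minutes on one
core while leaving every recovery metric statistically meaningful at the
0.9 thresholds; all are parameters, and nothing in the code depends on
them.

# Known limitations

* Additive energies compress the dynamic range between strong and weak
  hairpins; the MFEI/NQ/ND thresholds shipped here must not be compared
  numerically to nearest-neighbor-based literature values.
* The Karlin–Altschul E-values of the built-in protein aligner use fixed
  gapped BLOSUM62 parameters and are approximate; the external tabular
  adapter is preferred at scale.
* The homology scan is exhaustive and linear — appropriate to desk-scale
  genomes (tens of Mb), not to chromosome-scale assemblies with repeat
  masking needs.
* lncRNA sub-classification (intergenic / antisense / intronic),
  expression support, and degradome validation of targets are out of
  scope.
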