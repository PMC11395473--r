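---
title: "Screening promoters for master regulatory transcription factors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening promoters for master regulatory transcription factors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

masterscan asks a simple regulatory-genomics question: which transcription
factors (TFs) have predicted binding sites in the promoters of *every* gene
of a pathway group? A TF satisfying that intersection rule for, say, the
salicylic-acid biosynthesis genes is a candidate "master regulator" of that
pathway — the kind of factor (DOF, AHL, ERF family members in plants) that
can coordinate a whole hormonal response to a priming stimulus. The package
implements the full chain needed to ask the question reproducibly: promoter
window extraction, exact-p-value PWM scanning, intersection screening,
binding-region accounting, and a replicate-free differential-expression
layer that says whether the candidate masters actually moved after
treatment.

## Promoter windows

Windows are anchored on the transcription start site (TSS) and span
`upstream = 5000` bases before it and `downstream = 1000` bases from it
onward by default. The TSS is relative coordinate **+1**; there is no
position 0, upstream positions are negative, so the default window is the
familiar −5000..+1000. Minus-strand genes are reverse-complemented so the
TSS always reads left→right at +1, and the relative→absolute mapping is a
strand-consistent bijection (property-tested by round-trip). BED input is
treated as 0-based half-open, GFF3 as 1-based closed; both normalize to the
same 1-based TSS. Windows overlapping a contig end are truncated rather
than N-padded — padding would manufacture artifactual non-sites — and the
truncation is flagged. `N` bases are kept in the window; the scanner skips
any offset whose L-mer contains one, because no defensible score exists for
it.

## PWM scores and exact p-values

A position frequency matrix (counts) becomes a position weight matrix by
pseudocounted log-odds against an order-0 (i.i.d.) background:

$$w(i,b) = \log_2 \frac{(n_{i,b} + c\,\pi_b)/(N_i + c)}{\pi_b},$$

with total pseudocount $c = 1$ per column shared proportionally to the
background $\pi$ (a common JASPAR-tooling default). Every column then
satisfies $\sum_b \pi_b 2^{w(i,b)} = 1$, which the tests assert. A site's
score is the sum of its per-position weights, in bits.

The p-value of a score is computed **exactly**, not by sampling: weights
are discretized to integer units (1000 units per bit, round-half-even) and
the full distribution of the total score over random background sequence is
built by positionwise convolution — after column $i$,
$P(s) = \sum_b \pi_b P_{\text{prev}}(s - \hat w_{i,b})$ — followed by a
suffix sum for the tail $P(\text{score} \ge s)$. Scanning then reports
every offset with $p < 10^{-4}$, the stringency this kind of screen uses.
Because the scanner scores sites on the same integer grid, the reported
p-values are exact statements about the discretized score; the test suite
compares the DP tail against brute-force enumeration of all $4^L$
sequences (identically discretized) and requires agreement to 1e−9.
At 1000 units/bit the discretization error on the score itself is below
0.0005 bits per position; the scale is configurable (minimum 100).

Design choices worth stating:

* **Background**: defaults to the empirical base composition of the scanned
  promoter set, floored at 0.01 per base (plant promoters are AT-rich;
  a composition-aware null reduces false positives, the floor keeps
  log-odds finite). A uniform model is one argument away, and the model
  used is recorded in the output sidecar.
* **Strand**: the default scans the promoter's sense strand only;
  `both_strands = TRUE` scans the reverse complement and maps hits back to
  window coordinates. Public promoter-scanning services differ on this and
  rarely document it, so it is configuration, not an assumption.
* **Overlaps**: all qualifying offsets are reported, with no greedy
  masking — per-promoter totals in this kind of screen (hundreds of hits
  per 6-kb window) imply dense multi-TF counting.
* **Region classification**: a hit is `upstream` when its *start* is
  negative, `downstream` from +1 on; sites straddling the TSS count as
  upstream. Up + down always equals the total (tested).

## Master screening

`screen_masters()` applies the intersection rule per (TF, hormone,
category) group: a master must have ≥ 1 hit in every gene of the group.
Because the exact published rule behind such screens is rarely printed, a
`min_fraction` relaxation (default 1 = strict) is exposed. Hits are
attributed per matrix and aggregated to the TF name by default — distinct
matrices of one factor pool their evidence, which matters when two factors
share a DNA-binding domain — with `by = "matrix_id"` available. The
biosynthesis ∩ signaling overlap, per-hormone master lists and their union
are all reported, since "how many masters" depends on which of those three
views one counts.

## Differential expression without replicates

Expression is quantified as counts per million (CPM). For the pairwise
control-vs-treated design the package implements a noise-simulation M–D
procedure: per gene, $M = \log_2\frac{\mathrm{cpm}_t + k}{\mathrm{cpm}_c + k}$
(pseudo-CPM $k = 0.5$) and $D = |\mathrm{cpm}_t - \mathrm{cpm}_c|$. Noise
(M\*, D\*) pairs come from multinomial technical replicates of each library
at its observed gene proportions, compared within condition and pooled
across genes (default 5 replicates per condition per round, pooled to
`n_sim = 5000` points). The DE probability is the fraction of noise pairs
strictly less extreme in both coordinates; strict inequalities make the
degenerate case (identical libraries ⇒ probability 0) exact. Calls use a
configurable threshold `q = 0.8` — the source screens of this kind do not
print theirs, so no default can reproduce their DEG counts and the package
does not claim to. Because the noise model captures technical (counting)
variation only, it is intentionally liberal on data with real biological
overdispersion: on the bundled negative-binomial fixture most genes clear
`q = 0.8`. That is intrinsic to replicate-free noise-simulation DE, and is
the reason the null-calibration tests use Poisson (technical-noise-only)
tables where the procedure's probabilities are honest. The joint (M, D) condition is what keeps pooling across
expression strata honest: noise from highly expressed genes has small M\*
but large D\*, so it rarely dominates a weakly expressed gene's
comparison. Percent change follows the field's reporting convention
$(\mathrm{cpm}_t - \mathrm{cpm}_c)/\mathrm{cpm}_c \times 100$, so a
3.25-fold CPM ratio reads "+225%". The qPCR layer is the standard ddCt:
relative expression $2^{-\Delta\Delta C_t}$, with the Pearson correlation
against CPM provided for platform validation.

## What the synthetic data emulates — and what it does not

The generator produces (i) promoter windows with i.i.d. background at a
chosen composition and motif instances *sampled from the PFM* (not
consensus-only, so recovery tests see sub-maximal scores) planted at
recorded non-overlapping offsets; and (ii) negative-binomial count tables
with planted fold changes, columns scaled to target library sizes. Every
draw flows from one seed; fixtures are byte-identical across runs.

The bundled ground-truth fixture mirrors the cardinalities typical of
the screens this package targets: 32 biosynthesis + 9 signaling genes, 18
motifs of which 14 are planted masters (4 SA / 9 JA / 5 ABA / 10 ET
biosynthesis masters, union 14, 7 of them also mastering a signaling
group) plus 4 decoys planted in proper subsets, with 3 sites per (master,
target) — promoters in such screens typically carry several sites per
factor. Its motifs are 15 columns at 0.95 consensus probability
(≈ 20 bits), drawn with a rejection step that caps aligned consensus
similarity between (shifted) motif pairs at L/2, so one factor's planted
sites cannot double as near-threshold sites of another. Two further
properties make exact ground-truth recovery a fair test rather than a
coin-flip:

* Planting three sampled instances per promoter makes a missed
  (master, gene) pair vanishingly rare (a single sampled instance of a
  ≈ 20-bit motif fails the 1e−4 threshold with probability well under 2%,
  so three independent misses are ~1e−5).
* With a 6-kb window and p < 1e−4, *chance* sites are expected about 0.2–0.6
  times per window per matrix — enough that a 2-gene signaling group would
  be "mastered" by accident with non-trivial probability. The fixture
  therefore re-draws background segments that happen to contain a chance
  hit of any planned motif (scan-and-scrub, seeded and deterministic),
  leaving planted sites as the only ones passing the threshold. This is a
  deliberate property of the *fixture*: calibration tests of the
  false-positive rate use the raw, unscrubbed background generator.

What the synthetic data does **not** emulate: real promoter sequence is not
i.i.d. (CpG structure, TATA elements, repeats), real motifs have correlated
columns, real libraries have biological — not just technical — variance,
and real TF families share binding domains. Passing the fixture tests
therefore demonstrates the machinery is correct and calibrated under its
stated null, not that any particular biological master-TF list is right.

## Numerical and degenerate-input choices

Round-half-even discretization keeps the DP grid unbiased; p-values are
reported from the discretized distribution so scan decisions and reported
p agree exactly. Windows shorter than a motif yield an empty result (not
an error). A zero library size, a group gene without a scanned promoter,
duplicate identifiers, ragged matrices and off-sequence TSSs are all
validation errors raised before compute. Ties in the M–D comparison count
as "not less extreme" (strict inequalities). All tabular outputs have a
deterministic sort order, and reruns at a fixed seed are byte-identical —
tested end to end.

## Problem sizes

The shipped tests and the acceptance script run the oracle comparison on
50 random matrices (L ≤ 8, full 4^L enumeration), calibrate the false-positive
rate on 200 six-kilobase windows (~1.2 M offsets), plant 500 single-site
windows for recovery, screen the full 41-promoter fixture at the standard
−5000..+1000 window, and use 200 seeded count tables for fold-change
recovery plus 500 null genes for DE calibration — sizes chosen so each
property is measured with comfortable statistical margin on a laptop-class
machine.

## Limitations

Only order-0 backgrounds are supported (no Markov nulls); no motif
discovery; no FDR layer over hits (the screen thresholds raw p, as its
sources do); the DE procedure is the replicate-free noise simulation, not
a GLM — with real replicated designs, use edgeR/DESeq2 instead; one TSS
per gene (no isoform disambiguation).
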