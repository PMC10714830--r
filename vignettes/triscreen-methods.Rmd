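---
title: "Methods: the tri-modal screen, its statistics and its synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the tri-modal screen, its statistics and its synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triscreen)
```

## Why three search modes

A discovery screen for divergent enzymes trades precision for reach in
three steps. Sequence search (Smith–Waterman) is precise but blind beyond
roughly 25–30% identity. Profile HMMs built from a family alignment reach
further because they weight positions by conservation; in practice the
domain mode's hit set contains the sequence mode's. Structure comparison
reaches furthest: a fold can persist at effectively zero sequence identity.
The screen's interesting output is therefore the *structure-only* set —
proteins hit by the structural mode and by neither sequence-level mode —
after excluding anything the annotation pipeline already labels with the
family being screened for.

## Sequence mode

`smith_waterman()` is exact affine-gap local alignment (a gap of length
$L$ costs $o + Le$), delegated to Biostrings' dynamic programming, with
BLOSUM62 and $o = 11, e = 1$ as defaults. The source material for this
pipeline does not state the matrix or penalties behind its search tool, so
the de facto BLAST defaults are declared here and exposed as arguments. `X`
and any non-standard letter score 0 against everything.

Significance uses the Karlin–Altschul form $E = K m n e^{-\lambda S}$ with
the standard published gapped constants for this matrix
($\lambda = 0.267$ nats, $K = 0.041$), $m$ the query length and $n$ the
total database residues. Exactness of the constants is not load-bearing:
the screen only consumes the $E \le 10^{-5}$ filter, and the E-value's
structural properties (strictly decreasing in $S$, linear in $n$) are
tested rather than any particular magnitude.

## Domain mode

`build_hmm()` turns an aligned family FASTA into a profile HMM: columns
with residue occupancy $\ge$ `match_fraction` (default 0.5, boundary
inclusive) become match states; emissions are per-column residue
frequencies smoothed by `pseudocount` (default 1.0) times the background;
transition probabilities come from the observed match/insert/delete paths
with the same Laplace-style smoothing. Rows are weighted equally ($1/n$),
so duplicating a sequence does not move the profile. Insert states emit the
background and are therefore score-neutral.

`forward_bits()` scores a sequence as the log2 odds of the full forward sum
over a local-alignment-wrapped profile versus an i.i.d. background null.
The wrapping is uniform — entry probability $1/M$ into any match state at
any position, an exit factor $1/M$ from any match state — and flanking
residues cancel against the null. The implementation is a log-space
dynamic program in C++; a brute-force path enumeration over tiny profiles
(M ≤ 3, sequences ≤ 4) pins its correctness, and the forward score
dominates the Viterbi score on every input by construction.

Calibration is deliberately empirical: `calibrate_and_search()` scores
`n_null` (≥ 100, default 200) residue-shuffled sequences drawn from the
proteome itself and fits a Gumbel by moment matching
($\beta = s\sqrt{6}/\pi$, $\mu = \bar{x} - \gamma\beta$). This replaces the
analytic calibration of dedicated HMM software and is documented as an
approximation. A target's P-value is the Gumbel upper tail; its E-value
multiplies by the number of targets searched, and inclusion is
$E \le 0.01$. Two readings of that threshold are possible (per-sequence
P-value versus database-wide E-value); this package applies it to the
E-value, which keeps the expected number of false inclusions per screen at
about 1%, independent of proteome size, while the calibration tests assert
the P-value uniformity directly.

## Structure mode

Structures are C-alpha traces with per-residue confidence read from the
B-factor column (`read_structure()`: first model, first chain, altLoc
blank/A, CA-only files accepted). Confidence is carried but **never
filtered on**: disordered termini depress pLDDT-like scores for secreted
enzymes, precisely the proteins such screens target, and a property test
asserts hit sets are identical when every confidence is 95 versus 55.

`assign_sse()` assigns elements from short-range C-alpha distances alone
(models may lack all other atoms): helix where $d_{i,i+2} \in [5.1, 6.4]$ Å
and $d_{i,i+3} \in [4.6, 6.4]$ Å, strand where $d_{i,i+2} \in [6.4, 7.4]$ Å,
with at least two consecutive window hits (suppressing one-off artifacts at
segment junctions), minimum covered lengths 5 (helix) and 3 (strand),
overlap-merging of jittered runs, and helix precedence on conflicts. The
windows are exposed as an argument.

`match_sse()` aligns the two SSE *sequences* by dynamic programming over
order-preserving, type-consistent pairs; a pair scores
$2 - |\Delta \mathrm{len}|/\max(\mathrm{len}) - |\Delta\theta|/\pi$, where
$\theta$ is each element's angle to its predecessor's axis (axes are
principal components of the element's coordinates). Skips are free, so the
DP finds the maximal-score correspondence; exhaustive enumeration over all
matchings validates it for lists up to 5 elements. The *lowest acceptable
match* filter is the percentage of **query** SSEs matched — the denominator
is a genuine convention choice, so `denominator = "min"` and `"target"`
variants exist; query-side is the default because the screen asks "how much
of my known enzyme's architecture does the target reproduce".

Residue-level alignment seeds pairs across matched SSE midsections, then
iterates: Kabsch superposition (base-R SVD; proper rotation enforced) on
the current pairs, re-pairing as mutually nearest C-alpha neighbours within
4.5 Å (the first round at a doubled cutoff to enlarge the basin), stopping
when the pair set repeats or after 50 rounds. For equal-size models the
sequential correspondence is tried as an extra seed and the best final Q
wins — this rescues noisy near-identical folds whose SSE windows have
degraded, and cannot manufacture similarity where none exists because a
wrong fold refines to a low Q. The final score is
$Q = N_\mathrm{align}^2 \,/\, \big((1 + (\mathrm{RMSD}/R_0)^2) N_1 N_2\big)$
with $R_0 = 3$ Å, the established scale constant for this score; $Q = 1$
exactly when both models align completely at zero RMSD. Ties in rankings
break lexicographically by target id, everywhere, so reruns are
byte-stable.

## Triage, repertoire, density, expression

`combine_hits()` is pure set logic: union of the three hit id sets, minus
ids annotated with the excluded family (AA9 for the LPMO screen, AA1 for
laccases, AA2 for peroxidases); annotation metadata (InterPro-style labels,
accessions, signal peptides) is carried through but never used as logic.
Signal peptides and cleavage positions are inputs from a dedicated
predictor; the built-in N-terminal hydrophobic-window heuristic is labelled
non-authoritative. The LPMO-specific histidine check is
`residue[cleavage + 1] == "H"`, false when no signal peptide exists.

`profile_genome()` counts per **domain**, not per protein (a multi-domain
protein contributes several), subfamilies like AA3\_2 stay distinct at
family level but roll up to the class, and the AA proportion is
$100 \cdot \mathrm{AA}/\mathrm{total}$. `build_tree()` derives the taxonomy
topology from ranked lineage strings; clade statistics are the mean and the
**sample** SD ($n-1$; the convention is declared, the source prints
"mean ± SD" without one) over descendant genome AA proportions.
`prune()` removes genera with fewer than 3 and then families with fewer
than 8 species-level representatives — distinct species names, so multiple
assemblies of one species count once — and collapses nodes below genus.
Genus pruning precedes the family count, so a family is judged on the
species that actually remain under it. `percentile_rank()` is strictly
"population below value" over genomes (midpoint variant available).

Expression flags are the package's own operational test, declared as a
stand-in for whatever upstream differential-expression pipeline produced
the source data: per substrate timepoint, flag iff
$\log_2(\bar{T}_\mathrm{sub}/\bar{T}_\mathrm{glu}) \ge 1$ **and** a Welch
one-sided t-test on $\log_2(\mathrm{TPM} + 0.5)$ survives BH correction at
$\alpha = 0.05$ across the candidate × timepoint set tested together. The
0.5 pseudo-TPM handles zeros; precomputed flags can be ingested instead.
Flag invariance under global TPM rescaling is exact only far from the
pseudo-count and is tested in that regime.

## The synthetic benchmark

The generator exists so every downstream claim is testable without
downloads; its defaults are the study conditions, not tuning knobs.

* **Proteome** — one LPMO-like template (eight SSEs: seven strands and a
  short helix in coils, ~150 residues — an immunoglobulin-like
  beta-sandwich at desk scale) with family label AA9; one planted analog of
  each kind; 50 decoys of i.i.d. residues, uniform over the 20 amino acids
  (the simplest null, overridable), lengths uniform in [120, 400] (spanning
  the LPMO-to-laccase size range).
* **Divergences** — substitution *counts* are fixed fractions of length
  rather than binomial draws, so identity guarantees hold at every seed:
  close homolog 15% (identity ≥ 80%), remote homolog 50% within 40–60%
  random flanks, fold-only analog a residue permutation. A 50%-identity
  core is still sequence-detectable (as real remote homologs at that
  identity are); the fold-only analog is the one that isolates the
  structure mode.
* **Structures** — helices on ideal alpha geometry (2.3 Å radius, 1.5 Å
  rise, 100°/residue), strands extended (3.4 Å rise, alternating ±0.85 Å
  offset), coils random walks with step 3.8 ± 0.1 Å and turning angles in
  100–140°, which places them outside both assignment windows so coils
  cannot masquerade as elements. Planted analogs reuse the template's
  builder stream (same fold) plus 0.4 Å coordinate noise; decoys get 0–2
  short elements in long coils, the realistic expectation for random
  sequences (largely disordered) and the reason chance SSE agreement with
  an 8-element query stays below the 50% filter. Confidence is written as
  90 on elements, 50 on coils, mimicking pLDDT's habit — and then ignored,
  as the screen requires.
* **Tables** — per-genome AA proportions are drawn from the clade plan's
  Normal(mean, SD), truncated to [0, 100], and realised over 300 domains;
  expression is log-normal (s.d. 0.25 in log2) around per-protein
  baselines with the plan's fold-changes applied.

All randomness flows from one seed through named substreams
(`substream_seed()`), so regeneration is byte-identical and adding a stage
never perturbs another's draws.

What passing these tests does **not** show: real proteomes have biased
residue composition (decoys here are uniform), real predicted models have
correlated, confidence-dependent error rather than isotropic noise, real
folds drift and swap elements rather than jitter, and real expression has
overdispersion and batch structure. The benchmark validates the machinery
and its thresholds' set logic, not field performance.

## Numerical choices and degenerate inputs

Problem sizes default to desk scale — a 54-protein proteome, 200 shuffled
nulls, a 200-genome taxonomy plan, 100-seed calibration loops — chosen so
the whole suite runs in about two minutes while keeping every statistical
check comfortably powered. Empty sequences score 0 with empty alignments;
empty annotation sets profile to zero with a warning; an MSA with no match
columns, a null with degenerate variance, fewer than 3 superposition
pairs, and hit ids absent from the proteome are errors by design. Forward
scoring treats unknown residues as background-distributed wildcards.
Co-optimal alignments break ties toward smaller query start, then target
start; SSE DP traceback prefers the diagonal.

## Known limitations

The profile HMM is single-hit local (no multi-domain architecture); E-value
calibration is shuffle-based, so extreme tail P-values are extrapolations
of a moment-matched Gumbel; SSE assignment from C-alpha geometry degrades
beyond ~1 Å coordinate noise (real predicted models are smooth, so this
bites mainly on synthetic stress tests); the SSE matcher compares element
sequences, not contact topology, so fold identity at equal element
composition is left to the Q-score stage; and the expression test is a
two-sample Welch stand-in, not a negative-binomial model.
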