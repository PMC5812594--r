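---
title: "Predicting stable single alpha-helix domains with sahscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting stable single alpha-helix domains with sahscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sahscan)
```

## The model

Stable single alpha-helices (SAH-domains) are monomeric helices, typically
dominated by glutamate, lysine and arginine, that remain folded in polar
solution without tertiary contacts. Their stability comes from networks of
salt bridges between side chains that sit near each other on the same face
of the helix — sequence separations of *i*,*i+3* and *i*,*i+4*.

`sahscan` treats every protein sequence as one continuous right-handed
alpha-helix. On the helical net the first residue occupies heptad position
*a*, and positions repeat every seven residues (`heptad_position()`). No
coiled-coil predictor is consulted for the register: the register is fixed
by the sequence itself. This matters because the tool's job is to separate
SAH-domains from coiled coils, whose heptad assignment comes from a
hydrophobic seam.

For a window of *w* residues the raw score is

\[ S(a) \;=\; \sum_{i \in \text{window}} \big[ M_3(x_i, x_{i+3}) +
   M_4(x_i, x_{i+4}) \big] \;+\; \sum_{\text{triples}} s_{\text{net}} , \]

where \(M_3, M_4\) are editable 20x20 matrices of pairwise interaction
scores and the triple sum adds a network score for every residue triple in
(*i*,*i+3*,*i+6*), (*i*,*i+3*,*i+7*), (*i*,*i+4*,*i+7*) or
(*i*,*i+4*,*i+8*) spacing that is either alternating in charge (members of
{D,E} against {K,R}; stabilizing, +0.25 by default) or entirely
hydrophobic ({V,I,L,M,F,Y}; a coiled-coil seam signature, -0.25 by
default). Every pair and triple is attributed to its *first* index, and
pairs from the window's last helical turn to residues past the window end
are included (the helix continues); incoming pairs from before the window
are not. One consequence we exploit: the raw window score is an exact sum
of per-position contributions, so profiles are computed as rolling sums
yet equal a naive per-window enumeration to machine precision (this dual
computation is tested).

Raw scores are normalized by the score of the same window laid over a
perfect `EEEEKKK` repeat (`compute_normalization()`), which pins that
motif at SAH-score 1. Because the default windows (14, 21, 28, 49) are
multiples of seven, any interior window over the periodic repeat covers
each heptad position equally often, so the interior score is exactly 1
regardless of phase. Rescaling both matrices and the network scores by a
common positive factor leaves every normalized score unchanged.

The window score is assigned to the residue at window position
\(\lfloor w/2 \rfloor + 1\): 8, 11, 15 and 25 for the default windows.
The stated assignment positions "8 and 15" for the even windows are read
distributively (14 → 8, 28 → 15); the alternative reading (two scores per
window) is rejected because the number of terminus-affected residues
(7/10/14/24) matches one assignment position per window. Windows
overhanging a terminus are completed with strictly neutral dummy residues,
as are tolerated non-standard symbols (`X`, `U`, `B`, `Z`, `O`, internal
`*`), so profile values decay over a ramp of offset-1 residues at the N
terminus and about \(w - \text{offset} + 5\) at the C terminus.

## Default matrices

The published score table behind the original tool is not reproduced in
the text we build on, so the package ships its own documented defaults,
constrained by what short-peptide experiments established: E→R (at
*i*,*i+4*) is the strongest single salt bridge, E→K is next, both beat the
reverse bridges R→E and K→E, and aspartate bridges are distinctly weaker
than their glutamate homologs. Glutamine, asparagine and alanine get small
helix-supporting scores with charged partners and themselves; proline is
strongly penalized in either pair position, and glycine pairs are
penalized as the second canonical helix breaker. Identically charged pairs
score zero — they occur in every exemplary SAH pattern (four Es followed
by three Ks contains E–E and K–K pairs at the scored spacings), so they
carry no discriminating signal. The matrices are CSVs under
`inst/extdata/` (rows = residue at *i*, columns = partner) and can be
edited freely; the normalization constants are recomputed from whatever
matrices are active, never hard-coded.

## Domains

A candidate SAH-domain is a maximal span whose first and last residues
score strictly above the per-residue cutoff (default 0.25), that contains
at most 20% of residues at or below the cutoff, and that is at least as
long as the scoring window. The merge procedure is deterministic: maximal
above-cutoff runs are scanned left to right and greedily merged with the
next run whenever the union span stays within the gap tolerance. Greedy
merging (rather than, say, maximizing total covered length) is this
package's canonical behaviour: it is linear, cannot tie, and implements
the stated intent of not splitting long domains over one or a few weak
residues.

Candidates are ranked by the SAH-domain-score: the maximum over all
contiguous 14-residue sub-windows of the mean per-residue score. A domain
of length L admits exactly L − 14 + 1 such sub-windows, all of which are
evaluated. Averaging over a fixed-length sub-window keeps short and long
domains comparable; taking the best sub-window avoids penalizing long
domains for weak shoulders. Domains are retained when the score reaches
the per-window minimum: 0.35 (14 aa) and 0.25 (49 aa) as published, with
0.32 and 0.29 for the intermediate windows; for non-default window sizes
the cutoff is interpolated linearly between the 14 aa and 49 aa
endpoints. Residue comparisons are strict (`> cutoff`), domain-score
comparisons non-strict (`>= minimum`), mirroring "above the cut-off" vs
"minimum score". The sub-window length is capped at the window size so
every candidate is scorable.

## Dataset analytics

All analytics operate on the domain tables and are checked against
independent counting implementations in the test suite:

* `composition()` pools residues over all domains; the charged/polar
  fraction (D, E, K, R, N, Q) times seven gives the "heptad equivalent",
  the number of heptad positions fully occupied by charged/polar residues.
* `heptad_frequency()` counts every 7-residue substring per occurrence
  (sliding window, register ignored) and ranks by count with
  lexicographic tie-breaks.
* `unique_domains()` collapses identical domain sequences within a gene,
  computes the fraction of the gene's transcripts carrying each unique
  domain, and flags strict-substring (`including`/`included`) and
  terminal-overlap (`overlapping`, >= 5 residues, longest suffix–prefix
  match) relations. Overlap detection is string-based because the package
  sees protein sequences, not genomic coordinates; whether the original
  analysis used coordinates is unknown, so the string definition is
  documented as canonical here.
* `cross_gene_identity()` finds verbatim-identical unique domains shared
  by several genes and cross-gene inclusion pairs.
* `length_histogram()` bins protein lengths (50 aa bins, > 3000 aa
  omitted) for all proteins and for SAH-carrying proteins;
  `multi_domain_counts()` tallies domains vs domain-bearing sequences.

Analytics default to the 14 aa window domain set; any window can be
selected.

## Prediction and re-analysis

`cmd_predict()` parses, scores and persists a dataset in one pass;
`cmd_analyze()` re-detects domains from the stored profiles under possibly
tightened cutoffs, without re-scoring, and writes all report tables. The
store is a directory of TSV tables plus a YAML configuration snapshot and
matrix copies — plain text, diffable, and sufficient to reproduce the run.
Profiles are persisted only for sequences that carried at least one
retained domain, so re-analysis supports equal-or-stricter cutoffs; this
mirrors keeping only above-cutoff results. Scores in reports are printed
to 4 decimals; stored profiles keep full precision (17 significant
digits), so a reload reproduces them bit for bit and identical runs
produce byte-identical outputs. SVG profile plots are generated natively
rather than through an external plotting program.

## The synthetic generator

`make_planted_dataset()` emulates the one signal this method is designed
to find: perfect `EEEEKKK` repeats (35 aa by default) embedded in
charge-free low-complexity flanks drawn uniformly from {G, S, T, A}, with
a 15-residue margin from the termini so inserts sit in full-window
context. That background scores near zero, so detection boundaries
reflect the scoring-window ramp alone. It deliberately does not emulate
real proteomes: no realistic composition, no coiled coils, no
partially-charged regions, no isoform splice structure beyond a minimal
4-transcript family (two identical carriers, two insert-free). Passing
the recovery tests therefore demonstrates correctness of the scoring and
segmentation machinery, not field performance on real genomes. Flank
alphabets including breakers and hydrophobics (e.g. adding P, V, L) are
available via the `background` parameter; they make flank scores strongly
negative and noisy, which pulls detected boundaries inside the insert —
useful for stress tests, not for calibrated recovery checks.

## Numerical choices and known limitations

* **Boundary ramp.** With near-neutral flanks, the window anchored at a
  flank residue k positions before a planted insert still covers
  \(w - \text{offset} + 1 - k\) insert residues, so the 0.25 cutoff is
  crossed about \(0.75 w - \text{offset} + 1\) residues before the true
  start: ~3–4 residues for the 14 aa window but ~5–6 (21 aa) and ~6–7
  (28 aa) for the larger windows. This left-boundary overshoot is a
  property of forward-attributed windows plus a fixed cutoff, not of the
  matrix values; tests assert boundary accuracy at the ramp widths, and
  exact (+-4) boundary recovery should only be expected from the 14 aa
  window.
* **Terminal residues.** A residue at the very end of a sequence keeps
  only a small fraction of its window's interactions after dummy padding
  (about 2 of ~34 for the last residue at window 14), so terminal scores
  are structurally far below an interior score of the same motif. The
  bundled 62-residue Myo10 SAH region illustrates this: scored in
  isolation its final ~13 residues fall below the 0.25 cutoff and the
  region is reported as a single domain covering residues 1–49. In its
  native full-length protein context those residues would carry complete
  windows. Excerpt-level scoring near termini should be read with this
  in mind.
* Scores are not clamped at 1: matrices that reward some pattern more
  than `EEEEKKK` produce scores above 1 by design.
* Sequences shorter than the smallest configured window are flagged
  invalid, counted, and excluded from scoring.
* Determinism: no randomness anywhere in scoring, segmentation or
  reporting; fixture generation is seeded.

Test problem sizes were chosen to exercise every code path while keeping
the whole suite fast on one CPU: 200 random sequences of 15–120 residues
for the dual-computation (rolling sum vs naive enumeration) check, 50
seeded planted datasets for recovery, and fixture sets of tens of
sequences for the analytics oracles.

## A worked example

```{r example, eval = FALSE}
cfg <- sah_config()
myo <- bundled_examples()
prof <- score_profile(myo$sequence[1], window_size = 14, config = cfg)
domains <- filter_domains(detect_domains(prof, cfg), cfg)
domains[, c("start", "end", "length", "domain_score")]
heptad_frequency(domains, top_n = 5)
```

See the README for a full run of this example with its printed output,
and `scripts/acceptance.R` for the script that recomputes the package's
headline quantity (the perfect-repeat normalization identity) from
scratch.
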