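# sahscan

Prediction and analysis of **stable single alpha-helix (SAH) domains** in
protein sequences.

SAH-domains are monomeric helices — extremely rich in glutamate, lysine
and arginine — that stay folded in polar solution without any tertiary
contacts, and act as rigid connectors and constant-force springs between
structural domains (the lever-arm extensions of myosins are the classic
example). They are easy to confuse with coiled coils and disordered
low-complexity regions, which is exactly the distinction this package is
built to make: coiled coils are stabilized by a hydrophobic heptad seam,
SAH-domains by networks of charged side-chain interactions along a single
helix.

`sahscan` is for people who want to scan anything from one sequence to a
whole proteome FASTA for SAH-domains, tune the scoring to their lineage or
sub-type of interest, and compare predicted domains across alternative
transcripts of the same genes.

## The method

Every sequence is treated as a continuous right-handed alpha-helix with
residue 1 at heptad position *a*. For a sliding window of *w* residues
(defaults 14, 21, 28, 49) the raw score sums

- pairwise interaction scores *M₃(xᵢ, xᵢ₊₃)* and *M₄(xᵢ, xᵢ₊₄)* for every
  *i* in the window (pairs from the window's last helical turn reach past
  the window end — the helix continues), taken from two editable 20×20
  CSV matrices; and
- network scores for residue triples in (*i*,*i+3*,*i+6*),
  (*i*,*i+3*,*i+7*), (*i*,*i+4*,*i+7*), (*i*,*i+4*,*i+8*) spacing:
  +0.25 per alternating oppositely-charged triple ({D,E} vs {K,R}),
  −0.25 per all-hydrophobic triple ({V,I,L,M,F,Y}, a coiled-coil seam
  signature).

The window score is divided by the score of the same window over a
perfect `EEEEKKK` repeat, so that motif defines SAH-score 1, and assigned
to the residue at window position ⌊w/2⌋+1; windows overhanging a terminus
are padded with non-interacting dummy residues. An SAH-domain is a
maximal span, at least one window long, whose first and last residues
exceed the per-residue cutoff (0.25) with at most 20% of interior
residues at or below it. Domains are ranked by the **SAH-domain-score** —
the best mean score over all contiguous 14-residue sub-windows — and
retained when it reaches the per-window minimum (0.35/0.32/0.29/0.25 for
windows 14/21/28/49).

## A worked example

The package bundles the 62-residue SAH region of human myosin-10
(translation ENSP00000421280):

```r
library(sahscan)
cfg <- sah_config()
myo <- bundled_examples()
prof <- score_profile(myo$sequence[1], window_size = 14, config = cfg)
domains <- filter_domains(detect_domains(prof, cfg), cfg)
domains[, c("seq_id", "start", "end", "length", "domain_score")]
#>   seq_id start end length domain_score
#> 1    seq     1  49     49    0.8357143
heptad_frequency(domains, top_n = 5)
#>    heptad count
#> 1 AEKREQE     1
#> 2 AELRAQQ     1
#> 3 AQQEEET     1
#> 4 EAELRAQ     1
#> 5 EEEEKKK     1
```

One SAH-domain is reported, spanning residues 1–49 of the excerpt with an
SAH-domain-score of 0.836 — a very confident call (the retention cutoff
at window 14 is 0.35, and a perfect `EEEEKKK` repeat scores 1.0). The
domain's heptad table also contains the most common human SAH heptad,
`RERERER`, once. The last ~13 residues of the excerpt are not included in
the domain: scored in isolation, terminal residues keep only a fraction
of their window's interactions after dummy padding (in the full-length
protein they would carry complete windows); see the methods vignette.

Whole datasets run through the two pipeline stages, from R or the
installed command-line script:

```sh
sahscan --id myrun --input proteome.fa --out results --windows 14,21,28,49
# later, tighter filtering without re-scoring:
sahscan --id myrun --out results --stages analyze --residue-cutoff 0.3
```

which leave a plain-text result store plus, per window, composition,
domains-by-length, detailed-domain, heptad-frequency, unique-domain and
summary tables under `results/myrun/`.

## Package layout

- `R/` — scoring model and configuration, profile computation, domain
  detection, dataset analytics, FASTA/TSV/SVG I/O, result store, CLI,
  fixture generators.
- `inst/extdata/` — the default scoring matrices
  (`scoring_matrix_i_3.csv`, `scoring_matrix_i_4.csv`).
- `vignettes/sah-domain-prediction.Rmd` — the model, its assumptions,
  parameter choices and known limitations.
- `tests/testthat/` — unit, property and acceptance tests, including an
  independent naive re-implementation of the scorer used as an oracle.
- `exec/sahscan`, `R/cli.R` — command-line interface.
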