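---
title: "RUST: model, design choices and simulation conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RUST: model, design choices and simulation conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rustseq)
```

## The transformation and its statistic

Ribosome footprint counts are heteroscedastic and heavy-tailed: a single
cloning or ligation artefact can deposit more reads on one codon than the
rest of the transcript combined, and sparse coverage leaves long runs of
zeros. RUST replaces each transcript's codon-level count profile with a
binary step function — codon $i$ scores $1$ when its count strictly
exceeds the transcript's average density — so that the contribution of any
single position is bounded and the statistic depends only on whether, not
how far, a codon sits above its gene's average.

For a determinant $c$ (codon, nucleotide, amino acid, dipeptide,
tripeptide, peptide-property window or structure window) at position $l$
relative to the A-site, the observed RUST value $ro_{cl}$ is the mean of
the A-site indicator over all occurrences of $c$ at $l$, pooled over all
transcripts. Its expectation under the null that sequence does not matter
is not $1/2$, because highly expressed genes have both a higher chance of
above-average codons and a different codon composition. The expected
value $re_{cl}$ therefore averages, over the same occurrences, the
transcript-level mean of the binary profile; the ratio $ro/re$ is the
enrichment of footprints attributable to the determinant. An enrichment
above 1 marks slow decoding, below 1 fast decoding.

Per-position information is summarized by the Kullback–Leibler divergence
of the observed against the expected distribution over determinants.
$ro_{\cdot l}$ and $re_{\cdot l}$ are proportions, not probability
vectors, so both are renormalized by their own sums per position before
computing $D_l = \sum_c p_{cl}\log_2(p_{cl}/q_{cl})$ (bits; terms with
$p_{cl}=0$ contribute 0, and cells with no observation or $re=0$ are
excluded rather than zero-filled). Whether the original formulation
renormalized is ambiguous; renormalizing guarantees $D_l \ge 0$ with
equality exactly when the normalized profiles coincide, and shifts only
the absolute scale of the series, never the position of its maximum.

### Assumptions

* Footprint counts at distinct codons are treated as independent given the
  transcript's total; no flow-conservation coupling between neighbouring
  positions is modelled.
* Reads are attributed by their 5$'$ end plus a fixed A-site offset,
  irrespective of subcodon position; soft-clips are not corrected.
* One profile per gene — the longest coding isoform — so that each
  elongation event is counted once.
* Initiation and termination neighbourhoods behave atypically, so A-site
  positions within 120 nt (40 codons) of the start or 60 nt (20 codons)
  of the stop are excluded everywhere (the *admissible region*). The
  binarization threshold is the mean over this admissible region, not the
  full CDS, so the statistic and its normalizer see exactly the same
  data; transcripts with no reads in the region are excluded (their
  $ro/re$ would be $0/0$).

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| metafootprint window | $-40..+20$ | codons | spans the nascent-peptide exit tunnel upstream and the unwound mRNA downstream; 61 positions with the A-site at 0. The asymmetric span matches the figure convention of metafootprint profiles; a "window centred on the A-site" reading is inconsistent with that span and was not adopted. |
| analysis window | 120 / 60 | nt after start / before stop | excludes initiating and terminating ribosomes |
| read selection | predominant length, unique mappers | — | one length keeps the footprint-end-to-A-site distance fixed; ties fall to the smaller length; uniqueness is a switch because results with and without multimappers are nearly the same |
| A-site offset candidates | 16, 17, 18 | nt | the plausible 5$'$-end-to-A-site distances for ~28–30 nt footprints; the winner maximizes the combined K–L of an adjacent interior codon pair (the P/A pair has the greatest joint influence, and in some libraries the P-site divergence exceeds the A-site's) |
| CN / LMN density gate | 1 | read/nt | coding regions below it carry too little signal for count-based scores |
| RRT window | 19 codons, step 1 | — | windows must hold $>19$ reads, $<3$ empty codons, and a unique codon at window position 10 (1-based); the step is not specified anywhere, and step 1 maximizes the data |
| synergy scan | $-40..+17$, background $-40..+18$ | codons | 58 first-residue positions so the 3-residue window fits the profile; $20^3 \times 58 = 464{,}000$ combinations |
| prediction sites | $-6..+5$ | codons | the 12 codons centred on the P-site/A-site boundary: footprint codons plus one flank on each side. The boundary phrasing admits several integer mappings; this one yields exactly 12 codons symmetric about the boundary, and the site set is an argument |
| peptide windows | 10 residues | — | positives {H, K, R}, negatives {D, E}, hydrophobics {A, V, I, L, M, F, Y, W}; net charge counts histidine as fully positive |
| structure windows | 80 nt, step 10 | nt | MFE percentile classes 1/5/10%; thresholds either recomputed per dataset or the shipped human reference values (−40.1/−32.8/−29.0 kcal/mol) |

## The simulator and what it emulates

Counts are drawn per admissible codon position as
$\mathrm{Poisson}(D_m t_c / \sum_{c'} n_{c'm} t_{c'})$: decoding rate
depends exclusively on the A-site codon, and the expected transcript total
is $D_m$. Dwell grids are 61 equally spaced values between the printed
endpoints — 1 to 10.15 (ten-fold) or 1 to 92.5 (hundred-fold). Note these
endpoints are inconsistent with a literal increment of 0.15/1.5 over 61
points (which would end at 10.0/91.0); the endpoints are honoured, giving
an actual spacing of $9.15/60$ and $91.5/60$. Grid order follows
codon-usage rank (positive correlation: rarest = fastest; ties broken
lexicographically for determinism).

The synthetic transcriptome emulates the salient statistics of a
mammalian catalogue:

* CDS lengths log-normal, median 350 codons, clipped to 100–1200;
* codon composition from the aggregate human usage table;
* per-transcript read density log-normal with median 0.15 and
  $\sigma_{\log} = 2.0$ reads/nt — heavy-tailed across roughly three
  orders of magnitude, with mean $\approx 1.1$ reads/nt, as in real
  libraries where a small set of transcripts carries most reads;
* a usage–expression coupling (default 0.3): highly expressed transcripts
  are tilted toward abundant codons, the translational-selection confound
  that the expected-value normalization exists to correct. Setting the
  coupling to 0 removes it.

Noise models: *peaks* replaces a binomially drawn number of admissible
codons (expected fraction × covered codons, drawn from all coordinates,
previously empty ones included) with three times the profile maximum;
*dropout* zeroes each covered codon independently with the given
probability. Both are per-transcript, so realized alteration counts vary.

What the simulator does **not** reproduce: sequence-dependent biases at
footprint termini (ligation/digestion preferences), frame-dependent read
selection, alignment gaps from repetitive sequence, nascent-peptide or
structure effects (only A-site dwell and noise shape the counts), and UTR
reads. Tests passing on simulated data therefore certify the estimators
under the stated model, not the biology of any particular library.

Simulation sizes used by the test suite (500 transcripts for the recovery
and noise comparisons, 80–200 for round trips, 5–10 seeds for stochastic
claims) were chosen as the smallest sets at which the compared statistics
stabilize.

## Numerical and degenerate-input choices

* Binarization uses a strict inequality, so uniform profiles binarize to
  all zeros and contribute nothing.
* Cells never observed stay `NA`; they are excluded from K–L (which
  requires at least two defined determinants per position) and imputed as
  neutral 1 only inside the density predictor, where the imputation count
  is reported.
* The predictor accumulates log-ratios and subtracts the maximum before
  exponentiating, so long transcripts cannot underflow.
* Offset detection scores only codon pairs strictly inside the footprint
  (terminal codons carry end-bias); exact ties fall to the smallest
  candidate with a warning.
* The synergy standard score uses the per-tripeptide background mean
  *and* standard deviation over positions $-40..+18$ (subtracting the
  mean is part of the standard-score definition even though only the
  divisor is unambiguous in the source material); backgrounds with fewer
  than 3 defined positions, or numerically zero variance, are excluded.
* LMN scores live on the log2 scale (uniform data gives zeros); they are
  exponentiated before mean-normalized comparisons against linear dwell
  times.
* The evaluation of estimated against simulated dwell times
  mean-normalizes both sides over the 61 sense codons and reports log2
  ratios (the log base in such comparisons is conventional; log2 is used
  throughout the package) plus the squared Pearson correlation.

## Known limitations

* The fast-codon bias reported for all estimators — quickly decoded
  codons inferred as slower than simulated — is coverage-dependent for
  RUST and CN. It emerges when the binarization threshold sits below one
  read per codon (typical of real libraries at ~0.1–0.5 reads/nt); at a
  mean density of 1 read/nt and 500 transcripts, the zero-truncating
  estimators (LMN, RRT) display it while RUST and CN do not, and the
  corresponding acceptance check is deliberately left failing for RUST
  rather than relaxed.
* RUST ratios are monotone but not linear in dwell time; extreme
  (hundred-fold) rate ranges compress at the saturated end.
* Frame-restricted read selection, which could sharpen the signal, is not
  implemented.
* Reads mapping to several transcripts of one gene are counted only on
  the chosen (longest) isoform; no re-projection is attempted.
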