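# rustseq

Normalization and sequence-determinant analysis for ribosome profiling
(ribo-seq) data in R.

Ribo-seq measures translation by sequencing the ~28–30 nt mRNA fragments
protected by elongating ribosomes. The footprint density at a codon is, in
principle, proportional to the time the ribosome dwells there, so density
profiles should reveal codon decoding rates and other sequence features
that slow or speed the ribosome. In practice the data are plagued by
sporadic high-density peaks and long alignment gaps, which distort
estimators that work directly on counts.

`rustseq` implements the **Ribo-seq Unit Step Transformation (RUST)**: each
transcript's codon-level footprint profile is reduced to a binary step
function — codon *i* scores 1 if its count exceeds the transcript's average
density, else 0. For a determinant *c* (a codon, nucleotide, amino acid,
dipeptide or tripeptide) at position *l* relative to the A-site, the
observed RUST value *ro(c, l)* is the mean of the A-site indicator over all
occurrences of *c* at *l*, and the expected value *re(c, l)* is the mean of
the transcript-level average indicator over the same occurrences. The
enrichment ratio *ro/re* (> 1: slow, < 1: fast) is robust to outlier peaks
because no single codon can contribute more than 1, and the expected-value
normalization corrects for the non-random distribution of determinants
across genes of different expression levels. The per-position information
content of the resulting metafootprint profile is summarized by the
Kullback–Leibler divergence
*D<sub>l</sub> = Σ<sub>c</sub> p<sub>cl</sub> log₂(p<sub>cl</sub>/q<sub>cl</sub>)*,
with *p* and *q* the position-wise renormalized observed and expected
values.

The package also provides:

* the competing normalizations used for benchmarking — conventional
  normalization (CN>0, CN>1), logarithmic mean normalization (LMN) and
  ribosome residence time (RRT);
* a Poisson footprint simulator with configurable codon dwell-time grids
  (~10-fold and ~100-fold ranges) and two noise models (peak substitution
  and dropout), plus a synthetic transcriptome generator;
* automatic A-site offset detection from the K–L divergence of adjacent
  codon pairs at candidate offsets (16/17/18 nt);
* RUST profiling of nascent-peptide physicochemical windows and of stable
  RNA secondary structure windows (80 nt / step 10, MFE percentiles; the
  folding engine is an adapter — precomputed energies or RNAfold);
* tripeptide synergy detection (standard scores of observed vs
  independence-expected enrichment);
* prediction of per-transcript footprint density profiles from codon RUST
  ratios, with Pearson/Spearman evaluation against observed profiles;
* a per-dataset report bundle (metafootprint + K–L, codon ratios by amino
  acid, prediction summary, synergy map, triplet periodicity).

## Worked example

Simulate a 200-transcript ribo-seq experiment with a ten-fold dwell-time
range, estimate relative dwell times with RUST, and check them against the
simulated truth:

```r
library(rustseq)
world <- simulate_transcriptome(n = 200, seed = 42)
grid  <- build_dwell_grid("tenfold")
sim   <- simulate_dataset(world$transcripts, grid,
                          density = world$density, seed = 43)
sim
#> Simulated ribo-seq dataset: 200 transcripts, 188,590 footprints,
#> tenfold dwell grid (seed 43)

meta <- rust_metafootprint(sim$profiles, world$transcripts, "codon")
meta
#> RUST metafootprint (codon)
#>   positions -40..20 relative to the A-site, 61 determinant values
#>   200 transcripts, 65,395 A-site occurrences
#>   K-L divergence peaks at position 0 (0.183 bits)

coef(meta)[c("AAA", "GCC", "CGT")]      # A-site enrichment ratios
#>       AAA       GCC       CGT
#> 1.3139327 1.3305574 0.1971891

evaluate_estimates(rust_codon_scores(sim$profiles, world$transcripts), grid)
#> Dwell-time estimate evaluation (RUST)
#>   R-squared: 0.9781   Spearman: 0.9914
#>   log2(est/sim) quartiles: -0.154 / 0.005 / 0.061
```

The K–L maximum at position 0 confirms that the A-site codon dominates
footprint density in this simulation, and the estimated dwell times track
the simulated grid almost perfectly (slow codons such as GCC enriched,
fast ones such as CGT depleted). Injecting the peak-substitution noise
model shows why the transformation exists — RUST degrades gracefully while
conventional normalization collapses:

```r
noisy <- inject_noise(sim, "peaks", fraction = 0.2, seed = 44)
evaluate_estimates(rust_codon_scores(noisy$profiles, world$transcripts), grid)
#>   R-squared: 0.9399   Spearman: 0.9739
evaluate_estimates(cn_scores(noisy$profiles, world$transcripts), grid)
#>   R-squared: 0.4337   Spearman: 0.7379
```

Real data enter through `load_transcriptome()` (FASTA + CDS annotation)
and `read_alignments()` (transcript-space SAM/BAM), followed by
`detect_a_site_offset()` and `build_codon_profiles()`; `run_report()`
writes the full per-dataset bundle. A thin command-line front end over
the same functions ships in `inst/cli/rustseq.R`.

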