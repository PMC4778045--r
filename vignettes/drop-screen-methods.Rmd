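---
title: "Methods: the drop-screen generative model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the drop-screen generative model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropscreen)
```

This vignette documents the generative model behind `dropscreen`: what
each stage simulates, the parameters and their defaults, the numerical
choices that matter, and what the model deliberately does not attempt to
capture.

## 1. Library model

A library is a fixed peptide scaffold with degenerate codons at chosen
positions (`library_design()`; default: a 12-residue scaffold with NNK
codons at positions 3, 7 and 10). A degenerate codon is expanded by the
cartesian product of its IUPAC base sets; `orientation = "antisense"`
expands the reverse complement, so an MNN antisense scheme is the same
codon set as sense NNK.

NNK (N = A/C/G/T, K = G/T) yields 32 codons covering all 20 amino acids
with a single stop (amber, TAG). A three-position NNK library therefore
has 31³ = 29,791 stop-free genotypes encoding 20³ = 8000 peptides;
`enumerate_library()` returns each peptide with its genotype
multiplicity and expected frequency. Two abundance conventions are
supported by `screen_config(weights = )`:

- `"uniform"` (default): each of the 8000 peptides is equally abundant.
  This matches the usual screen-planning arithmetic, where coverage is
  quoted per library *member* (e.g. "10 drops per member at λ = 0.1"),
  and corresponds to a library assembled from normalised variants.
- `"codon"`: each stop-free genotype is equally abundant, so a peptide's
  frequency is its codon multiplicity over 29,791 (e.g. 3/29,791 for a
  peptide with one F, one W and one L codon under NNK).

The choice is a statement about how the physical library was made; it is
not fitted.

## 2. Encapsulation and occupancy

`simulate_encapsulation()` draws the template count of each drop as
Poisson(λ). At the default λ = 0.1, the analytic occupancy is 90.5%
empty, 9.0% singlet and under 0.5% multiple; `poisson_occupancy()`
returns the analytic table and `occupancy_histogram()` the realised one.
Each template is a library draw under the abundance weights; a
designated set of binder peptides (`binders`, default `"FWL"`) gives
drops a fluorescent readout (section 3). Expected binder-bearing drops
follow `n_drops * λ / n_library` (`expected_binder_drops()`), e.g. 37.5
≈ 38 among three million drops for an 8000-member library.

Pre-encapsulation leakage — transcripts released before drop formation —
is modelled by adding, per drop, Poisson(λ × `leakage_rate`) *leaked*
molecules drawn from the same library distribution (default
`leakage_rate = 0.2`). Leaked molecules contribute no fluorescence but
are carried into the sorted pools and amplified, which is what puts
background peptides into the bright pool.

## 3. Fluorescence and sorting

Drop fluorescence (in fold-over-background units) is

mean(k) = `baseline` + `increment` × k^`cooperativity`

for k binder templates (defaults 1.0, 1.0 and 1.35: a singlet binder
drop has mean 2.0, a doublet 3.55; non-binder and empty drops sit at
baseline). Measurement noise is additive with `noise_sd = 0.10`, drawn
from a **truncated** normal restricted to ±`noise_limit` = 3 standard
deviations (inverse-CDF sampling).

The truncation is a deliberate numerical choice. The sorting threshold
(default 1.3) sits exactly 3σ above baseline; with untruncated Gaussian
noise the ~0.135% upper tail of a million empty/non-binder drops would
produce on the order of a thousand false-positive bright drops,
swamping the ~12.5 genuine binder drops and contradicting the observed
bright-drop counts (tens per million). Physically, detector noise at
this scale is bounded, not Gaussian-tailed; the ±3σ bound encodes that.
A `width_gate_outlier_rate` (default 1%) excludes a random subset of
drops from sorting, emulating the width/scatter gate of a sorter.

`sort_drops()` labels gate-passing drops `bright` (fluorescence ≥
threshold) or `dark`, and reports the bright fraction among gate
passers. At λ = 0.1, one binder among 8000 members and a 1.3 threshold,
the expected bright count per million drops is ≈ 12.4 (12.5 binder
drops less gate losses).

## 4. Amplification and sequencing readout

RT-PCR is collapsed into a per-genotype weight model
(`amplification_model()`):

- an expressed template contributes `transcripts_per_template = 300`
  weight units (a DNA template yields hundreds of mRNA copies in the
  drop), a leaked transcript contributes 1;
- each genotype's weight is multiplied by a log-normal amplification
  efficiency, LogNormal(0, `efficiency_sd = 1`).

The efficiencies are **drawn once per run and shared across the bright,
dark and input pools** (`run_pipeline()` passes the same vector to every
`amplify_pool()` call). Amplification bias is sequence-dependent — RT
priming and GC content are properties of the genotype, not of the pool
it happens to be sequenced from — and this sharing is also what makes
fold-enrichment interpretable: the bias multiplies numerator and
denominator of the bright/input ratio and cancels. Drawing the bias
independently per pool would instead let a background peptide's lucky
bright-pool draw, divided by an unlucky input-pool draw, overtake a true
binder. Standalone `amplify_pool()` calls draw their own efficiencies
unless a vector is supplied.

The input pool is the unsorted library itself (abundance weights × bias),
sequenced deeper than the sorted pools by default
(`n_reads = c(bright = 2e4, dark = 2e4, input = 1e5)`): every
fold-enrichment needs a defined input frequency, so the input depth must
be large relative to the library size (at 10⁵ reads an equal-abundance
member expects ~12.5 reads).

`simulate_reads()` emits reads of the fixed 56-nt amplicon window (10 nt
of 5' context, the 36-nt peptide CDS, 10 nt of 3' context) with
independent per-base substitution errors (`error_rate = 0.005`) and
Phred qualities: constant Q35, with a `degraded_fraction = 0.2` of reads
carrying an exponential 3' quality decay. FASTQ I/O uses Biostrings.

## 5. Sequence analysis

- **Trimming** (`trim_reads()`): optional 3' adapter removal (suffix
  match, ≤ `adapter_mismatches` substitutions), then quality trimming by
  the running-sum algorithm used by cutadapt/BWA: from the 3' end
  accumulate (cutoff − q) and cut at the position maximising the sum.
  Tie-break: the *rightmost* minimal suffix-sum index, so a tie keeps
  the longer read. Property-tested against a brute-force oracle.
- **Extraction** (`extract_codons()`): the amplicon layout is compiled
  into an `extraction_syntax()` of constant anchors and codon slots;
  anchors must match with ≤ `max_mismatches` substitutions each. Reads
  shorter than the layout are `truncated`; multiple valid placements are
  `ambiguous`; rejection reasons are tabulated.
- **Tabulation** (`tabulate_codons()`): joint peptide frequencies plus
  per-position residue marginals; codon tuples containing a stop are
  counted separately (`n_stop`), not as peptides.
- **Enrichment** (`enrichment()`): fold = bright frequency / input
  frequency, ranked; peptides absent from the input are flagged
  `undefined_input`, never divided by zero.
  `enrichment_significance()` gives a percentile-bootstrap CI on the
  binomial frequency ratio.

## 6. Planning

`plan_screen()` implements coverage arithmetic
(`drops = coverage × n_library / λ`) and warns away from λ = 0.1 in both
directions, quoting computed numbers. Note that at λ = 0.33 the doublet
fraction P(2) is 3.9% — sometimes casually rounded down to "3%"; the
software reports the computed value. Similarly `expected_binder_drops()`
reports the formula value of one binder drop per 0.8 × 10⁵ drops at
λ = 0.1 with 8000 members.

## 7. Determinism and problem sizes

`run_pipeline()` requires a seeded `screen_config()`; every stochastic
stage gets a seed derived as `(seed × 7 + stage × 104729) mod (2³¹ − 1)`,
so identical configs give byte-identical outputs. The test suite
exercises the full pipeline at up to 10⁶ drops (seconds per run);
replicate studies in the tests use 20 independent seeds.

## 8. Limitations

The model is a screening-statistics emulator, not a biophysical
simulation. It does not model: binding-affinity dose response (binders
are a discrete set), transcription/translation kinetics inside drops,
drop-size polydispersity beyond the width gate, PCR cycle-by-cycle
stochasticity or chimera formation, indel sequencing errors, or sorter
droplet coincidence. Fluorescence noise is homoscedastic; real detectors
scale noise with intensity. These simplifications are intentional: the
package's purpose is planning screens and validating analysis code
against known ground truth.
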