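---
title: "Fragment-length-resolved analysis of fragile nucleosomes"
author: "fragilenuc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-length-resolved analysis of fragile nucleosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragilenuc)
```

## The problem

Promoters, active enhancers and CTCF-bound sites carry a
nucleosome-depleted region (NDR) flanked by well-positioned nucleosomes
(the −1 and +1 nucleosomes at a TSS). Under mild MNase digestion the NDR
is not empty: it contains MNase- and salt-sensitive particles — partially
unwrapped ("fragile") mononucleosomes and subnucleosomes protecting less
than the 147 bp core. Because these particles are defined by the *length*
of the DNA they protect, paired-end sequencing with fragment-length
resolution is the instrument of choice: fragments ≤150 bp read out
subnucleosomes, 151–230 bp mononucleosomes, and larger fragments
nucleosome–factor complexes.

`fragilenuc` implements the analysis stack for this kind of experiment —
size fractionation, spike-in and depth normalisation, anchor-centred
meta-profiles, NDR definition and length scaling, fragment-length V-plots
with highest-density-region (HDR) contours, CTCF motif-oriented occupancy
and 3′-asymmetry, differential gain/loss classification with congruence
enrichment, and A/T-content comparison — together with a synthetic
chromatin simulator that generates libraries with known ground truth, so
every stage can be validated by parameter recovery rather than by eye.

## The simulator: what it emulates

`sim_config()` + `simulate_chromatin()` build a small genome (default
five 1 Mb chromosomes) with:

* **Promoters** — a stranded TSS per gene; a configurable fraction overlap
  a CpG-island (CGI) interval whose sequence is G/C-enriched by ≥0.10 over
  background. The NDR (width ~N(160, 20), floored at 100 bp) lies
  immediately upstream of the TSS; −1/+1 nucleosome dyads sit 73 bp (half
  a 147 bp core) outside the NDR edges, with phased arrays at the
  190 bp repeat length beyond them. A fraction of CGI promoters is
  polycomb-repressed: transcriptionally near-silent and carrying no
  H3K27ac on any particle, while H3K115ac in the NDR is allowed.
* **NDR-internal fragile particles** — one subnucleosome placed
  TSS-proximally (¼ of the NDR from the TSS) and one fragile
  mononucleosome displaced towards the −1 nucleosome (¾ of the NDR from
  the TSS). Their relative occupancies (0.45 vs 0.30) were chosen so that
  the intra-NDR geometry survives size fractionation: the fragile-mono
  length law (145 ± 12 bp, truncated to [40, 400]) straddles the 150 bp
  class boundary, so roughly two thirds of its fragments land in the
  subnucleosomal class and would otherwise mask the TSS-proximal
  subnucleosome.
* **Enhancers** — 600 bp accessible intervals with one or two Oct4
  motifs; fragile particles between the motifs, stable H3K27ac-marked
  nucleosomes flanking.
* **CTCF sites** — a stranded, scored motif per site with latent
  occupancy ~U(0.15, 1). The site hosts a CTCF–subnucleosome complex at
  the motif, a subnucleosome displaced `ctcf_sub_shift` (15 bp) towards
  the motif 3′ end (the source of the downstream occupancy asymmetry),
  nucleosome-plus-factor particles (280 ± 35 bp) at ±150 bp, and flanking
  arrays whose *downstream* positioning spread grows as occupancy falls
  (12 + 35·(1−occ) bp) — upstream phasing is occupancy-independent.
* **Marks** — Bernoulli per particle with per-context probabilities
  (`default_mark_probabilities()`): H3K115ac concentrated on NDR-internal
  particles (0.85 at CGI promoters vs 0.05 at non-CGI, reflecting the
  strong CGI preference of the mark) and the −1 nucleosome; H3K27ac on
  +1/flanking nucleosomes and gene bodies, never inside NDRs.
* **Libraries** — input picks particles ∝ occupancy; ChIP ∝ occupancy ×
  mark × `chip_efficiency` (0.8) plus a 5% background drawn from the
  input law. Fragment length is the particle-class truncated normal;
  midpoint jitter is N(0, positioning_sd). Spike-in barcoded nucleosomes
  are appended: exact configured counts in the input, binomial recovery
  in ChIP (25% on-target, 2% cross-reactive). ChIP efficiency and
  background are free parameters of the design — the source experiments
  do not quantify them — and the defaults are documented as such.
* **Ground truth** — per-promoter differential labels with the congruence
  law P(gain) = P(loss) = 0.15, P(up | gain) = 0.7, P(down | gain) = 0.1
  (mirrored for loss), P(up or down | nc) = 0.1 each; fold changes 4×
  (gain/up) and 0.25× (loss/down) on Poisson count tables with a 1.3×
  day-7 depth factor.

Each pipeline stage draws from its own RNG stream (`seed` + fixed
per-stage offset), so adding a library never perturbs another and two
runs of the same configuration are byte-identical on disk.

**Sequence composition.** The A/T enrichment of fragile-particle DNA is
written onto the genome by `imprint_fragile_sequence()`: stable-nucleosome
footprints are re-sampled at the background composition and
fragile-particle footprints at background A/T + `at_bias_fragile` (0.05),
fragile taking precedence on overlap. Re-writing the stable footprints is
deliberate: it makes the configured fragile-vs-stable contrast exact even
where stable nucleosomes sit inside G/C-rich CGIs, at the cost of
flattening CGI G/C within nucleosome footprints. The CGI G/C guarantee
therefore applies to the `simulate_genome()` output, the compositional
contrast to the imprinted genome used for fragment-level A/T analyses.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: read-level errors and mappability, MNase
sequence preference beyond the imprinted A/T contrast, PCR duplication,
chromatin-state heterogeneity across cells, overlapping/nested genes, and
distance-dependent contact structure. Recovery results validate the
*analysis operations*, not the biology of any particular dataset.

## Analysis model and conventions

* Coordinates are 0-based half-open (BED); a TSS or motif anchor is a
  single base; a dyad is a single base.
* **Size classes**: sub ≤150 bp, mono 151–230 bp by default; the
  alternative printed variant (<150, 150–225) is the `"methods"` preset
  of `size_class_rule()`. Fragments above `mono_max` are kept in an
  `excluded` set because the 225–350 bp nucleosome-factor band at CTCF
  sites is analytically interesting.
* **Normalisation**: depth normalisation rescales a track so the implied
  fragment total is 10⁷; whether the canonical target applies to
  fragment counts or summed base coverage is ambiguous in the field's
  descriptions — fragment counts were chosen and the choice is flagged
  here. Spike-in scaling is `10⁶ / spike reads`, exact.
* **NDR definition**: −1 nucleosome = nearest called dyad upstream of the
  TSS (≤1 kb); NDR = [dyad + 73, TSS). The 73 bp half-width is the 147 bp
  core ÷ 2.
* **Scaled profiles** rebin the region interior to a fixed number of bins
  with length-weighted means, conserving interior mass to ~10⁻⁶
  relative; flanks are appended unscaled (±500 bp default, matching the
  window used for unscaled panels; the exact flank width is a free
  choice).
* **V-plots**: signed distance = (fragment midpoint − nearest anchor) ×
  orientation; nearest anchor by absolute distance with ties to the
  smaller coordinate (ties are rare after conservative-TSS isolation).
  Default grid x ∈ [−400, 400], y ∈ [40, 400], 5 bp cells, with edges at
  half-integer offsets so orientation flips reflect the grid exactly.
* **HDR contours**: binned Gaussian product-kernel KDE on the grid
  (bandwidth `sd · n^(−1/6)` per axis, overridable). The KDE is always
  computed from the binned mass rather than raw points — with 5 bp cells
  and bandwidths ≥10 bp the binning bias is negligible, and the cost is
  independent of library size. A level-p region is the smallest
  super-level set holding ≥p of estimated mass; nesting is structural.
* **Differential classification** uses the printed fold-change gate
  (≥2×) plus a two-sided exact binomial test of the day-N count share
  against the normalisation-implied null, BH-adjusted ("pAdj" without a
  named method is interpreted as BH). A negative-binomial GLM would add
  dispersion handling the simulated Poisson counts do not need; the
  fold-change gate dominates the classification either way.
* **Congruence enrichment**: expected = row × col / N over *classified*
  promoters (the background universe is a free choice; classified-only
  was chosen), log2(obs/exp), two-sided Fisher exact p.
* **Ties and degenerate input**: quartiles are rank-based with stable
  input order; equal-activity TSSs resolve to the smaller coordinate;
  even-length fragment midpoints use `floor((start+end)/2)`; anchors
  overlapping chromosome edges are skipped, not zero-padded; the
  asymmetry statistic guards empty windows with ε = 10⁻⁹.

## A worked run

```{r run, eval = FALSE}
cfg <- sim_config(seed = 1)
sim <- simulate_chromatin(cfg)
lib <- lapply(sim$libraries, function(x) split_by_genome(x)$target)
vapply(lib, function(f) median(f$end - f$start), numeric(1))
#>    input H3K115ac  H3K27ac
#>      164      158      165
```

The H3K115ac ChIP selects shorter fragments than its input while the
H3K27ac median stays within a few bases of it — the fragment-length
signature of a mark on fragile particles. The same run drives the NDR
V-plot mass fractions, the scaled-NDR geometry, the CTCF asymmetry and
the congruence recovery shown in `scripts/acceptance.R`.

## Problem sizes and runtime choices

The validation study uses the default configuration: 5 × 1 Mb
chromosomes, 300 genes, 150 enhancers, 200 CTCF sites, 10⁶ fragments per
library, seed 1 — about 20 s to simulate and ~2.5 min for the full
recovery suite. Byte-identity of reruns is exercised on a smaller
configuration (1 × 200 kb, 2 × 10⁴ fragments): determinism comes from the
fixed per-stage RNG streams and is not scale-dependent. Exhaustive oracle
sweeps (Fisher vs hypergeometric enumeration) cover all 2×2 tables with
N ≤ 40.

## Known limitations

* `call_nucleosomes_lite()` is a smoothing/peak-spacing caller adequate
  for phased, deeply covered landscapes; it does not model fuzziness or
  occupancy statistically.
* The exact-binomial differential test assumes Poisson-like counts; real
  ChIP replicates are overdispersed and would need a count model with
  dispersion.
* Spike-in normalisation is modelled at the genome-label level; hybrid
  genome alignment and barcode demultiplexing happen upstream of this
  package.
* The KDE bandwidth rule is the normal-reference rule; heavily
  multi-modal grids may prefer a smaller bandwidth, which is exposed as a
  parameter.
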