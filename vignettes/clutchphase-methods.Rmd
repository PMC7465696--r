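---
title: "Heterochromatin-like domains and clutch-level phase separation: methods"
author: "ClutchPhase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterochromatin-like domains and clutch-level phase separation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
    library(ClutchPhase)
    library(GenomicRanges)
    library(GenomeInfoDb)
})
```

## Scope and model

HP1 proteins and H3K9me3 are the hallmarks of constitutive
heterochromatin, but they also co-localize at thousands of sites outside
the pericentric, telomeric and nucleolar-organizer territories. Genomic
intervals co-enriched for at least one HP1 isoform and H3K9me3 in those
regions are *heterochromatin-like* domains and complexes: complexes span
10–100 kb, domains 0.1–1 Mb, and the largest domains exceed 1 Mb.
ClutchPhase implements the two halves of this picture:

1. a **genomic census**: windowed correlation of HP1 tracks with
   H3K9me3, interval calling by thresholding and intersection, size
   classification, and a census summary table, all relative to a
   constitutive-heterochromatin mask;
2. a **thermodynamic layer**: Flory–Huggins χ at four levels of
   description, the segregation product χN, the
   random-phase-approximation (RPA) spinodal of a diblock copolymer
   that sets the order–disorder threshold (χN)~ODT~ ≈ 10.5, lamellar
   composition profiles in the weak and strong segregation regimes, and
   a loop-extrusion mixing model.

Coordinates are 0-based half-open at every file boundary (BED/bedGraph
native); in memory the package uses Bioconductor `GRanges`/`Seqinfo`,
which are 1-based, and conversion happens only inside the readers and
writers. Nothing is stranded: all inputs are coverage-like.

## Binned tracks and the correlation survey

A `BinnedTrack` stores one mark's fold enrichment averaged into
fixed-width bins (`readBedGraph` weights each record by its overlap
with the bin; uncovered positions count as 0, because fold-enrichment
tracks are dense and absence means no enrichment). The last bin of each
chromosome clips at the chromosome end rather than padding. The
correlation window *is* the bin width — 5 kb is the preset scale for
mammalian and fly genomes, 200 bp for fission yeast.

`windowedCorrelation` computes Pearson *r* (not Spearman) between two
marks over the bins retained under a *region mode*: `whole_genome`,
`exclude_mask` (drop every bin whose midpoint lies inside the
constitutive-heterochromatin mask — the membership rule is the bin
midpoint, which is simple and order-independent), or `mask_only`.
Bins where both tracks are exactly zero are retained: co-absence is
informative about co-localization. Fewer than 3 retained bins, or a
zero-variance vector, is an error rather than an `NA`. No log transform
is applied before correlating; callers who want one can transform the
bin values themselves.

```{r coloc}
si <- Seqinfo("chr1", 2e7)
ranges <- c(defaultSizeRanges(), list(mask = c(1e6, 2e6)))
planted <- plantTruth(si, c(complex = 8, domain = 2, mask = 2),
                      sizeRanges = ranges, seed = 7)
mask <- planted[planted$sizeClass == "mask"]
mcols(mask) <- NULL
truth <- planted[planted$sizeClass != "mask"]
b <- simulateTracks(si, 5000, truth, mask = mask,
                    marks = c("HP1a", "H3K9me3"),
                    coloc = 0.5, noiseCV = 0.4, seed = 7)
surveyMatrix(bundleTracks(b)$HP1a, bundleTracks(b)$H3K9me3,
             bundleMask(b))
```

The characteristic ordering — whole-genome *r* above outside-mask *r*
when the mask is strongly co-enriched in both marks, and within-mask
*r* highest of all — is asserted in the test suite as an ordering on
synthetic data built to have that structure, not as any particular
coefficient values.

## The domain caller

`enrichedIntervals` segments maximal runs of bins at or above a
fold-enrichment threshold τ, merges runs separated by at most
`mergeGap` bp, and length-filters. There is no canonical τ for these
data, so the default is 2-fold and the value is recorded in the
output's metadata; the default merge gap is one bin width, the
smallest gap distinguishable at track resolution.

`callDomains` intersects the union over HP1 isoforms of their enriched
intervals with the enriched intervals of H3K9me3 (a call needs at
least one isoform; `combine = "intersection"` requires all isoforms
instead). Under `exclude_mask`, a call is dropped when at least 50% of
its length overlaps the mask (midpoint and any-overlap rules are
selectable). Survivors of at least `minSize` (10 kb) are classified
with half-open edges, which resolves touching class bounds
deterministically:

* complex: [10 kb, 100 kb)
* domain: [100 kb, 1 Mb)
* large domain: ≥ 1 Mb

`summarizeCalls` tabulates counts per class and mode and the share of
complexes in the closed interval [10 kb, 30 kb], the figure usually
quoted for the complex class; with no complexes the share is reported
as `NA` with an explicit flag rather than silently omitted.

```{r caller}
trs <- bundleTracks(b)
byMode <- list(
  whole_genome = callDomains(trs$HP1a, trs$H3K9me3, mask = bundleMask(b),
                             mode = "whole_genome"),
  exclude_mask = callDomains(trs$HP1a, trs$H3K9me3, mask = bundleMask(b),
                             mode = "exclude_mask"))
summarizeCalls(byMode)
```

## The synthetic-data generator

Every genomic claim in the test suite runs against
`plantTruth`/`simulateTracks`, so what the generator does and does not
emulate bounds what passing tests show about real data.

It emulates: co-enriched intervals in the three size classes (sizes
uniform within each class range, non-overlapping, minimum-gap
separated); a constitutive-heterochromatin mask enriched in every mark;
interval-granularity co-localization (`coloc` is the probability an
interval carries all marks rather than one random mark — matching the
domain-level intersection logic of the caller); multiplicative
log-normal noise with mean 1 (multiplicative, not additive Gaussian,
because fold enrichment is a ratio and must stay non-negative); and a
bin-level intensity profile inside the mask shared across marks
(default CV 0.5), since constitutive heterochromatin's locus-to-locus
enrichment is common to the mark and its readers — this is what makes
within-mask correlations approach 1.

It does not emulate: read-level sampling noise, fragment-length or GC
structure, input-normalization artifacts, replicate structure, or
enrichment that decays toward interval edges. Recovery results on
these tracks are therefore statements about the caller's interval
algebra and thresholds, not about peak-calling on raw reads.

Planted starts and sizes are snapped to a grid equal to the intended
bin width (default 5 kb). Binned tracks cannot represent sub-bin
boundaries, so off-grid truth would make "exact recovery" undefined at
the edges; with snapping, noise-free recovery is exact and the
recovery tests assert equality rather than a fuzzy margin. One RNG
stream drives each bundle, seeded once, and the caller's RNG state is
saved and restored, so identical parameters give bit-identical bundles.

Default study conditions: enrichment mean 8-fold over a background of
1 (a strong but realistic ChIP enrichment), noise CV 0.3, genomes of
20–50 Mb at 5 kb bins. The recovery and ordering tests use 10–20
replicate seeds at these sizes, which keeps the whole suite well under
a minute of simulation time.

## Flory–Huggins χ, four ways

All four forms are plain vectorized functions.

* `chiLattice`: mean-field incompressible lattice,
  χ = (z/k~B~T)[ε~AB~ − ½(ε~AA~ + ε~BB~)].
* `dispersiveContactEnergy`: London-dispersion pair energy
  ε~ij~ = −(3/4)·(I~i~I~j~/(I~i~+I~j~))·α~i~α~j~/r⁶. This is a
  *per-pair* energy; summation over pairs is left to the caller to
  keep the operation referentially transparent.
* `chiDispersive`: χ = (3/8)·(I/k~B~T)·(z/V²)·(α~A~ − α~B~)², with I
  the mean ionization potential and a warning when the two potentials
  differ by more than 10%, the stated domain of the shared-I
  approximation. The result is non-negative: purely dispersive blocks
  always have some tendency to demix. Note a tension we document
  rather than resolve: substituting the pair energies into the lattice
  form with I~i~ = I~j~ and V = r³ yields a coefficient 3/16, while
  the printed coefficient of the dispersive formula is 3/8; the
  difference amounts to a contact-counting convention that is not
  stated with the formula. `chiDispersive` implements 3/8 as printed.
* `chiEmpirical`: χ = α/T + β, the empirical enthalpic/entropic form.

### The clutch decomposition

For chromatin the repeat unit is not a monomer but an oligo-nucleosomal
clutch of 2–10 nucleosomes (modelled at six). `chiClutch` computes

χ~HC~ = [H~CD~ + H~CSD~ − H~COMP~ − m·H~TL~]/T + S~COMP~,

with m = 2 when the domain/complex is flanked by euchromatin on both
sides (it pays the terminal-linker penalty twice) and m = 1 otherwise.
Conventions, since none are fixed by the decomposition itself:

* **Units**: H terms are energies divided by the Boltzmann constant
  (kelvin); S~COMP~ is in units of k~B~; T in kelvin. χ is then
  dimensionless and the 1/T scaling is literal.
* **Signs**: favourable binding contributions (chromodomain–H3K9me3,
  chromoshadow dimerization) enter as positive magnitudes; the
  compaction and terminal-linker potentials oppose separation and are
  subtracted. The sign of S~COMP~ is left to the caller: compaction
  entropy is "given up", which argues for a negative value, but the
  decomposition does not fix it, so neither does the function.
* With every term zero (no HP1), χ~HC~ = 0: absent the bridging
  protein, a K9me3-marked clutch is thermodynamically equivalent to a
  euchromatic one.
* Severing the terminal linker (H~TL~ → 0) can only raise χ~HC~ —
  the algebraic counterpart of fragmentation strengthening
  compartmental segregation.
* No HP1–HP1 cooperative term is included; adding one as an extra
  positive contribution to the numerator is a caller-side extension.

The function makes no claim about biological magnitudes: it computes
χ from user-supplied terms only.

## The RPA spinodal and (χN)~ODT~

`debyeG` implements the Debye-type block correlation function
g(f, x) = 2(fx + e^(−fx) − 1)/x², with a series branch for fx < 10⁻⁴
(g = f²(1 − u/3 + u²/12 − u³/60), u = fx) because the direct
expression suffers catastrophic cancellation near zero; the threshold
is tested against the exact branch at the seam. `rpaF` is the Leibler
correlation quotient

F(x, f) = g(1,x) / [g(f,x)·g(1−f,x) − ¼(g(1,x) − g(f,x) − g(1−f,x))²],

and `spinodal` minimizes F(x, f)/2 over x on a log-spaced grid (512
points over x ∈ [10⁻³, 10³]; log-spaced because F diverges as x → 0)
followed by Brent refinement of the best grid cell. At f = 1/2 this
gives (χN)~s~ = 10.4949 — the classical "phase separation at χN around
10.5":

```{r spinodal}
spinodal(0.5)
```

Chromatin fibres are semi-flexible, so heterochromatin-like and
Polycomb domains have their own thresholds distinct from the flexible
Gaussian-chain value. The package therefore treats (χN)~ODT~ as a
parameter everywhere, with `chiNodtRPA()` (the memoized f = 1/2
spinodal) only as the default; no semi-flexible correction is invented.

`classifySegregation` splits the ordered regime at `strongRatio` × ODT
(default 5): below the threshold disordered, then weak/"wavy"
(liquid-like interfaces), then strong/"sharp". The factor 5 is a
configurable stand-in for "much greater than" — the qualitative
distinction is what matters, and the boundary is exposed rather than
hidden.

## Lamellar profiles

`lamellarProfile` tabulates ϕ~A~(r⊥) across the lamellae. In the weak
regime the profile is a single harmonic, ϕ = f + A·cos(q\*r) with
A = min(f, 1−f)·√(1 − ODT/χN) — a phenomenological amplitude law
chosen for continuity at the threshold (A → 0 exactly at ODT, hence
the flat profile there) and saturation well above it; theory fixes
only the scaling near the threshold, not a closed form. In the strong
regime the profile is a duty-cycle-f square wave smoothed at each edge
by ½[1 + tanh(2(r − r~edge~)/w)] with the standard strong-segregation
(Helfand) interface width w = 2b/√(6χ); adjacent-period images are
summed so the tanh tails wrap periodically, and b (the repeat length)
defaults to 1 so r is in repeat units. The lamellar period is taken
from the spinodal wavevector, D = 2πR~g~/√x\*(f) with R~g~ = b√(N/6).
Positions exclude the endpoint so they tile whole periods exactly and
the spatial mean of ϕ~A~ equals f to numerical accuracy; profile
sharpness (max |dϕ/dr|) grows monotonically with χN through the
wavy-to-sharp progression, which the tests check across
χN ∈ {11, 20, 50, 100}.

## Loop-extrusion mixing

Cohesin-driven loop extrusion converts ATP hydrolysis into work that
mixes heterochromatin-like blocks with euchromatin. The available
descriptions are qualitative, so `extrusionMixing` uses the simplest
monotone form: an activity E subtracted from the segregation product,
χN~eff~ = χN − E, with a call separated iff χN~eff~ ≥ (χN)~ODT~. This
reproduces the three cohesin regimes — no extrusion (cohesin loss)
reconstitutes even small complexes; moderate activity mixes only
small-N complexes; unrestrained activity mixes large domains too — and
makes the smallest blocks mix first at any fixed E:

```{r mixing}
extrusionMixing(chi = 0.5, N = c(100, 25), E = 5)
```

Any alternative monotone map of activity to effective χN can be
emulated by transforming E before the call.

## Numerical choices and degenerate inputs

* Thresholding is ≥ τ, merging is gap ≤ mergeGap (one more bin splits),
  class edges are half-open — every boundary case is deterministic and
  pinned by a test.
* `spinodal` refuses a minimum at the edge of the x grid rather than
  returning it, and reports the grid diagnostics in the error.
* Correlation with fewer than 3 bins, or zero variance, errors;
  an empty call list summarizes to zero counts with an `NA` fraction
  and an explicit flag.
* `plantTruth` reports roughly how many intervals would fit when a
  packing is infeasible instead of looping forever (200 placement
  attempts).

## Known limitations

* The census on real data depends on upstream processing (peak
  segmentation, input normalization) that published summaries leave
  unstated; with externally processed tracks the pipeline reproduces
  layouts and orderings, not any particular published counts. The
  package treats fold-enrichment values as given and records which
  normalization the caller declares, nothing more.
* The RPA spinodal is the flexible-chain, bulk result; fluctuation
  corrections and the full mesophase diagram (cylinders, gyroid,
  spheres) are out of scope, as is any semi-flexible correction to the
  threshold (parameterized instead).
* The extrusion model is an energy bookkeeping device, not a dynamical
  model of cohesin.
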