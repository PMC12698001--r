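---
title: "Detecting introgression with introkit: models, parameters and design choices"
author: "introkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting introgression with introkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introkit)
```

# Scope and data model

introkit implements an end-to-end workflow for detecting gene flow
between species from biallelic SNP genotypes: four-taxon site-pattern
statistics with jackknife uncertainty, windowed scans, haplotype
localization from fixed differences, gene-tree displacement, crown-age
dating, coding-sequence analysis, and tract-decay reasoning.

The central container is `GenotypeExperiment`, a
`RangedSummarizedExperiment` whose single assay holds ALT-allele
dosages (0/1/2/`NA`) for sites (rows, a width-1 `GRanges` in 1-based
VCF coordinates) by individuals (columns, each assigned to one
species/population group). Two conventions run through the package:

* **Coordinates** are 1-based inclusive internally (the VCF
  convention); every BED output converts to 0-based half-open (the BED
  convention). These are the only two standards the package touches.
* **Phasing is ignored**: `0|1` and `0/1` both mean one ALT allele.
  All statistics here are functions of genotype dosages and group
  allele frequencies, so phase carries no extra information for them.

Multiallelic and non-SNP VCF records are skipped (with a logged
count), not split: the downstream statistics are defined for biallelic
sites only. Genotype likelihoods, BCF and indexed access are out of
scope.

# The site-pattern statistics

All four-taxon statistics start from per-site derived-allele
frequencies in P1, P2 (putative recipient), P3 (putative donor) and
the outgroup (`derivedFrequencies()`). The derived allele is the
outgroup *minor* allele, with ties broken toward ALT; sites where any
group has zero called alleles are excluded and counted. Polarization
by outgroup minor allele is the standard convention for these
statistics; it matters only through the pattern weights, and f4-type
products are invariant under per-site polarity flips.

**D.** With weights `C_ABBA = (1−p1)·p2·p3·(1−p4)` and
`C_BABA = p1·(1−p2)·p3·(1−p4)`,
`D = Σ(C_ABBA−C_BABA)/Σ(C_ABBA+C_BABA)`. The frequency-weighted
(population-sample) form is used rather than single-haplotype
sampling: with population samples per taxon it is the appropriate
estimator, and it reduces to the classical counts when each group is a
single haploid. When every weight is zero the statistic is undefined
and returned as `NA`, never a crash.

**f_d.** The numerator is the same ABBA excess; the denominator
substitutes the *donor-like* population `P_D = argmax(p2, p3)` for
both P2 and P3 at each site, i.e. the value the numerator would take
under complete sharing. Windows with a non-positive numerator report
`f_d = 0` (the statistic estimates an introgressed *fraction*, so
negative ABBA excess carries no such interpretation), and a zero
denominator with positive numerator yields `NA`.

**f4-ratio.** The admixture proportion is estimated as
`α̂ = f4(P1,P2;P3a,O)/f4(P1,P3b;P3a,O)` with `P3a`/`P3b` disjoint
random halves of P3's called alleles at each site (a hypergeometric
split, re-drawn per site under the user's seed; sites with fewer than
two called P3 alleles are dropped). Splitting the donor sample keeps
the numerator's and denominator's sampling noise independent, which is
what makes the ratio consistent. The estimator is validated by
simulation recovery (planted α of 0, 0.25, 0.5 and 1 are recovered to
within ±0.05 at 10^5 sites, averaged over 20 seeds) rather than by a
formula identity. One caveat established while testing: if P2's
genotype *calls* are literal copies of the P3 individuals' calls, the
shared sampling noise between P2 and the P3a half inflates the ratio
upward; the full-admixture limit is meaningful at the
population level (P2 *drawn from* the donor population), which is what
the tests exercise.

**Block jackknife.** Blocks are contiguous runs containing equal
numbers of *informative* sites (equal-count, not equal-bp: this
stabilizes the leave-one-out variance when informative sites are
unevenly spread; only the block count — 200 by default — is a
published convention). The standard error is the delete-one jackknife
`SE = sqrt((n−1)/n · Σ(θ(i) − θ̄)²)` and `Z = θ/SE`; degenerate
zero-variance cases return `SE = 0` with `Z = NA`.

# Window scans and outlier calls

Windows are non-overlapping 10-kb tiles anchored at coordinate 0 on
each chromosome. Published scans of this kind state the window size
but rarely the anchor or step; fixed tiling from 0 is the simplest
reproducible choice, and each SNP belongs to exactly one window.
Windows with fewer than `minSnps` (default 10) usable sites report
`NA`: f_d in sparse windows is noise-dominated. The outlier threshold
is the linear-interpolation empirical quantile (R type 7) of all
non-`NA` windows, with ties flagged inclusively — again, the estimator
behind a reported "99.9th percentile outlier" is rarely stated, so
ours is declared rather than inferred. The optional gene annotation
flags windows overlapping a user interval expanded by `proximity`
(default 10 kb) per side.

# Haplotype localization

`diagnosticSites()` retains sites where lineage A carries one allele
at frequency ≥ τ_A, lineage B the other allele at ≥ τ_B, with
per-group missingness (fraction of individuals uncalled) at most a
cap. Defaults are τ = 0.90 with τ = 1 meaning "fixed"; putative
recipients must be excluded from both groups by the caller, since
including them would dilute the very contrast being tested.

`paintAndCallBlocks()` assigns each recipient at each diagnostic site
a state in {donorHom, het, backgroundHom, missing} from its
donor-allele dosage. Blocks are maximal runs of donor-carrying sites
(≥1 donor allele) tolerating up to `gapTolerance` intervening
zero-donor sites (default 0). Missing sites neither extend nor break a
run, and do not count toward the gap: an uncalled genotype is evidence
of nothing. Visual delineation of such blocks in published figures is
inevitably somewhat subjective; the explicit run/gap rule here is the
reproducible replacement, and the default of zero tolerated gaps is
the most conservative choice. Species-level painting is a majority
vote across individuals (missing excluded, ties → het).
`sharedCore()` intersects blocks across species — the short central
interval every carrier retains, which is where a selected functional
variant is expected to sit.

# Gene-tree displacement

The gene-tree signature of introgression is a recipient taxon falling
on the branch normally occupied by the donor clade. Given a rooted
gene tree, species tree and donor clade C (monophyletic in the species
tree), `displacedTaxa()` applies two set-theoretic rules in order:

1. **Intruders**: if the gene-tree subtree spanned by C's MRCA
   contains non-members, those are the displaced set — something
   foreign sits inside the donor clade.
2. **Unexpected grouping**: otherwise walk rootward from C's MRCA; the
   first gene-tree clade containing C whose leaf set is *not* a
   species-tree clade contributes its extra leaves, and reaching a
   species-tree-concordant ancestor stops the walk with an empty
   result.

A support-value-aware test was deliberately not used: the assessment
this mirrors is topological, and the set-theoretic rule is
deterministic and testable — simulated grafts into the donor clade are
recovered exactly (100/100 random 20-leaf trials in the test suite),
and concordant trees yield no false positives. Displacements onto
branches *above* the donor clade are attributed to the larger clade,
not to C; call the function with that larger clade to probe them.

# Divergence dating

`calibrateNodeAges()` scales relative node depths by external
crown-age calibrations: relative depth = (mean path length to
descendant tips) / (mean root-to-tip path length), age = relative
depth × crown age, reported as (min, mean, max) across the calibration
set. On a non-clock tree the mean-path rule is a declared, monotone
substitute for model-based rate smoothing (penalized-likelihood dating
is out of scope); a repair pass clamps each child's relative depth to
its parent's so ages never increase tipward. Ages are exactly linear
in the crown age, which the tests assert.

# Coding sequences

`spliceAndTranslate()` concatenates exons in genomic order,
reverse-complements minus-strand models, and translates with the
standard genetic code (Biostrings); codons containing N or IUPAC
ambiguity translate to X, and a trailing partial codon is dropped with
a warning. `diagnosticResidues()` reports alignment positions where
all non-missing focal species share a residue absent from every
background species; X and gaps are missing and never match, so
within-species polymorphism (encoded X) can never create a spurious
diagnostic. The default tolerance of zero missing focal species is
strict; it is configurable because real alignments from low-coverage
samples have uncalled sites whose resolution (e.g. by read inspection)
lies outside this package.

# The simulator

`simulateGenotypes()` is the package's ground-truth generator, built
to produce the statistical structure the analyses assume without
requiring any external data:

* site positions uniform without replacement on `[1, chromLength]`;
* per-site ancestral ALT frequency from Beta(0.8, 0.8) — a mildly
  U-shaped site-frequency spectrum resembling a standing-variation
  panel;
* frequencies evolve along the species tree by Gaussian increments
  with variance `driftScale × branch length`, clamped to [0, 1]. This
  truncated-Gaussian drift is a deliberate substitute for a coalescent
  engine: it is fast, exactly seedable, and produces the two features
  the methods consume — near-fixed differences accumulating on long
  inter-generic branches, and shared polymorphism on short ones. It
  does not model linkage, recombination or mutation, so decay of LD
  and tract-length distributions are *not* emulated (the tract-decay
  module models those separately and explicitly);
* diploid genotypes are binomial draws from tip frequencies;
* an introgression event replaces the recipient's tip frequency with
  the donor's at each tract site independently with probability ρ
  (`mode = "fixed"`), inducing exactly the donor–recipient allele
  sharing that D/f_d detect; `mode = "polymorphic"` instead threads a
  single donor haplotype through named carrier individuals with 0, 1
  or 2 copies, reproducing incomplete-fixation genotype patterns
  (one homozygous carrier, several heterozygotes, one ancestral
  homozygote);
* `quantizeTips = TRUE` rounds tip frequencies to 0/1 after drift: the
  noiseless fully-lineage-sorted limit in which fixed differences and
  planted tract bounds are exact. The localization tests run in this
  limit because their assertion is exactness; what passing them shows
  about real data is that the *coordinate bookkeeping* is correct, not
  that real backgrounds are noiseless.

Default study conditions used by the tests and the acceptance script:
a pectinate (((P1,P2),P3),O) tree with branch lengths 1/2/3/7 (in
drift-time units), `driftScale = 0.08`, four diploids per species, and
20,000 sites per Mb. These were chosen once to give realistic
intermediate differentiation — ingroup pairs sharing most
polymorphism, genera nearly fixed at a substantial fraction of sites —
and are not tuned per analysis. Null calibrations use 10^5 sites so
that 200 jackknife blocks each contain hundreds of informative sites;
planted-signal runs use a 1-Mb chromosome with a single 10-kb tract at
ρ = 0.9, i.e. a strong but incompletely retained introgression pulse.
Because sites are independent in this generator, jackknife blocks are
trivially exchangeable; on real linked data the equal-count blocks are
the device that absorbs LD.

`simulateGeneTrees()` returns species-tree topologies with lognormal
branch-length jitter; displacement events prune each recipient and
re-graft it onto a uniformly chosen edge inside the donor clade's
subtree — the generative counterpart of the detection rule above.

# Tract decay and transfer order

`simulateTractDecay()` models the erosion of an introgressed tract
around a selected focal site: crossover breakpoints accumulate along
the tract as a homogeneous Poisson process of intensity r·t per unit
length, and the surviving tract is the interval between the nearest
breakpoints flanking the focal site (whose donor allele is assumed
kept by selection). Unlinked donor DNA elsewhere in the genome is
deliberately ignored — the model asks only how much of the *selected*
haplotype survives. Units are abstract (only the product r·t·length
matters); mapping to bp and cM is the user's. The one-sided mean
flank length has the closed form `(1 − e^(−rtf))/(rt)` for available
flank f, which the Monte-Carlo implementation matches within three
standard errors at 10^5 replicates in the tests — the simulation and
the formula are independent routes to the same quantity. Chaining
rounds (serial transfer through successive recipients) composes decay
on the surviving tract; by the superposition property of Poisson
processes, two chained rounds equal one round of doubled duration,
which is also asserted.

`scenarioEventCounts()` books the number of transfer events per
recipient under three serial-introgression topologies (independent:
1 each; hub: 1 then 2 each; chain: 1, 2, …, k), and
`inferTransferOrder()` ranks recipients by remaining block length —
earliest recipient, largest surviving haplotype. The ranking is
explicitly a heuristic under the decay model (the documentation labels
it so): with stochastic tract lengths, single realizations invert the
expected order in a sizeable minority of cases, which the test suite
quantifies rather than hides.

# Numerical and degenerate-input choices

* Undefined statistics (all-zero weights, zero denominators below
  1e−12, zero jackknife variance) return `NA` with the partial sums
  preserved, never errors.
* Quantiles: R type 7 (linear interpolation), ties inclusive.
* NJ branch lengths are clamped at 0; negative estimates on additive
  data indicate noise, not signal.
* Monotonicity repair in dating clamps children to parents rather than
  re-fitting, preserving linearity in the crown age.
* Simulator positions are unique integers (collisions avoided by
  sampling without replacement), keeping VCF sites distinct and
  strictly sorted.
* All stochastic functions take explicit integer seeds; identical
  seeds give bitwise-identical output including VCF text.

# Known limitations

* The drift simulator has no linkage, so window-scan null
  distributions on real data will be wider than simulated ones;
  calibrations here validate correctness of the machinery, not
  genome-specific significance thresholds.
* f_d per-window site-inclusion rules vary subtly among published
  implementations (treatment of uncalled groups, polarization,
  minimum-site rules); ours are declared above and in the function
  documentation, and no claim is made that they byte-match any
  particular external tool.
* Crown-age scaling is a display/approximation device; it does not
  replace model-based divergence dating with rate variation.
* The displacement rule attributes grafts onto branches above the
  donor clade to the larger containing clade (see above), and mixed
  graft positions for multiple recipients are reported from the
  deepest unexpected grouping only.
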