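---
title: "Simulating translocation crosses, heterokaryons, and RIP in Neurospora"
author: "octadkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating translocation crosses, heterokaryons, and RIP in Neurospora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octadkit)
```

## The system being modeled

A chromosome translocation heterozygote (`T x N` cross) forms a quadrivalent
at meiosis I whose centromeres can disjoin in two ways.  *Alternate*
segregation sends both translocated chromosomes (`T^D`, `T^R`) to one spindle
pole and both normal-sequence homologs (`N^D`, `N^R`) to the other, yielding
eight parental-type nuclei (4 `T` + 4 `N`) after meiosis II and the
postmeiotic mitosis.  *Adjacent-1* segregation pairs each translocated
chromosome with the non-homologous normal chromosome, yielding eight
nonparental nuclei: four carrying a duplication (`Dp`, segment copy number 2)
and four the complementary deficiency (`Df`, copy number 0).  `Df` ascospores
are inviable and stay white, so in *N. crassa* an insertional (`IT`) or
quasiterminal (`QT`) translocation cross produces 8B:0W and 4B:4W asci at
comparable frequencies, while a reciprocal translocation (`RT`) cross
produces 8B:0W and 0B:8W — in an `RT`, both adjacent-1 products are
unbalanced (`Dp1/Df2` and `Dp2/Df1`), so the whole ascus dies.

Breakpoint junctions diagnose the products: an `IT` is defined by three
junctions (A on the deleted donor chromosome; B and C flanking the insertion
in the recipient), a `QT` or `RT` by two (A and B).  A `T` nucleus carries
all of them, `Dp` carries B (and C) but not A, `N` none, and `Df` only A.
Junction *presence* in pooled DNA cannot distinguish a `[T + N]` from a
`[Dp + Df]` nuclear mixture — both unions are the full set — which is the
central inference problem the package's classifier addresses.

*N. tetrasperma* packages the eight nuclei as four binucleate ascospores,
each receiving a nonsister *mat A* + *mat a* pair, so one spore founds a
self-fertile heterokaryotic mycelium (pseudohomothallism).  A `T x N` cross
in this species can therefore yield `[T + N]` and `[Dp + Df]` heterokaryons,
and self-crosses interconvert the two classes, because the `[Dp + Df]`
karyogamy reconstitutes exactly the `T x N` zygote chromosome complement.

## The meiosis model

`simulate_meiosis_octet()` works at chromatid resolution:

* Each of the four relevant chromosomes contributes two sister chromatids.
* With probability `c_donor` (resp. `c_recipient`) a single crossover in the
  interstitial region between centromere and breakpoint exchanges the
  breakpoint-distal content between one chromatid of each homolog.  At most
  one crossover per region per meiosis is modeled: one exchange suffices to
  generate the observed 6:2 and 2:6 ascus classes, and the regions involved
  are short relative to the genetic map, making double exchanges rare.
  Donor and recipient crossovers are independent.
* Meiosis I assigns centromeres to poles by the alternate/adjacent-1 pattern,
  drawn with probability `p_alt` (default 0.5, the equal-likelihood case;
  set 0 or 1 to force a pattern).  Adjacent-2 segregation (homologous
  centromeres to the same pole) is not modeled; it is rare in Neurospora
  translocation crosses.
* Meiosis II separates sisters with a random assortment at each pole, which
  is what converts a crossover into second-division segregation, and the
  postmeiotic mitosis duplicates each product into adjacent positions.
  Positions 1-4 descend from pole 1, 5-8 from pole 2.
* The mating-type locus always segregates at the first division (its
  centromere linkage is tight and, in *N. tetrasperma*, recombination on the
  mat chromosome is blocked), so every octet carries 4 *mat A* + 4 *mat a*
  in pole blocks, and markers ride with the parent's pole.

The model was validated against an exhaustive enumeration of the chromatid
assortments (the test suite's independent oracle): for every segregation
pattern x crossover configuration the simulated octet compositions coincide
with the enumerated set, and without crossovers the expected black-spore
fraction of a crassa `IT x N` cross is `p_alt + (1 - p_alt)/2` (0.75 at
`p_alt = 0.5`).

## Packaging and its anomalies

`package_ascospores()` emits eight uninucleate spores in octet order for
`species = "crassa"`.  For `"tetrasperma"` it pairs the j-th nucleus of the
pole-1 lineage with the j-th of pole 2 — deterministic nonsister pairing; a
`pairing = "random"` option permutes the pole-2 lineage, and both guarantee
one nucleus of each mating type per spore.  Two anomalies are modeled:

* `replacement_prob`: each dikaryotic spore is independently replaced by two
  smaller homokaryotic spores, producing the 5-8-spored asci seen in this
  species.  The *Eight-spore* (`E`) mutant elevates this; no quantitative
  rate has been published, so the preset `e_mutant_replacement_prob = 0.15`
  is an explicitly arbitrary working value.
* `anomaly_prob`: once per ascus, one binucleate spore may receive a third
  nucleus from an adjacent spore.  This conserves the eight nuclei and is
  the route by which rare triple heterokaryons (e.g. `[T a + N A + Df A]`)
  arise from a 6:2 octet.

Spore viability is pluggable.  The default `"union"` rule lets nuclei
complement within a spore (a `[Dp + Df]` binucleate spore is viable), which
reproduces the recovery of complementary-duplication/deficiency
heterokaryons.  The `"autonomous"` rule requires every nucleus to carry a
full complement; it exists because one interspecies `RT`-like cross yielded
only white spores, a result attributed to a segregation mutation rather than
to spore autonomy — the package exposes both rules and takes no position.

## Vegetative phase

`evolve_nuclear_ratio()` iterates the replicator map
\(\rho' = \rho f_1 / (\rho f_1 + (1-\rho) f_2)\) per nuclear division cycle.
`sample_conidial_derivatives()` draws, per conidium, a nucleus count `k`
from a zero-truncated Poisson (rate `mean_nuclei = 2.5`; the real
distribution is unmeasured, and this is the main free parameter controlling
the homokaryotic-conidium frequency, e.g. \(\rho^k + (1-\rho)^k\) at fixed
`k` for two components) and fills it multinomially from the component
proportions weighted by division fitness.  A germling must contain a
division-competent nucleus *and* a full segment complement among its
competent nuclei — a bare `Df` conidium never grows into a derivative,
which is why a `[Dp + Df]` heterokaryon yields self-sterile homokaryons
only of the `Dp` mating type, and why `[N + Df]` derivatives (PCR pattern:
junction A alone) betray a third `Df` nucleus.

The published observation that `[Dp(B362i) + Df(B362i)]` heterokaryons make
*only* self-sterile conidia is representable as `division_fitness = 0` for
the `Df` nucleus.  Two mechanisms have been proposed (disruption of
co-evolved internuclear interactions vs. deletion of a nucleus-limited
division gene); both collapse onto the single fitness knob, and the package
makes no mechanistic claim.

`self_cross_zygote()` wires the sexual phase: it picks one competent
nucleus of each mating type and flags RIP exposure for any nucleus carrying
a segment at copy number 2 — hence RIP can occur in `[Dp + Df]` but never
`[T + N]` self-crosses.  `msud_fertility()` models meiotic silencing by
unpaired DNA: a segment is unpairable iff its total copy number over the
zygote is odd (three copies in `Dp x N`: barren; two copies in `T x N` or a
`[Dp + Df]` self-cross, where the quadrivalent pairs them: fertile).  We
deliberately use this zygote-level parity rule rather than comparing the two
haplotypes' copy numbers, because `[Dp + Df]` self-crosses are productive —
their zygote is chromosomally a `T x N` zygote.  Suppressor backgrounds are
scalar strengths (`msud_presets`: OR 1, Esm 0.5, Sad 0.1) against a barren
threshold of 0.5, chosen so that full silencing is barren and Sad-suppressed
crosses are fertile; per-duplication variation in Esm crosses is not
modeled.

## Genotype inference

`infer_heterokaryon_genotype()` encodes the discrimination procedure as a
flagged rule cascade (deliberately not a Bayesian posterior — the published
calls are rule-based and auditable).  Junction patterns are interpreted
against the rearrangement's *assayable* panel, which for two presets is
smaller than the model-level junction set (no B/C assay for `UK14-1`, no C
for `IBj5`); with a panel of `{A}` alone, `Dp` and `N` patterns coincide and
only mating-type logic remains.  Key choices:

* `n_min = 10`, `alpha = 0.05`: a single-class result is called `[Dp + Df]`
  (or `[T + Df]`) without hedging only when at least `n_min` derivatives
  were typed or the exact-binomial skew probability
  (`balanced_split_probability()`, two-sided tail at p = 0.5, capped at 1)
  falls below `alpha`; otherwise the `[X + N]` alternative is attached as a
  "not excluded" flag.  The defaults mirror the published treatment of
  n = 6 single-class results as inconclusive and n >= 10 as conclusive.
* The unseen partner of a single evidenced class is `Df` only when junction
  A is present in the heterokaryon's own pattern; otherwise `Df` would
  contribute an A junction the heterokaryon DNA does not show, and the
  partner is called `N`.
* One informative derivative is never enough to name the partner: the call
  is `[? + X]`.
* Contradictory patterns produce multi-nucleus calls (the triple
  heterokaryon) rather than errors, and an A-only derivative is always
  interpreted as a `[N + Df]` heterokaryotic germling, never as a viable
  `Df` homokaryon.

## RIP simulation and detection

`rip_mutate()` applies one round of repeat-induced point mutation to a
duplicated sequence: per copy, every eligible site mutates with probability
`rate`, with opposite strand polarity between the two copies by default —
one copy accumulates only C-to-T changes on the top strand, the other only
G-to-A (C-to-T on the bottom strand), the pattern observed when both copies
of a duplication are recovered from one cross.  Dinucleotide context
preference is real in this process but unquantified for these alleles, so
it is off by default.  `classify_substitutions()` is the detector: every
differing aligned column becomes an event classed as `G>A`, `C>T`,
`other-transition`, or `transversion` on the top strand; transitions at G:C
sites in the non-RIP direction (`A>G`, `T>C`) are excluded from
`rip_fraction`.  Because two events can hit one codon, the report carries
both the event count (`n_exonic`) and the affected-codon count
(`n_codons_affected`).  Codon effects are rendered in the conventional
compact style (`H22Y`, `Q122*`, `N97N`), 1-based on the spliced CDS; exon
intervals are 1-based closed internally and 0-based half-open in BED files.

Input pairs are assumed co-linear and pre-aligned (the intended use is
alleles of one gene); equal length is enforced, and columns containing gaps
or ambiguity codes are excluded from event calling.

## Synthetic data and what passing tests do (and do not) show

`generate_fixtures()` builds everything the test suite needs offline: toy
genomes whose junction "amplicons" are deterministic motifs (in-silico PCR
is substring detection — sufficient for presence/absence logic, with no
primer thermodynamics), observation tables simulated from known heterokaryon
genotypes, ascus tallies, and RIP'd allele pairs.  Generation is
byte-identical for a fixed config; motif construction uses a keyed generator
independent of R's RNG so fixtures never perturb simulation seeds.

The generator emulates the *structure* of the experimental data — octad
composition, packaging statistics, derivative tables, substitution spectra —
under idealized assumptions: no vegetative drift of nuclear ratios during
sampling, no PCR failure or contamination, no secondary mutations, and
marker-free backgrounds.  Passing the closed-loop tests therefore shows the
algebra and inference are self-consistent, not that the free parameters
(`mean_nuclei`, `e_mutant_replacement_prob`, fitness values) are
quantitatively calibrated: the published wet-lab tallies have unknown
nuisance parameters and are reproduced qualitatively (class
presence/absence), not numerically.

## Problem sizes and numerical notes

The shipped tests use 2,000 asci for rate-recovery checks (binomial
standard-error tolerance of three SEs), 30-40 octets per
segregation/crossover case against the enumeration oracle, 20 derivatives
per genotype for classifier round trips, and 200-600 bp synthetic alleles
for RIP round trips — sizes at which every stochastic tolerance is
comfortably met while the whole suite runs in a few minutes on one CPU.
All simulators consume R's global RNG (`set.seed()` for reproducibility);
`simulate_cross_tally()` additionally records its seed in the returned
object.  Probabilities are validated to `[0, 1]` at construction;
degenerate inputs (empty spores, all-zero fitness, same-mating-type
crosses, misaligned sequence pairs) raise immediate errors rather than
propagating.

## Known limitations

* No spindle geometry, ascus developmental timing, or adjacent-2
  segregation; multi-crossover configurations are out of scope.
* Markers do not recombine; they ride with the mating type's pole.
* The heterokaryon model has no spatial (hyphal network) structure and no
  expression-level mating-type bias; biased ratios are representable only
  through initial proportions and fitness.
* Genome-scale RIP indices (TpA/ApT composites) and RIP's homology search
  are not modeled.
* The classifier infers one rearrangement at a time.
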