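---
title: "Methods: bulked-segregant SNP-index mapping of a dominant locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bulked-segregant SNP-index mapping of a dominant locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaqtl)
```

## The mapping problem

A fruit-colour locus segregates in a biparental zucchini-type cross: a
light-green inbred parent crossed to a yellow inbred parent gives an
all-yellow F1, a ~3:1 yellow:green F2 and a ~1:1 backcross to the green
parent — the signature of a single fully penetrant dominant nuclear locus
(call it *Y*). `bsaqtl` implements the downstream mapping arithmetic of such
a study as reusable, tested functions, together with a synthetic-data
generator so that every stage can be exercised and validated without any
sequencing data: pooled-sequencing bulked-segregant analysis (BSA) with
SNP-index statistics, Mendelian segregation tests, recombinant-based
interval narrowing, co-dominant InDel marker selection, and the
spectrophotometric pigment and colorimetric phenotype formulas.

## The cross and meiosis model

Individuals are mosaics of the two founder genomes. Each haplotype is a
run-length encoding of parental origin along a chromosome; meiosis draws a
Poisson number of crossovers per chromosome with mean `length_cM / 100` and
places them uniformly on the genetic map (linear cM–bp interpolation), i.e.
a no-interference (Haldane) model. This is the simplest standard choice;
real plant meiosis shows positive crossover interference, so the simulator
slightly *over*-produces double crossovers in short intervals — a point that
matters for fine mapping (below).

Defaults emulate the study conditions: an F2 of 623 plants and a BC1 of 71,
phenotyped with full penetrance (yellow iff at least one dominant allele),
with an optional misphenotyping rate (default 0). Chromosomes default to
5 Mb at 40 cM (~8 cM/Mb, the order observed in the small, recombination-rich
cucurbit genome), with the causal locus mid-chromosome and one informative
site per 10 kb.

## Pooled sequencing and the reference convention

Two 33-plant bulks are drawn from the F2 by phenotype. At every informative
site the bulk's true green-parent allele frequency is the mean over its 66
haplotypes. Read counts are then simulated per site and bulk as

* total depth ~ Poisson(`mean_depth`), default 30 — the order of the pooled
  coverage in the study design (parents ~23x, pools ~34x);
* green-allele reads ~ Binomial(depth, `f(1-e) + (1-f)e`) with base error
  `e = 0.005`.

The simulated reference genome carries the **yellow-parent allele** at every
informative site, so REF is the yellow allele and ALT the green allele. This
orientation makes the green bulk's SNP-index high in the linked region and
reproduces the published signature (green-pool index above 0.875, delta
above 0.5); it is a bookkeeping convention, not a claim about any real
reference assembly. Sites are written to and re-read from VCF (GT:AD:DP,
four samples) so the ingest path is exercised by every pipeline run.

## SNP-index statistics

At a site, a bulk's SNP-index is the fraction of its reads carrying the ALT
(green-parent) allele; the delta SNP-index is the green-bulk index minus the
yellow-bulk index. Expected values under this design:

| location                | green bulk | yellow bulk | delta |
|-------------------------|-----------:|------------:|------:|
| unlinked site           |        0.5 |         0.5 |     0 |
| fully linked site       |          1 |         1/3 |   2/3 |

The yellow-bulk value follows from genotype enumeration: yellow F2 plants
are 1/3 YY : 2/3 Yy, so the green-allele frequency among them is
(2/3)(1/2) = 1/3. Zero-depth sites get an undefined index and are dropped
from windowed statistics rather than imputed.

Windowed means use half-open windows `[start, start + window)` advanced by a
fixed step (defaults 1 Mb / 100 kb; windows with fewer than 10 defined sites
are flagged ineligible). The published curves smooth per-site indices the
same way but do not state their window parameters, so these are declared,
configurable defaults, not inferred values. A candidate region is a maximal
run of at least 3 consecutive windows in which **both** criteria fire
strictly: green-bulk mean index > 0.875 and mean delta > 0.5. Runs separated
by a single failing window are kept separate; region boundaries are the
outer edges of the qualifying windows (sub-window refinement is the fine
mapper's job).

## Segregation testing

Phenotype counts are tested against a hypothesized yellow:green ratio with
the plain two-class Pearson statistic, df = 1, no continuity correction, and
the chi-squared upper tail for the P-value; `verdict` applies the
conventional 5% level (critical value 3.84). The statistic-to-P pairs
printed in the source study's segregation table (2.2039 -> 0.1377;
0.007 -> 0.933) are reproduced exactly by the tail function; the standard
Pearson statistic computed from the printed counts themselves differs
(5.0342 and 0.0141), so the package implements the standard formula and
makes no attempt to reverse-engineer the published arithmetic.

## Interval narrowing from recombinants

Co-dominant marker calls (`A` homozygous green, `H` heterozygous, `B`
homozygous yellow, or missing) over ordered markers give each individual a
piecewise-constant genotype along the chromosome. Full-penetrance dominance
turns phenotypes into genotype constraints at the locus: green -> {A};
yellow F2 -> {H, B}; yellow BC1 -> {H}. The mapped interval is the largest
component of the intersection, over individuals, of the positions where each
individual's genotype satisfies its constraint. Missing calls are
uninformative at their marker, never imputed; yellow individuals contribute
their (weak) {H, B} constraint rather than being discarded.

Where exactly does a genotype switch between two discordant markers? Two
conventions are provided:

* `boundary = "midpoint"` (default): the switch is placed at the midpoint —
  a symmetric point estimate, matching a 1 bp brute-force compatibility scan
  used as the test oracle.
* `boundary = "marker"`: each genotype stretch extends conservatively to the
  discordant markers themselves — the classical flanking-marker logic.

The midpoint convention can *wrongly exclude* the true position whenever a
crossover falls between the true locus and the midpoint, and in a large
population two opposing recombinants in the same marker interval produce
contradictory midpoint constraints and an empty intersection. This is not a
rare pathology: at 623 plants with ~0.4 Mb marker spacing it happens in
essentially every run. The pipeline therefore narrows with marker bounds,
which never exclude the true locus under error-free genotyping; midpoint
remains the default in `narrow_interval()` as the sharper point estimate for
small recombinant panels, where the oracle-checked examples live. Apparent
contradictions are handled loudly, not silently: individuals compatible with
their phenotype nowhere in the spanned region (phenotyping errors, or double
recombinants whose matching stretch falls between markers) abort the
intersection with an error naming them; `screen_recombinants()` drops them
with a message, and `drop_conflicting = TRUE` drops at most one
irreconcilable individual with a warning.

The validation suite places the causal locus **at** an internal genotyped
marker for the 100-runs-out-of-100 containment check. With the locus
strictly between markers no breakpoint convention can guarantee containment
(a double crossover between flanking markers hides the local genotype from
any method), whereas at a genotyped marker the constraint is evaluated on
directly observed data and containment is exact. This mirrors the endpoint
of a real marker walk, where the final diagnostic marker sits inside the
candidate gene.

## Pigment and colour formulas

Chlorophyll a/b and carotenoid concentrations come from the standard linear
spectrophotometric equations for 96% ethanol extracts read at 470/649/665 nm
(`C_a = 13.96 D665 - 6.88 D649`; `C_b = 24.96 D649 - 7.32 D665`;
`C_xc = (1000 D470 - 2.05 C_a - 114.8 C_b)/245`), in mg/L of extract. The
source protocol states tissue mass and extract volume (1 g in 15 mL) but
not the reported unit, so per-gram conversion is an optional multiplier
(`volume_l_per_g = 0.015`) rather than a default. The map is linear, so
averaging three replicate readings before or after conversion is equivalent
(asserted as a property test). The colorimetric index is
`CCI = 1000 a / (L b)` from CIELAB readings, negative for green hues,
undefined (NA with a warning) when `L b = 0`.

## Statistical behaviour of the null, and what passing tests show

Two different "unlinked" baselines appear in the tests, deliberately:

* **Genuinely unlinked markers** (single-marker chromosomes): per-site bulk
  allele frequencies are independent across sites, and the mean SNP-index
  over a few hundred such sites concentrates tightly at 0.5 (SD below 0.01).
  This is the setting in which a ±0.02 calibration band is a sound check.
* **One neutral 5 Mb chromosome**: the 66 haplotypes of a 33-plant bulk are
  long parental blocks, so per-site frequencies are strongly correlated
  along the chromosome and the chromosome-wide mean index has an intrinsic
  SD of ~0.04 *regardless of depth or marker density*. Values like 0.46 or
  0.54 on a single neutral chromosome are ordinary sampling behaviour of
  33-plant bulks, which is why genome-wide null statements in real BSA
  average over many chromosomes.

The generator reproduces the statistical structure the analysis assumes —
Mendelian segregation, linkage decay, binomial pooled sampling, base error —
but not library/alignment artefacts, variant-calling error, repeat-induced
mismapping, or segregation distortion. Passing tests therefore validate the
arithmetic and the inference logic, not the robustness of the thresholds to
real-data artefacts.

## Problem sizes and numerical choices

The test suite simulates populations of up to 100,000 plants for ratio
checks (phenotype ratios at that size resolve 3:1 and 1:1 within ~1%), 100
seeded replicates of the full 623-plant BSA design for region-recovery rate,
and 100 seeded 200-plant fine-mapping panels; these sizes were chosen so
each statistical property is measured with comfortable margin while a full
run of suite plus acceptance script stays in the minutes range on one core.
Other fixed choices: strict inequalities at the 0.875/0.5 thresholds (the
published criteria are printed as strict); 1-based inclusive coordinates
internally (VCF convention) with BED export converting to 0-based half-open,
stated in file headers; all randomness derived from one master seed via
fixed per-stage sub-seeds, making every artifact byte-reproducible; interval
intersections on closed intervals with degenerate (zero-length) overlaps
discarded.

## Known limitations

* Haldane recombination overstates double crossovers in short intervals;
  with crossover interference, midpoint narrowing would fail less often,
  but the conservative marker-bounded mode would still be the safe default.
* The region caller reports window unions; its resolution is bounded below
  by the window size.
* Heterozygous or missing parent calls disqualify a site (justified for
  inbred parents); no attempt is made to rescue sites by depth-based parent
  genotyping.
* The two-class segregation test covers yellow/green only; multi-class
  ratios are out of scope.
* `select_codominant_indels()` filters on allele-length difference only; it
  does not model primer design or amplicon context.
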