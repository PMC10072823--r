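---
title: "Models and methods behind mitoconverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitoconverge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoconverge)
```

# The scientific setting

Mitochondrial function depends on tightly co-evolved products of two
genomes. A mitonuclear hybrid (cybrid) pairs the nuclear genome of one
yeast strain with the mitochondrial genome of another; evolving many
replicate populations of several such hybrids, in media that do or do not
require respiration, asks whether the nuclear background, the
mitochondrial background, the environment, and their interactions channel
adaptation toward different mutations. mitoconverge implements the
statistical machinery for that question: calling genomic changes from
coverage data, quantifying divergence between per-circumstance mutation
profiles, scoring locus specificity, and measuring fitness effects of
candidate mutations — together with a generator of synthetic cohorts whose
ground truth makes every estimator testable.

An *evolutionary circumstance* is one mitonuclear genotype in one medium.
The default design has 7 genotypes (NN, ND, DN, DD, DY, YD, YY; nuclear
letter first) × 2 media (FF fermentable, NF nonfermentable) = 14
circumstances, with 96 replicate populations each (1,344 populations).

# The synthetic world

`generate_cohort()` draws, for every surviving clone, a Poisson number of
mutations at each catalog locus with a circumstance-specific rate. The
defaults state the emulated world:

* **Replication and attrition.** 96 replicates per circumstance;
  extinction removes populations before clone isolation, either as a
  Bernoulli per population (probability 230/1344, the attrition of the
  emulated design) or as an exact count (`extinction_count = 230` gives
  exactly 1,114 survivors, used when the design arithmetic must be exact).
* **Locus catalog.** Hotspots echo the emulated study's structure:
  chromosome XII and IV aneuploidies concentrated in NN (mostly
  nonfermentable), chromosome IX gains in nuclear-D derivatives, an HPF1
  CNV hotspot in ND/fermentable, an MNN4 CNV hotspot in YD/nonfermentable,
  plus biased SNV targets (RIM20, TSA2). The background is a long tail of
  150 rarely hit genes (rate 0.004/clone everywhere, 0.20 in one
  round-robin-assigned circumstance each). This calibration — fixed once,
  before any test was run against it — reproduces the emulated study's
  scale: ~3 calls per clone and a mean pairwise Bray–Curtis dissimilarity
  of ~0.91 at full design size.
* **Mutation type mix** (SNV 0.900 / CNV 0.066 / aneuploidy 0.034, used
  only for catalog rows without a fixed type) follows the ratio of
  published tallies (3,710 SNVs, 272 CNVs, aneuploidies of order 10²).
* **Noise models.** Gaussian noise truncated at zero for depth of coverage
  (SD proportional to the local mean) and colony size; binomial/multinomial
  sampling for pileup base counts and cytometry counts — the simplest
  models matching each data type's support.
* **Coordinates.** All emitted tables are 1-based inclusive
  (samtools-depth convention); BED input is converted from 0-based
  half-open on read, GFF3 is native 1-based.
* **Ploidy.** Evolved clones are treated as clonal/haploid: planted SNVs
  default to allele fraction ≈ 1, and the SNV caller's default
  `min_alt_fraction = 0.8` encodes the same assumption. Both are exposed
  as parameters.
* **Generations.** 5.2 generations/day (≈300 generations over 58 days of
  daily passage), configurable everywhere it matters.

What the generator does **not** emulate: read-level noise (mapping
artefacts, GC bias, indels), mitochondrial genome structure or
recombination, linkage between mutations within a clone, and clone-level
heterogeneity in mutation rate. A green recovery test therefore
establishes that the estimators are correct *for data obeying the stated
noise models*, not that they are robust to every artefact of real
sequencing; the artifact-resolution step (below) is the one place where a
specific real-data artefact (shared coverage bias) is modelled and
removed.

# Depth-based callers

**mtDNA fraction.** Depth (assumed base-quality-filtered upstream, > Q20)
is summed over mitochondrial coding intervals and divided by the sum over
the whole genome. The statistic is scale-free and equals the coding-length
fraction under uniform depth; it deliberately makes no claim about
mitogenome copy number, which per-base depth cannot support given the
complex branched topology of yeast mtDNA.

**Aneuploidies.** Depth is summarised as 1-kb window medians. A
chromosome's copy ratio is its median window depth over the median of all
other chromosomes; a call requires ratio ≥ 1.35 (gain) or ≤ 0.65 (loss)
*and* a Wilcoxon rank-sum test of its windows against the rest,
Bonferroni-corrected over chromosomes, at α = 0.05. The dual condition is
a design choice: the ratio thresholds make the call biologically
meaningful (0.65/1.35 sit between euploid noise and a one-copy change in
diploids while catching any haploid change), the test guards against
calling on noise; the underlying significance criterion in the emulated
study was unspecified, so these values are fixed here for reproducibility.

**CNVs.** 50-bp window means are normalised by the enclosing chromosome's
median depth (removing whole-chromosome shifts so aneuploid chromosomes do
not bleed into CNV calls), and maximal runs of windows beyond 1.5×/0.5×
spanning ≥ 150 bp become calls. The 150-bp minimum sits below the smallest
event the emulated study reported (184 bp) so that all real-scale events
are recoverable. The cited segmentation method of the original pipeline is
not reproduced verbatim; this windowed equivalent is documented as such.

**Artifact resolution.** A locus that is unusually deep in *every* sample
is a mappability/coverage artefact, not a clone-specific CNV. For each
recurrent candidate locus the per-sample mean locus depth is regressed on
per-sample genome-wide mean depth; only samples whose standardised
residual exceeds the cutoff (default 2) keep their call. At least 8
samples are required; with fewer, calls pass through unflagged with a
warning rather than being silently judged. Near-zero residual variance is
treated as exactly zero so floating-point noise cannot fabricate a
"deviant" sample.

**SNVs.** At each site the most frequent non-reference base is the
candidate allele; a call requires depth ≥ 10, alternative fraction ≥ 0.8
(clonal assumption) and the same base at ≤ 0.05 fraction in the ancestor
pileup (ancestral subtraction). The original pipeline's full filter list
is unpublished; these surrogates are deliberately few, explicit and
testable against brute-force evaluation.

# Convergence statistics

**Profiles and dissimilarity.** Mutation calls are counted per
(circumstance, annotation) with equal weight per event regardless of size,
so dissimilarity reflects *which loci* were used, not event length.
Bray–Curtis dissimilarity, BC(u,v) = 1 − 2·Σmin(u,v)/(Σu+Σv), is computed
directly from that definition (the vegan implementation is used only as an
independent cross-check in the tests). A pair of all-zero profiles is
undefined and reported NA with a warning.

**NMDS.** Nonmetric MDS minimises Kruskal stress-1 with monotone
regression (primary tie treatment), delegating the inner minimisation to
`vegan::monoMDS` while this package owns multi-start control: the first
start is the metric (principal-coordinates) configuration, the rest are
random, and the best final stress is retained — the retained stress is
never worse than any discarded start, which the tests assert. Defaults
follow exhaustive practice (10,000 starts, 3,000 iterations, stress
tolerance 1e-9); tests run reduced start counts purely for speed, which
only risks retaining a local optimum, never an invalid one.

**Match/mismatch partitioning.** Every pair of circumstances is classified
by environment match, nuclear match and mitochondrial match, and the
pairwise dissimilarities enter a three-way factorial ANOVA. One structural
fact deserves note: a pair matching on all three factors would be the same
circumstance, so the (match, match, match) cell is empty by construction
and the three-way interaction is inestimable; `factorial_anova()` drops
such terms with a warning rather than guessing.

**Locus specificity.** For each annotation a 2×k table (calls inside vs
outside the locus, across the k levels of the chosen factor) yields a χ²
test of independence (no continuity correction, since k is often > 2) and
mutual information in dits (base-10 logarithms, per the reporting
convention of the emulated study). An annotation is *specific* only if its
Benjamini–Hochberg q ≤ α **and** its MI is ≥ 2 SD above the mean MI across
all annotations in the same analysis (≈ 95th percentile). The dual
threshold matters: with thousands of calls, a locus can reach a tiny χ² p
with a distributional tilt too weak to be interesting; the MI criterion is
the effect-size gate. Expected cell counts below 1 trigger a warning and a
Monte-Carlo χ² option. BH was chosen for the unspecified "corrected for
false discovery rate"; permutation tests confirm the empirical false-flag
rate stays within the nominal level plus Monte-Carlo error.

**Spectra and phenotypes.** SNVs collapse to the six pyrimidine-context
substitution classes for between-group χ² comparison. Phenotype
association uses rank-sum tests of mutant vs non-mutant clones within each
circumstance (≥ 5 clones per group) with BH correction — nonparametric by
choice, since colony-size-derived phenotypes have no guaranteed
distributional form.

# Growth curves and factorial tests

Colony growth curves are fitted to the Zwietering modified Gompertz form

$$y(t) = A \exp\!\big(-\exp\big(\tfrac{\mu e}{A}(\lambda - t) + 1\big)\big)$$

with A the carrying capacity (size units), µ the maximum specific growth
rate (size/h, the slope at inflection) and λ the lag (h). The emulated
study cites this model family without printing an equation; the Zwietering
form is fixed here as the canonical parameterisation. Fitting is
least-squares on the raw size scale (the model family targets sigmoidal
size curves directly; a log-scale flag exists for users who prefer it),
from data-driven starts (A ≈ max size, µ ≈ steepest finite-difference
slope, λ ≈ extrapolated first-rise time) refined over a small
deterministic perturbation grid — deterministic rather than random so fits
never perturb global RNG state. Flat or monotone-decreasing curves raise a
`degenerate_curve` condition (or are flagged non-converged inside
`fit_plate()`, where one bad replicate must not abort a plate; per-clone
summaries are replicate medians with non-converged counts reported).

Factorial ANOVA uses **Type II sums of squares** via the standard
model-comparison definition (each term adjusted for all terms not
containing it), appropriate for the unbalanced replicate counts that
survive an evolution experiment; on balanced data it coincides with the
sequential decomposition, which the tests verify, and its interaction-term
null rejection rate is calibrated by simulation. Tukey HSD provides post
hoc pairwise comparisons; comparisons involving singleton groups are
reported as undefined.

# Competition fitness

The selection coefficient is the OLS slope of ln(mutant/reference counts)
on elapsed generations — per generation, not per day, so values are
comparable across media with different growth rates (the time axis of the
original regression was unstated; per-generation is this package's
documented choice, with `generations_per_day` always explicit, default
5.2). Days where either population counts zero receive a symmetric 0.5
pseudocount on both sides — symmetric so the adjustment never biases the
ratio's direction. Fewer than 3 usable timepoints raise
`insufficient_series`. Recovery simulations show the estimator unbiased to
within ±0.01 at s = 0.1 with 10⁴ cytometry events/day, with near-nominal
t-interval coverage.

`rank_concordance()` tests whether selection's locus preferences predict
evolutionary usage: Spearman ρ between per-locus fitness effects and
mutation frequencies, plus the p-value that the regression slope is zero,
with concordance declared at ρ > 0.7 and p < 0.05.

# Numerical and design choices, in one place

* Multiplicity: Bonferroni inside callers (few hypotheses, conservatism
  cheap), Benjamini–Hochberg everywhere else.
* χ² without continuity correction throughout (k > 2 is common);
  Monte-Carlo p-values optional where expected counts are small.
* Coordinates 1-based inclusive internally; conversions only at format
  boundaries.
* Every generator takes a mandatory seed and restores RNG state on exit
  (`withr::with_seed`); pipeline manifests record seeds, parameters and
  output checksums.
* The exact-count extinction mode exists because the Bernoulli model
  cannot reproduce the *exact* 230/1,114 split of the emulated design;
  both modes are first-class.

# Known limitations

* The default synthetic world assigns background-gene biases round-robin
  across circumstances, so biases are orthogonal to the nuclear/
  mitochondrial structure; the match-partition ANOVA consequently shows
  weak match effects on default cohorts. Structured catalogs (biases
  nested within backgrounds) demonstrate the test's power in the test
  suite and are straightforward to configure.
* CNV boundaries are window-quantised (± one window).
* The aneuploidy caller assumes most of the genome is euploid; a genome
  where half the chromosomes shift would distort the baseline.
* Indels, mitogenome copy number, dN/dS and functional enrichment are out
  of scope.
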