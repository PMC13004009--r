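---
title: "Methods: repeat-aware nascent-transcription analysis with rdnascent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-aware nascent-transcription analysis with rdnascent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and rationale

`rdnascent` quantifies nascent-transcription and chromatin-profiling signal
over loci that standard references handle badly: tandemly repeated gene
arrays such as the human ribosomal DNA (rDNA), whose ~44.8-kb unit is
repeated hundreds of times on the acrocentric short arms and is masked or
absent from older assemblies. The package covers the analysis stages
downstream of alignment — the input is a BED file of mapped fragments — and
upstream of interpretation:

1. **Composite mini-genome construction** (`build_minigenome`): a small
   reference assembled from coordinate recipes, e.g. one rDNA repeat unit
   written 16 times in tandem next to control regions (housekeeping genes,
   histone clusters), with a segment map for lifting annotations onto every
   tandem copy.
2. **Fraction-normalized coverage tracks** (`compute_track`,
   `fraction_normalize`): per-base, strand-separated signal scaled so that
   library size cancels.
3. **Locus quantification and ranking** (`quantify_loci`, `rank_loci`,
   `ma_points`): per-sample signal over annotated loci, tie-averaged
   descending ranks, and modified Bland–Altman (MA) points for matched
   sample pairs.
4. **Region statistics** (`overall_ratio`, `compartment_fractions`,
   `correlation_matrix`): strand-averaged perturbation ratios and
   inter-compartment Pearson correlation matrices across cohorts.
5. **Hairpin-precursor discovery** (`detect_broad_peaks`, `fold_hairpin`,
   `nominate_candidates`): ~50-bp broad peaks in single-strand tracks,
   100-bp window extraction, and secondary-structure scoring by a weighted
   maximum-pairing dynamic program.
6. **A synthetic-data generator** (`sim_config`, `simulate_genome`,
   `simulate_fragments`, `simulate_cohort`) that plants known truth so
   every stage is testable end to end without external data.

Read trimming, alignment, BAM handling, and thermodynamically exact RNA
folding are out of scope by design; the package consumes fragment BEDs and
emits tracks, tables and candidate lists.

# Coordinate conventions

Recipe coordinates are 1-based inclusive — the convention in which genome
regions are printed in browsers and assembly descriptions — so a region
`chr21:3,141,168-3,185,955` has length `end − start + 1 = 44,788` bp.
All internal interval arithmetic and all BED/bedGraph I/O are 0-based
half-open, the BED standard. `region_spec` is the boundary type between the
two; the conversion happens in exactly one place (`lift_annotation` /
`lift_back`). Published recipe listings occasionally disagree by one at the
start coordinate (a 0-based start pasted into a 1-based listing);
`rdnascent` canonicalizes on the variant consistent with the stated segment
length and leaves resolving individual sources to the user.

Tandem expansion (`xN`) is restricted to single-segment recipes. A
multi-segment tandem repeat would make the segment map ambiguous (which
junctions are real?), and the motivating use case — a repeat-unit array —
needs only one segment. Features lifted onto a mini-genome are emitted once
per tandem copy; features straddling the junction between two concatenated
segments are dropped with a warning rather than split, because
junction-spanning intervals are artifacts of concatenation, not biology.

# Fraction normalization

For raw per-base counts $c_i$ with total $C = \sum_i c_i$ over a reference
of $L$ bases, the fraction-normalized track is

$$ f_i = \frac{c_i}{C} \cdot L, $$

so that uniformly distributed counts give exactly 1 at every base and
$\sum_i f_i = L$. The contract `mean(f) == 1` (relative tolerance $10^{-9}$)
is enforced for any nonempty input in any counting mode.

Two details matter in practice:

* **The denominator is sample-wide.** When the two strands of one sample
  are kept as separate tracks, both are divided by the same
  $C = C_+ + C_-$ (`normalize_strand_pair`), so the strand split survives
  normalization and per-region sums remain comparable between samples. If
  each strand (or each mini-chromosome) were normalized by its own total,
  every per-region ratio between samples would be forced to 1 and
  perturbation statistics would be meaningless.
* **Counting modes.** `span` increments every covered base (run-on and
  chromatin data); `end3` increments only the 3′-terminal base (`end − 1`
  for `+` fragments, `start` for `−` fragments under half-open
  coordinates), the natural representation for NET-seq-style active-site
  profiles; `end5` is the symmetric 5′ mode for initiation (PRO-cap-style)
  data. Duplicates are counted — upstream pipelines for these assays do not
  deduplicate.

# Perturbation ratios and compartment correlations

The **overall ratio** for a perturbation experiment sums normalized signal
over a region separately per strand, takes the treated/control fold change
per strand, and averages the two strand ratios arithmetically:
$R = (R_+ + R_-)/2$. Fraction normalization makes $R$ invariant to each
library's depth, so unperturbed control regions sit near 1. When the
control signal is zero on one strand the ratio falls back to the defined
strand with a warning; zero on both strands is an error.

Because normalized signal is compositional (shares of a fixed total), a
planted depletion $\rho$ on a region carrying a fraction $\lambda$ of the
library is recovered as $R = \rho / (1 - \lambda(1-\rho))$, not $\rho$
exactly. For the small regulatory loci this statistic is aimed at
($\lambda \le 0.05$) the distortion is well inside binomial sampling error;
the package's recovery tests use exactly this algebra for their expected
values.

**Compartment correlations** work on compositional fractions: each
sample's signal in a compartment divided by the sample's total. No external
size factor exists for cross-patient comparisons of this kind, so fractions
are the only normalization available — with the caveat, worth stating
plainly, that closure alone pushes a dominant, variable compartment toward
anticorrelation with the rest. That is not an artifact here; it is the
measurable signature of repeat copy-number variation: when the repeat
array's share swells, everything else's share must shrink. Pearson $r$ is
computed for every compartment pair and two-sided $p$-values come from
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of freedom, unadjusted, as
is conventional for these matrices (cross-checked against `cor.test` in the
test suite). Zero-variance compartments yield `NA` with a warning rather
than a fabricated value.

# Ranking and MA points

Ranks are assigned per sample with rank 1 = highest signal and ties
averaged, then averaged across samples. Ranking is invariant to per-sample
scaling, so whether raw or normalized signal is ranked is immaterial; MA
values are not scale-free, which is why tracks entering `ma_points` should
be fraction-normalized. Loci sharing a `group_id` — e.g. the 16 lifted
copies of one repeat-resident microRNA — are **summed**, not averaged:
copy-number amplification of signal is precisely the effect one wants to
see in the quantification.

"Modified Bland–Altman" plots in this field are MA plots; with per-feature
signals $T$ (tumor/treated) and $N$ (matched normal/control) and a
pseudocount $\varepsilon > 0$:

$$ A = \log_{10}\!\left(\tfrac{T+N}{2} + \varepsilon\right), \qquad
   M = \log_{10}(T + \varepsilon) - \log_{10}(N + \varepsilon). $$

$M$ as a difference of logs and $A$ as a log of the mean is the standard
genomics convention and stays finite for features absent from either
sample. The default $\varepsilon = 0.5$ is half a count on the normalized
scale; it only matters near zero, and swapping the pair negates $M$ and
preserves $A$ exactly for any $\varepsilon$.

# Hairpin-precursor discovery

Short microRNA precursors show up in single-strand nascent-transcript
tracks as broad peaks about 50 bp wide — wider than single-base pause
spikes, much narrower than genes. `detect_broad_peaks` smooths the track
with a centered moving average (default 5 bp, shrinking at chromosome
edges), takes maximal runs at or above a threshold $\theta$, keeps runs
with width in `[w_min, w_max]` (defaults 30–80 bp), and reports each with a
100-bp extraction window centered on the run midpoint. $\theta$ has no
universal default: it is data-scale-dependent and deliberately exposed,
since published analyses of this kind identify such features
semi-manually in a browser.

Window sequences are folded by `fold_hairpin`, a maximum-weight
non-crossing pairing dynamic program with pair weights G:C = 3, A:U = 2,
G:U = 1 (hydrogen-bond counts) and a minimum hairpin loop of 3 nt
(steric reality, and the default of thermodynamic folders). The score is
reported negated as a "pseudo-energy" so more stable is more negative.
This is *not* a nearest-neighbor free energy: it has no stacking, no loop
penalties, and its units are arbitrary. What candidate triage needs is a
consistent stability *ordering*, which maximum pairing provides, and which
the test suite pins to an independent brute-force enumeration of all
non-crossing pairings for every sequence up to length 12. For users who
want kcal/mol, `fold_hairpin_rnafold` shells out to an external
thermodynamic folder when one is on the PATH; nothing in the package
depends on it.

`nominate_candidates` folds every peak window and flags those whose score
reaches a configurable fraction $\varphi$ (default 1) of a reference
hairpin's score — the reference playing the role of a known precursor
whose stability sets the bar.

A known limitation: on windows much longer than a hairpin, random RNA
pairs promiscuously under any maximum-pairing model, so the contrast
between a planted stem and background shrinks as windows grow. The
package's discovery benchmarks therefore plant GC-rich stems (real
repeat-promoter hairpins sit in regions of ~80% GC), and the recovery test
measures the planted-vs-random score gap empirically.

# The synthetic-data generator

`simulate_genome` builds a desk-scale composite reference emulating the
structure of the real mini-genomes: by default a repeat array of 16 tandem
2-kb units (a scaled-down rDNA array), a 20-kb euchromatin block, two 6-kb
histone-cluster analogs, a 6-kb housekeeping control and a 2-kb 5S-like
block (~72 kb total). Each repeat unit carries planted stem-loop loci
written as perfect reverse-complement stems flanking a loop — truth
stability is therefore analytic — with the dominant locus's stem at 85% GC,
matching the GC-richness of real repeat-promoter hairpins. Sequence is
i.i.d. at configured GC content.

`simulate_fragments` uses a **region-weight multinomial model**: each
fragment's region is drawn with probability proportional to its weight
$\lambda_r$, its start is uniform within the region, its length is
truncated-normal (default mean 75 bp, sd 15, range 20–150, further
truncated to the region width so fragments never cross region borders),
and its strand is Bernoulli with a per-region forward-strand probability
(0.9 on the repeat array, mirroring the strong strand asymmetry of rRNA
transcription; 0.5 elsewhere). Planted loci are carved out of their
chromosome's background region, so a locus's expected fragment share
equals its weight exactly — this is what makes binomial error bars for the
recovery tests exact rather than approximate. The model is intentionally
the simplest one matching the region-level statistics the pipeline
computes; it does **not** emulate sequencing error, mappability,
GC-amplification bias, fragment-level autocorrelation, or within-region
signal structure. Passing tests demonstrate that the pipeline's statistics
recover region-level planted truth, not that the pipeline is robust to
those read-level artifacts.

`simulate_cohort` supplies three designs with recorded truth tables:

* **copy_number** — 20 samples whose repeat-array weight is multiplied by
  $\kappa_k \sim \mathrm{lognormal}(0, 0.3^2)$, emulating the few-fold
  rDNA copy-number variation observed between individuals.
* **knockdown** — a control/treated pair with a planted ratio $\rho$
  (default 0.5 on the dominant repeat-resident locus) multiplying the
  target's weight, the ground truth for `overall_ratio`.
* **paired** — 7 matched tumor/normal pairs with a planted effect $\delta$
  (default 10 on the *low*-abundance locus, $\lambda = 0.01$) multiplying
  the target's weight in tumors. The low-weight default keeps the
  compositional distortion of the expected MA shift small:
  $M = \log_{10}(\delta/(1 + (\delta-1)\lambda)) \approx 0.96$ for one
  decade planted.

All three operations are byte-deterministic under the config seed;
per-sample seeds are derived as small offsets from it.

# Problem sizes and numerical choices

* Ratio-recovery experiments use the generator default of 50,000 fragments
  per sample and check planted ratios $\{0.25, 0.5, 1, 2\}$ within 3
  binomial standard errors computed from expected per-strand counts.
* The copy-number sign-recovery experiment runs 100 replicate cohorts of
  20 samples at 5,000 fragments each; at that depth sampling noise in a
  compartment fraction (≲0.01) is far below the planted $\kappa$ spread,
  so the experiment probes the pipeline, not the noise floor.
* Discovery benchmarks plant four hairpins of spans 40/50/65/80 bp (stems
  17/20/28/35 nt at 90% GC) in a 2-copy array, with short NET-seq-like
  fragments (mean 30, range 20–40 bp) so coverage blocks match locus
  spans, and run 100 seeded draws checking detection, ±2-bp centering and
  score separation from uniform-random 100-mers.
* Folding-oracle equivalence is checked exhaustively for all sequences of
  lengths 5–6 and on 1,000 seeded random sequences up to length 12.
* Ties in the folding traceback are broken toward the smallest pairing
  partner index; ties in ranking are averaged; bedGraph values are written
  with `%.17g` so round trips are bit-identical.

# Known limitations

* The folding score orders candidates; it is not an energy. Hairpins with
  long internal loops or multi-branch structures are scored by the same
  maximum-pairing criterion and may be over-rated relative to a
  thermodynamic model.
* Compartment correlations on compositional fractions cannot distinguish
  "compartment A grew" from "everything else shrank"; they quantify
  association, and interpreting a negative $r$ as copy-number variation
  requires the planted-mechanism reasoning above (or orthogonal data) —
  the matrices alone do not prove it.
* `lift_annotation` drops junction-spanning features rather than splitting
  them; counts are reported so users can audit what was lost.
* The generator's multinomial model has no overdispersion between
  replicates beyond sampling; cohort variance in real patient data is
  larger.
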