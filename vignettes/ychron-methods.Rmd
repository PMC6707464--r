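---
title: "Dating Y-chromosome splits with ychron: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating Y-chromosome splits with ychron: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The male-specific portion of the human Y chromosome does not recombine, so
jointly called haploid genotypes from a cohort of men define a single
genealogy whose internal nodes can be dated from mutation counts. `ychron`
implements this dating workflow: quality filtering of a joint call set,
polarization of alleles into ancestral/derived states using deep-rooting
outgroup samples (A/B-haplogroup chromosomes), per-sample branch-length
calibration, rho-statistic split-time estimation with mutation-rate
uncertainty propagation, placement of novel lineages by derived-SNP sharing,
and the downstream arithmetic that turns a set of dated splits into
out-of-Africa migration windows.

## The clock model

Mutations accumulate along each branch as a Poisson process with rate

$$\lambda = \mu \, L \, t,$$

where $\mu$ is the single-nucleotide mutation rate per site per year, $L$
the callable region length in bp, and $t$ the branch duration in years. The
default clock (`clock_params()`) is the ancient-DNA-calibrated rate
$\mu = 0.76 \times 10^{-9}$ /site/year with 95% HPD
$(0.67{-}0.86) \times 10^{-9}$. Mutation counts are reported normalized per
$10^7$ bp (`norm_length`). The model assumes the rate is constant in time;
rate differences *between lineages* are handled empirically through the
calibration coefficients below, not through lineage-specific rates.

## Polarization and root counts

A site's ancestral allele is the allele monomorphic among the designated
outgroup samples (`assign_ancestral()`); sites where the outgroup is
polymorphic or insufficiently called stay unassigned with a reason code.
The rule is monomorphism, not REF identity — an outgroup unanimous for the
ALT allele makes ALT ancestral.

`derived_root_counts()` then counts, per sample, the assigned sites at
which the sample's call differs from the ancestral allele. Each sample's
count is normalized per 10 Mb using an *effective* callable length: the
physical callable length scaled by the fraction of assigned sites actually
called in that sample. This choice means missing data shrink the
denominator along with the numerator instead of deflating the sample's
apparent branch length; the alternative (normalizing everyone by the same
physical length) biases counts downward for low-coverage samples.

Note that the outgroup samples themselves carry the ancestral allele at
every assigned site by construction, so their root counts are identically
zero; they must be excluded from the root-count table (the `samples`
argument), and the calibration mean is taken over the ingroup.

## Calibration and the rho statistic

Root-to-tip mutation counts differ systematically between haplogroups. To
date nodes on a common scale, every sample receives a calibration
coefficient

$$\alpha_i = \bar{c} \, / \, c_i,$$

the dataset mean normalized root count over the sample's own
(`calibration_alpha()`). By construction the mean of $\alpha_i c_i$ equals
$\bar{c}$ exactly.

For two samples $i, j$ under a node, `pair_divergence()` computes

$$t_{ij} = \frac{\alpha_i \, n_{ij}}{S_{ij} \, \mu},$$

with $n_{ij}$ the number of sites where $i$ is derived and $j$ ancestral
(both called) and $S_{ij}$ the number of sites ancestral in both. A node's
split time (`node_split_time()`) is the mean of $t_{ij}$ over all pairs
with $i$ in one clade and $j$ in the other, by default in both directions
(each direction using the first sample's $\alpha$). The reported 95%
interval propagates only the mutation-rate HPD:
$(t\,\mu/\mu_\text{high},\; t\,\mu/\mu_\text{low})$ (`rate_ci()`); no
pair-to-pair variance is added, which reproduces the conventional intervals
for this statistic.

### The denominator

$S_{ij}$ literally requires monomorphic ancestral sites to be present in
the matrix. Joint call sets often contain only variable sites, so
`pair_divergence()` offers two bookkeeping modes:

* `called_ancestral_sites` (default): count $S_{ij}$ from the matrix — use
  when monomorphic sites were emitted (e.g. a caller's
  report-monomorphic mode).
* `callable_length_proxy`: $S_{ij} = L - d_{ij}$, where $L$ is the physical
  callable length and $d_{ij}$ the number of assigned sites at which the
  pair is *not* confidently ancestral-in-both; every unemitted callable
  position is taken as ancestral in everyone. This is the appropriate mode
  for variants-only call sets and for the simulator's output.

### Direction averaging and what calibration can and cannot fix

Averaging both directions symmetrizes the estimator. A consequence worth
stating explicitly: if the two clades being dated carry rate multipliers
that are symmetric about 1 (say 0.8 and 1.2), the *uncalibrated*
both-direction mean is already unbiased in expectation — the deviations
cancel. Calibration matters when the heterogeneity is one-sided relative
to the dataset average, which is the realistic situation (a rate-deviant
lineage dated against a large, mostly rate-typical cohort). The package's
calibration-efficacy simulations therefore use three ingroup clades —
multipliers 0.8 and 1.2 on two of them, the third at 1.0 — and date a split
where one side is rate-deviant; there the uncalibrated estimator is biased
by about half the deviation while the calibrated one removes most of it.
A single-direction mode (`directions = "first"`) is available; under
calibration both directions agree in expectation, which is precisely the
point of the correction.

## QC filters

`filter_calls()` masks calls with DP < 5, GQ < 30, or a supporting-read
fraction not strictly greater than 0.8 (absent annotations fail).
Boundary semantics are exact: DP = 5 and GQ = 30 pass, fraction = 0.8
fails. `filter_sites()` then removes sites whose total depth across
samples falls outside 0.5x–3x the dataset mean total depth, or missing in
more than 20% of samples (missingness evaluated after call masking).

The depth window is relative by default because absolute bounds only make
sense for a specific cohort size and coverage; absolute overrides
(`site_depth_low_abs`/`site_depth_high_abs`) are available. One caveat
follows: with relative bounds, re-applying the site filter can remove
further sites because removal shifts the mean; at fixed absolute bounds the
filter is idempotent, and that is the form in which the idempotence
property is tested.

`detect_duplicates()` flags sample pairs whose pairwise mismatch rate over
co-called sites is at or below a threshold (default 0.01);
`remove_duplicates()` keeps the member with fewer missing calls, ties
broken by sample-id order.

## Lineage placement

`clade_derived_sites()` collects sites at which every called member of a
clade is derived. `sharing_profile()` partitions a query clade's derived
sites into exclusive (no outside carrier), shared with exactly one
reference clade, and multi-clade (carriers spanning several references or
outside all of them; treated as unstable and never used as placement
support). Sharing with a clade requires at least one derived member of it —
not unanimity — because reference clades are large and internally
structured. `place_lineage()` sets aside reference clades sharing no more
than `recurrence_threshold` SNPs (default 1: a single shared SNP is
parsimoniously a recurrent mutation) and places the query with the largest
remaining count; ties are `AMBIGUOUS`, nothing above threshold is `BASAL`.

## Scenario arithmetic

`lineage_table()` ships the dated deep phylogeny used for the migration
scenarios (B/CT 101 ky, CT divergence 77 ky, C/FT 76 ky, D/E 73 ky, D0/D
71 ky, E divergence 59 ky, FT diversification 57 ky, E-M35 47/28.5 ky, D0
coalescence 2.5 ky) as data, so re-estimated dates flow through the same
code. From it `scenario_windows()` derives three exit windows and their
requirements: which lineages are extant in each window
(`extant_lineages()`), which must migrate (those with non-African
descendants), and which African sublineages must back-migrate (windows 1
and 2: D0 and E, between the D0 origin and the E divergence; window 3:
none). Relevance is defined as the root-most lineage with non-African
descendants plus everything below it.

`rescale_times()` applies a fractional rate speedup $f$ (times scale by
$1-f$; a pedigree-derived rate about 14% faster than the ancient-DNA
calibration gives $f = 0.14$). `admixture_window()` converts an
introgression estimate of "$g_1$–$g_2$ generations before a fossil aged
$a_1$–$a_2$ years" into years ago with a generation time (default 29
years). `intersect_windows()` intersects intervals in years-ago space.

### Rounding

Reported years are rounded half-up — nearest 100 below $10^5$, nearest
1,000 above (`round_years()`); rescaled scenario bounds use nearest 1,000
and admixture windows nearest 100. Half-up (not banker's) rounding is
deliberate: it reproduces the conventional printed values from the raw
arithmetic (e.g. $71{,}400 \times 0.76/0.86 = 63{,}097.7 \to 63{,}100$;
$46{,}880 + 430 \times 29 = 59{,}350 \to 59{,}400$). All rounding is
reporting-side; internal values stay unrounded.

## The simulator

The genealogy is user-specified (`build_truth_tree()`, from a node table or
an ultrametric newick whose branch lengths are durations in years), not
coalescent-sampled: the analysis object is a fixed estimated topology, and
a coalescent prior is out of scope. Branches carry rate multipliers to
emulate haplogroup-specific mutation accumulation; values in 0.8–1.2 span
the heterogeneity scale used in validation.

`drop_mutations()` draws per-branch Poisson counts with mean
$\mu \cdot \text{mult} \cdot L \cdot t$, positions uniform over the
callable region, unique except that each mutation re-uses an existing
position on another branch with probability `recurrence_prob` (default
0.002 — chosen so that recurrent sharing is rare but routinely present at
10 Mb scale; no empirical rate is available). A recurrent re-draw copies
the original ancestral and derived alleles, producing identical-by-state
sharing across lineages, the confounder the placement rules must handle.

`synthesize_calls()` overlays a coverage model: negative-binomial depth
(default mean 16 reads, size 8), per-call error (0.002) and missingness
(0.05), binomial supporting-read counts (per-read error 0.02), and GQ as a
deterministic function of depth and the error draw. Defaults emulate a
~16x short-read Y-chromosome call set after joint calling; a noiseless
setting (`error_rate = 0, missing_rate = 0, seq_error = 0`) gives exact
truth recovery, which the round-trip tests rely on. The simulator does not
model reads, mapping artifacts, structural variation, or the correlated
(regional) missingness of real data — so passing tests demonstrate
estimator correctness under the stated statistical model, not robustness
to alignment pathology.

For polarization to be exact in simulations, the outgroup leaves attach
directly at the root: mutations private to one outgroup leaf render the
outgroup polymorphic (site unassigned) rather than mispolarized. A shared
outgroup stem would instead flip the apparent ancestral state at its
mutations — a real-data caveat inherent to outgroup polarization, not
specific to this implementation.

## Validation problem sizes

Simulation-based checks use a 10 Mb callable region at the default clock:
a 3+3-leaf split at 71,400 years recovered over 20 seeds (point estimate
within 5% of truth), parameter recovery at 2,500 / 30,000 / 71,400 years
bounded by twice the per-pair Poisson relative error, and 20 paired seeds
for the calibrated-vs-uncalibrated comparison. Hand-count fixtures for
filters, polarization and placement are tiny (tens of sites) and asserted
exactly. The demo pipeline configuration simulates a 200 kb region so an
end-to-end run stays near-instant.

## Known limitations

* Confidence intervals propagate rate uncertainty only; sampling noise in
  the pair counts is visible in simulations but not in the reported CI,
  matching the conventional reporting for this statistic.
* The calibration coefficient rescales a sample's whole root-to-tip path;
  when rate heterogeneity is confined to part of the path, the correction
  is partial (see the direction-averaging discussion above).
* Polarization trusts the outgroup: recurrent mutations on the outgroup
  stem masquerade as universally derived sites. With outgroups spanning
  the root (several A and B lineages) the effect is confined to the short
  shared stem.
* The site filter's relative depth window is cohort-dependent; use
  absolute bounds when comparing filter reports across call sets.
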