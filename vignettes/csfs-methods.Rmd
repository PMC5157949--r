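---
title: "Mutation-rate variation and the site frequency spectrum: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation-rate variation and the site frequency spectrum: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfs)
```

# The scientific problem

In a sample of a few hundred chromosomes, the site frequency spectrum (SFS)
of neutral variants is essentially independent of the mutation rate: under
the infinite-sites assumption every mutation creates a new segregating site,
so fast- and slow-mutating positions contribute spectra of the same shape.
In modern exome aggregation panels with $10^5$ or more chromosomes this
breaks down. Genealogies of such samples are enormous, the expected number
of mutation *origins* per site approaches or exceeds one for the fastest
classes (CpG transitions above all), and recurrent mutation pushes allele
frequencies upward: the fraction of rare variants at fast sites falls well
below the infinite-sites prediction.

`csfs` implements the modelling toolkit for this regime:

* spectrum containers with folding, hypergeometric subsampling, and
  rare-variant summaries;
* piecewise-exponential demographic models with analytic and simulated
  expected spectra;
* a finite-sites simulator (Kingman coalescent plus 4-allele Jukes–Cantor
  mutation dropping) that estimates, on a grid of mutation rates $M$, the
  probability $P(S{=}1\mid M)$ that a site is a biallelic polymorphism and
  the expected rare fraction $E[Y\mid S{=}1, M]$ among biallelic sites;
* the lognormal within-mutation-type rate mixture and the
  total-expectation integral
  $$E[Y \mid S{=}1;\mu] \;=\; \frac{\int E[Y\mid M, S{=}1]\,
    P(S{=}1\mid M)\, g(M;\mu)\, dM}{\int P(S{=}1\mid M')\, g(M';\mu)\,dM'},$$
  with $\log_{10} M \sim \mathcal N\!\big(\log_{10}\mu - \sigma^2\ln(10)/2,\,
  \sigma^2\big)$, the location shift making the mixture mean-preserving
  ($E[M]=\mu$ for every $\sigma$);
* construction of the phylogenetically-conditioned SFS (cSFS) from
  human-plus-primate site tables: classification into human-private and
  substituted-species categories, strand-collapsed mutation types, CpG
  context, coding/template strand partition;
* a two-category molecular-clock model (uniform-clock vs generation-scaled
  mutation types) for the distribution of rates at parallel-substitution
  sites;
* the logistic model
  $\mathrm{logit}\,P(Y{=}1) = \beta_0 + \vec\beta_\mu\cdot\vec\mu
  + (1-Z)\,\vec\beta_s^{\,syn}\cdot\vec s + Z\,\vec\beta_s^{\,ns}\cdot\vec s$
  for the probability that a coding variant is rare, with an exact
  permutation test for the ordering of the substituted-species
  coefficients; and
* a synthetic site-table generator with a complete ground-truth manifest,
  so that every stage of the pipeline can be validated offline.

# Conventions and units

Sample sizes are counted in chromosomes (twice the number of diploid
individuals); the command-line interface accepts `--diploids` and doubles
it with a log message. Time runs in generations before the present with
half-open epoch boundaries $[t_{\text{start}}, t_{\text{end}})$. Mutation
rates are per basepair, per generation, per haploid genome. "Rare" means a
minor-allele count of at most 2 (singletons and doubletons) unless a
different threshold is passed; this matches the common working definition
for large exome panels and is deliberately arbitrary.

A diploid effective size $N$ implies a pairwise coalescence rate
$1/(2N)$ per generation, so for a constant population the expected time to
coalescence of two lineages is $2N$ generations and the expected
level-$k$ holding time is $4N/\big(k(k-1)\big)$.

# Demographic models

A model is an ordered tibble of epochs (present backwards), each with a
duration, the diploid size at its recent end, and a growth rate. Two growth
conventions are supported: compound per-generation
($N(t) = N_0 (1+g)^{-t}$, the default) and instantaneous exponential
($N(t) = N_0 e^{-g t}$). Both reduce internally to an exponential decay
rate, $\rho = \ln(1+g)$ or $\rho = g$.

Three literature parameterizations ship as presets:

* `demog_tennessen_eur()` — the European lineage of Tennessen et al.
  (2012), built on Gravel et al. (2011): ancestral 7,310; African expansion
  to 14,474 at 5,920 generations; out-of-Africa bottleneck to 1,861 at
  2,040; European founding at 1,032 with 0.307%/generation growth from 920
  generations, accelerating to 1.95%/generation over the last ~205
  generations. Migration of the original two-deme model is ignored; this
  single-population reading is what SFS-only analyses use.
* `demog_nelson_eur()` — the two-epoch European model of Nelson et al.
  (2012): constant 7,700 until exponential growth over the last 375
  generations to a present effective size of about 4 million diploids.
* `demog_modified_nelson()` — the same ancestral background with a
  re-estimated recent epoch: present size 4,009,877 diploids, growth onset
  119.47 generations ago at 5.38% per generation (compound convention).

At 67,500 chromosomes the analytic expected spectra of these presets give
rare-variant fractions of about 59%, 75% and 78% respectively — the
ordering expected from their recent growth intensities.

## Expected spectra at large sample sizes

The expected unfolded spectrum follows from expected level times,
$E[\xi_b] = \sum_k k\, p(n, b, k)\, E[T_k]$, with
$p(n,b,k) = \binom{n-b-1}{k-2}/\binom{n-1}{k-1}$ the classical probability
that a level-$k$ branch subtends $b$ leaves; $p$ is evaluated in log space
so the mixture is stable at any $n$. For $E[T_k]$ the `analytic` method
uses a hybrid:

* for a single constant epoch, the closed form $4N/\big(k(k-1)\big)$
  (exact, so the $1/i$ law is reproduced to numerical precision);
* for piecewise models and lineage counts above `K_exact` (default 200),
  the deterministic decay of the ancestral lineage count. In pair-intensity
  units $\Lambda(t) = \int_0^t dt'/\,2N(t')$ the decay ODE has the closed
  form $K(\Lambda) = \big(1 - \tfrac{n-1}{n} e^{-\Lambda/2}\big)^{-1}$,
  which is inverted per epoch;
* below `K_exact`, the exact death chain integrated as a small ODE system
  (deSolve, `rtol = 1e-10`), with the unbounded constant terminal epoch
  added in closed form via the survival probabilities at its boundary.

The deterministic phase carries an $O(1/k)$ relative bias per level, which
is why the hand-off is delayed until $k \le 200$; the simulation method
(`method = "simulation"`) provides an unbiased cross-check and the two are
required to agree within Monte-Carlo error in the test suite.
`expected_rare_fraction()` evaluates only the extreme frequency classes
plus the total branch length, so it is $O(n)$ and comfortable at
$n = 67{,}500$; the full-spectrum function guards its $O(n^2)$ cost with
`max_n`.

## Ancestral polymorphism bound

The probability that a polymorphism predates a species split is bounded by
the probability that at least two sample lineages survive to the split
time. The estimator simulates genealogies, weights each by its total
branch length (the mutation opportunity — conditioning on the site being
polymorphic), and reports the weighted fraction with two or more lineages
at the split. `worst_case = TRUE` replaces all post-out-of-Africa epochs
with "no coalescence", so all $n$ lineages enter the ancestral epoch. The
weighting is our concrete reading of the polymorphism conditioning; the
bound is validated against a brute-force oracle on small constant-size
samples, and is monotone in the pre-out-of-Africa size as expected.

# Finite-sites simulation

Genealogies are drawn from the Kingman coalescent under the piecewise
model (multiple mergers are irrelevant at these sample-to-population-size
ratios). Each genealogy carries `L = 1000` non-recombining sites; per site
the number of mutation events is Poisson with intensity $M$ per generation
along every branch, the root base is uniform on the four nucleotides, and
every event replaces the current base by one of the other three uniformly
(the 4x4 Jukes–Cantor model). Sites are classified monomorphic /
biallelic / tri- / quadallelic; tri- and quadallelic sites are excluded
from spectra (mirroring the usual data filter) but counted. The derived
allele is the non-root allele; when recurrent mutation removes the root
allele from the sample the minor allele is reported as derived —
mispolarization is part of the phenomenon being modelled.

Allele states are resolved per site in $O(k \cdot \text{depth})$ for $k$
mutation events, using subtree leaf counts and the nesting structure of
mutated edges rather than propagating bases through every node. This is
what makes spectra at $n = 67{,}500$ chromosomes affordable on a single
core (seconds per rate).

Two estimator details matter:

* **Stopping bias.** Simulating "until 10,000 biallelic sites" and
  estimating ratios from the stopped totals overweights high-yield
  genealogies; with high rates a handful of trees reaches the floor and
  the bias is visible. `estimate_grid()` therefore uses staged sampling:
  a fixed pilot estimates the per-tree yield and each subsequent stage's
  tree count is fixed before its outcomes are seen.
* **Correlated sites.** Sites sharing a genealogy are strongly dependent,
  so standard errors come from independent batches of genealogies, not
  from binomial formulas.

The simulator is validated against a closed form at $n = 2$: integrating
the Jukes–Cantor mismatch probability over the exponential coalescence
time gives $P(\text{biallelic}) = \tfrac34\,\theta'/(1+\theta')$ with
$\theta' = \tfrac{16}{3} N M$.

# The rate mixture

Within a mutation type, rates follow the mean-preserving lognormal above.
With $\sigma = 0.57$ (the package default; 0.83 and 0.8 are shipped as the
Hodgkinson et al. reference values for non-CpG and CpG sites) about 3% of
sites exceed five times their type's mean rate. Conditioning on a site
being a biallelic polymorphism tilts the rate distribution by
$P(S{=}1\mid M)$ (Bayes), and the expected rare fraction is the trapezoid
quadrature of the total-expectation integral in $\log_{10} M$ over
$\mu \cdot 10^{\pm 4\sigma}$ (capturing over 99.9% of the mixture mass;
the span is configurable). Grid quantities are interpolated log-linearly,
matching the log-uniform grid design; a mixture whose support leaves the
grid raises an error naming the gap rather than extrapolating. Note that
the biallelic conditioning also *damps* the influence of the fastest
sites: at high $M$ most sites are tri- or quadallelic and drop out of
$P(S{=}1\mid M)$, so the conditioned rare fraction falls much more slowly
with $\mu$ than the fixed-rate curve does.

Fitting $\sigma$ by least squares on a rare-fraction curve is provided
(`fit_sigma()`) as an extension; the headline analyses keep $\sigma$
fixed.

# The conditioned SFS

Site records carry the human major/minor alleles and counts, 30-bp flanks,
gene strand, functional class, and orthologous reference alleles for
chimpanzee, gorilla, orangutan, gibbon, macaque and baboon. A site is
*human-private* when every non-missing primate allele equals the human
major allele, and *substituted-s* when exactly species *s* carries the
human minor allele and all other primates carry the major allele. Baboon
participates in the ascertainment but never forms a category. Because the
ascertainment uses all six species, the default (strict) mode requires
complete primate data for a substituted call; a lenient mode that ignores
missing species is provided but labelled non-faithful. An alternative
conditioning by the most closely related minor-allele carrier is also
implemented.

Mutation types are computed on the major-to-minor change and collapsed
with the reverse complement (six mononucleotide types; `CpG>TpG` overrides
`C>T` when the reference context matches; trimer types append the
strand-collapsed flanking bases). CpG context uses the human reference
flank only. The coding/template strand partition re-expresses changes
relative to the gene's coding strand without the reverse-complement
collapse, excluding CpG transitions.

# The two-category clock model

Mutation types split into a uniform-clock category U (constant yearly
rate across lineages; CpG-transition-like, driven by spontaneous
deamination) and a generation-scaled category G (constant per-generation
rate, so the yearly rate is inversely proportional to generation time).
A site carries a lognormal multiplier with mean one. Substitution on a
lineage is Poisson thinning of branch length in years; human polymorphism
probability is linear in the per-generation human rate by default (a rate
grid can replace this). The posterior category mix and rate distribution
at substituted-$s$ sites follow by Bayes weighting and quadrature.

Two qualitative predictions are exercised in the tests: in the pure
uniform-clock limit the rate distribution is identical across substituted
species (branch lengths cancel in the linear regime), and with two
categories the uniform-clock share — and hence the expected CpG
enrichment — increases with the substituted species' generation time.
Default branch lengths and generation times are round literature numbers
(e.g. Langergraber et al. 2012) and are explicitly user-editable;
orangutan's long generation time is the known exception to the
relatedness ordering, which is why the tests assert monotonicity in
generation time, never in relatedness.

# The rare-variant logistic model

Only coding sites enter; the species blocks interact with the synonymous
indicator exactly as in the formula above, and there is no main effect of
$Z$ — human-private synonymous and nonsynonymous sites share the
baseline. Sites are aggregated by covariate pattern and fitted by IRLS
(`glm`), which is deterministic; the reported log-likelihood is the
Bernoulli likelihood of the fitted cell probabilities, so nested type
resolutions (`none` ⊂ `mono` ⊂ `trimer`) are directly comparable.
Complete separation raises an error naming the covariate. CpG transitions
are excluded by default and can be kept with `include_cpg = TRUE`.

The trend test on the species coefficients is Spearman rank correlation
against split times with a *two-sided exact permutation* p-value from all
$n!$ orderings (midranks under ties). For five species a perfect ordering
gives $p = 2/120 \approx 0.0167$ and a single adjacent transposition
($|\rho| = 0.9$) gives $p = 10/120 \approx 0.083$; printed values of
0.016 and 0.08 in the literature correspond to these configurations up to
rounding convention.

# The synthetic-data generator

`generate_sites()` draws, per site: a substitution category (human-private
majority; substituted categories in the relative proportions of a large
exome call set, upweighted so desk-scale tables have usable category
counts); a mutation type from a per-category composition in which the CpG
fraction declines with phylogenetic distance (0.30 down to 0.10 across
chimpanzee to macaque, 0.17 for human-private); a latent site rate from
the mean-preserving lognormal; a minor-allele count from the type's
conditional spectrum; primate alleles consistent with the category; flanks
consistent with the type (CpG sites get their context base, non-CpG C>T
sites have it explicitly broken, and each site is presented on a random
strand); and nuisance covariates. Every latent is recorded in the
manifest, so the classifiers can be held to 100% agreement.

Type spectra come from the analytic infinite-sites expectation when the
expected number of mutation origins per site is negligible, and from the
finite-sites simulator otherwise. One deliberate calibration is applied:
the **mutation opportunity scale** (default 16). Demographies fitted to
SFS *shape* underestimate the absolute polymorphism density and hence the
recurrence level of real exome data; multiplying the opportunity by 16
places CpG transitions at roughly 6–7 expected origins per site at
67,500 chromosomes, the regime in which their spectra show the
rare-variant depletion, the cross-population sharing excess, and the
small-sample rank inversion seen in such data. Setting
`opportunity_scale = 1` recovers the raw demographic-model opportunity.
Even at the calibrated opportunity the mixture-conditioned CpG rare
fraction (about 0.67 at full scale, versus about 0.73–0.76 for the slow
types) is far less depleted than the most extreme published data values;
under this construction the biallelic conditioning bounds how much the
fast tail can weigh in, and we document rather than force that gap.

Two-population splits are hypergeometric by default. A stylized structure
mechanism can be layered on: single-origin low-frequency sites become
private to one subpopulation with a given probability, while sites with
multiple independent origins place each origin wholly into a random
subpopulation — reproducing, qualitatively, the excess sharing of
high-rate types at low frequencies.

What the generator does **not** emulate: linkage disequilibrium (sites are
independent, as in all site-wise analyses here), sample-size heterogeneity
across sites, sequencing error, biased gene conversion, and selection
(unless the optional nonsynonymous singleton boost is switched on). Tests
passing on synthetic tables therefore validate the machinery and the
modelled mechanisms, not the full complexity of real call sets.

# Subsampling and the rank inversion

Whether the rare fraction of a subsampled spectrum should be renormalized
to sites still segregating in the subsample is a genuinely open design
point; `project_sfs()` therefore reports the raw expected counts with the
lost and fixed mass as attributes, and `fraction_rare()` on the projection
gives the renormalized form. The two behave very differently for the
fast-versus-slow type comparison. Renormalized, the rare-fraction gap
between a CpG-like and a slow type collapses under subsampling (from
several percentage points at 67,500 chromosomes to a fraction of a point
by a few hundred chromosomes) but, in this finite-sites construction, does
not resolvably invert. Per original site (unrenormalized), the ordering
inverts cleanly: below roughly 30,000 chromosomes the fast type carries
*more* rare-variant mass, because its recurrence-lifted sites populate the
moderately-low frequencies that become singletons in subsamples while the
slow type's ultra-rare excess is simply lost. The acceptance suite asserts
the inversion on the per-site form and the gap collapse on the
renormalized form, using a paired simulation design (both rates dropped on
one stream of genealogies) so that the contrast is free of genealogy-level
noise.

# Problem sizes and numerical choices

The test suite runs the scaled-down study conditions: rate grids at 200
chromosomes with a 10,000 biallelic-site floor per rate (40 grid points,
$10^{-9}$ to $5.3\times10^{-5}$); mixture cross-checks at 20,000 biallelic
sites; full-scale (67,500-chromosome) simulated spectra only where the
phenomenon requires them — the conditioned-SFS gradient and the
subsampling inversion — at a 20,000–60,000 biallelic floor. Bootstrap
intervals default to 1,000 percentile replicates, seeded. Quadratures use
512 trapezoid nodes in $\log_{10} M$; doubling the resolution moves the
mixture rare fraction by less than $10^{-3}$. All stochastic entry points
take explicit seeds and are bit-reproducible under them.

# Known limitations

* The analytic expected-SFS method is approximate between `K_exact` and
  the deterministic regime; its agreement with simulation is asserted
  statistically, not to machine precision, for growing populations.
* The ancestral-polymorphism estimator's branch-length weighting is one
  defensible reading of the polymorphism conditioning; alternatives
  (e.g. unweighted genealogies) differ at the few-percent level.
* The lognormal is the only mixing distribution implemented; bimodal
  rate structure (methylated vs unmethylated CpGs) is not represented,
  which is one reason the generator cannot reach the most extreme
  depletion levels seen in data.
* No recombination within simulated blocks, and no context dependence
  inside the simulator — context lives entirely in the site-table layer.
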