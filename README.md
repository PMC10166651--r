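# microtrace

Individual and species assignment from longitudinal fecal-microbiota
profiles.

## The problem

Fecal 16S profiles carry two nested signals: a **species** signal (core
bacterial families tied to diet and digestive physiology — a carnivore's
microbiota looks nothing like a ruminant's) and an **individual** signal
(signature families and host-specific abundance fluctuation). Day-to-day
oscillation of the microbiota blurs both: a single sample can sit closer
to another animal's profile than to its own host's profile of the
previous day. `microtrace` asks whether hosts can nevertheless be
re-identified from their microbiota, by clustering *whole time series* of
daily samples instead of single samples, and which bacterial families
carry the discrimination.

The intended users are microbial-ecology and animal-welfare researchers
with family-level amplicon feature tables from repeated (daily) sampling
of known individuals — for example zoo populations, where a non-invasive
individual microbiota profile is a cheap monitoring tool.

## The method

Two branches share one backbone (distance → k-nearest-neighbor sets →
Jaccard similarity → two clusterers → scoring):

- **Single clustering.** Each sample is an item. Distances are Euclidean
  between relative-abundance vectors.
- **Time-series clustering.** Each individual's consecutive-day series is
  an item. Distances are dynamic time warping (DTW) with local cost
  `c(t,u) = ||a_t − b_u||₂` and the recursion
  `D(t,u) = c(t,u) + min(D(t−1,u), D(t,u−1), D(t−1,u−1))`;
  element repetition along the warping path absorbs missed sampling days.

From either distance matrix, item *i*'s k nearest neighbors `N(i)` (self
included, `k = round(√N)` by default) define the shared-nearest-neighbor
similarity `J(i,j) = |N(i)∩N(j)| / |N(i)∪N(j)|`. Two clusterers consume
the graph:

- **Ward's linkage** on `d = 1 − J`: at each step the merge with the
  minimal increase in error sum of squares (ESS), via the Lance–Williams
  update; the cluster number is chosen automatically at the largest
  merge-height gap (at least 2 clusters in species mode, at least 3 in
  individual mode).
- **Greedy modularity community detection**: starting from singletons,
  repeatedly apply the merge with the largest gain in weighted modularity
  `Q = Σ_c (e_c − a_c²)`, and return the best partition seen.

Agreement between clusterers and with the true labels is scored by
normalized mutual information, `NMI = I(a;b) / √(H(a)H(b))` (natural
logs). Finally, the families that drive the separation are identified by
L1-penalized multinomial logistic regression (LASSO) on z-standardized
proportions, with the penalty chosen by stratified 5-fold cross-validated
deviance; descriptive *core* (present in every consecutive sample) and
*persistent* (present on at least two consecutive days) taxon calls and
mean ± sd percentage summaries complete the attribution.

A seeded generator (`generate_dataset()`) emulates the study design —
2 species × 7 series × up to 8 consecutive days, logistic-normal
compositions with planted species-core and individual-signature families,
AR(1) day noise, sporadically present families, missed days for the
carnivore, multinomial depths between 5,836 and 230,928 reads — so the
whole pipeline is testable against known ground truth.

## Worked example

```r
library(microtrace)

sim <- generate_dataset(generator_config(seed = 1))
fit <- microtrace(sim$counts, sim$metadata)
print(fit)
```

```
Individual/species assignment from longitudinal microbiota profiles
NMI normalization: sqrt 

Single clustering 
      slice       mode nmi_com_ward nmi_ward_true nmi_com_true k_ward k_com
      total    species         0.85          0.83         0.71      3     4
      tiger individual         0.69          0.19         0.23      3     3
 wildebeest individual         0.67          0.23         0.21      4     3

Time series clustering 
      slice       mode nmi_com_ward nmi_ward_true nmi_com_true k_ward k_com
      total    species         1.00          1.00         1.00      2     2
      tiger individual         0.50          0.61         0.44      3     2
 wildebeest individual         0.66          0.74         0.47      5     2
```

Reading the table: on single samples, species assignment is imperfect
(Ward vs truth 0.83 with 3 clusters instead of 2) and individual
assignment within a species nearly fails (NMI ≈ 0.2). Aligning each
individual's series by DTW first lifts species assignment to exact
recovery (NMI = 1, 2 clusters) and roughly triples individual-mode
agreement — the package's central claim: host identity lives in the
*temporal pattern* of the microbiota, not in any single day's snapshot.

```r
head(coef(fit, "species"), 4)
```

```
      tiger wildebeest
fam01 0.255     -0.255
fam02 0.344     -0.344
fam03 0.313     -0.313
fam04 0.637     -0.637
```

The species-mode LASSO selects exactly `fam01`–`fam08` here — precisely
the eight planted species-core families of the generator
(`sim$truth$families`), with tiger cores weighted positive for tiger and
negative for wildebeest. `summary(fit)` additionally lists per-species
individual-mode selections and the families that are core in every
series; `plot(fit, "timeseries.total")` draws the series dendrogram.

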