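# DyeTrace

Clonal lineage-tree reconstruction and branching-process modelling of
cortical neurogenesis from dye-dilution intensities.

During neocortical development, radial glial progenitors (RGPs) produce
excitatory neurons directly (N divisions) or indirectly through
intermediate progenitors — neurogenic IPs, which divide once into two
neurons, and proliferative IPPs, which make two IPs and hence four
neurons. A division-tracking dye (CFSE) loaded into a mitotic RGP halves
at every division, so each labelled neuron's fluorescence intensity
records its division depth: cells at intensity φ₁/2^(h−1) sit at
hierarchy level h, where φ₁ is the brightest cell of the clone. DyeTrace
is for developmental neuroscientists and quantitative biologists who want
to:

* **reconstruct** each clone's binary lineage tree from per-cell
  intensities, using the sibling combination algebra
  ([βγ, γβ, κγ, γκ, αγ, γα, γγ] = γ; [κκ] = β; [ββ] = α; seven pairs
  prohibited — γ, α, β, κ denoting RGP, IPP, IP, neuron), exhaustive
  pairing enumeration, canonical deduplication, and spatial proximity to
  decide which equal-intensity neurons share an IP;
* **simulate** lineages under a four-rule stochastic model: clone size
  `PyN ~ 0.35·tPois(λ₁ = 4.09) + 0.65·tPois(λ₂ = 7.62)` (zero-truncated),
  a uniform first-generation fate, a stationary 3×3 row-stochastic
  transition matrix p_ij over (IPP, IP, N), and boundary renormalization
  when fewer than four neurons remain;
* **synthesize** realistic observation tables (truncated-normal
  intensity-partition noise, inside-out radial positions with tight
  same-IP sibling clusters, Satb2/Ctip2/Fog2-consistent neuron classes,
  ~7% apoptotic dropout, 2× background detection threshold);
* **quantify** populations of clones: per-generation division-pattern
  summaries, exponential decay of neuron output `y(g) = a·e^(λg)`,
  transition-matrix estimation with chi-square dependency and homogeneity
  tests, Kullback–Leibler comparisons, zero-truncated Poisson mixture
  fitting by EM, cumulative distance analysis (Kolmogorov–Smirnov), and
  20-feature Ward clustering of clones into k = 5 clusters.

## Worked example

Simulate a five-neuron lineage, generate noisy observations, and
reconstruct it:

```r
library(DyeTrace)
set.seed(7)
truth <- simulateLineage(pynTarget = 5, cloneId = "demo")
syn <- synthesizeCellTable(list(truth),
                           noise = NoiseModel(daughterFractionSd = 0.02),
                           dropout = FALSE, threshold = FALSE, seed = 8)
round(cells(syn$clones[[1]])$intensity, 1)
#> [1] 253.6 263.2 121.6 114.7 122.9
res <- reconstructClone(syn$clones[[1]])
chosenTree(res)
#> LineageTree 'demo' (root RGP, 5 neurons)
#>   generations: G1:IP G2:IP G3:N G4:EXIT
#> RGP ti=1
#>   IP ti=0.5
#>     NEURON [demo_n1] ti=0.25
#>     NEURON [demo_n2] ti=0.25
#>   RGP ti=0.5
#>     IP ti=0.25
#>       NEURON [demo_n3] ti=0.125
#>       NEURON [demo_n4] ti=0.125
#>     RGP ti=0.25
#>       RGP (exit) ti=0.125
#>       NEURON [demo_n5] ti=0.125
matchesGroundTruth(res, truth)
#> [1] TRUE
```

The two brightest cells (~250 a.u.) form the G1 IP pair; the three cells
near 120 a.u. lie one halving deeper, and proximity assigns the adjacent
two to the G2 IP, leaving the third as the G3 neuron beside the exiting
RGP. Population statistics over a 258-lineage batch:

```r
set.seed(9)
trees <- lapply(1:258, function(i) simulateLineage(cloneId = paste0("c", i)))
gs <- summarizeGenerations(trees)
head(gs[, c("generation", "nLineages", "outputMean", "propIPP",
            "propIP", "propN", "exitFraction")], 5)
#>   generation nLineages outputMean propIPP propIP propN exitFraction
#> 1          1       258      2.205   0.295  0.322 0.384        0.000
#> 2          2       231      1.395   0.074  0.338 0.589        0.105
#> 3          3       184      1.043   0.043  0.332 0.625        0.203
#> 4          4       128      0.740   0.070  0.281 0.648        0.304
#> 5          5        82      0.419   0.024  0.244 0.732        0.359
fitDecay(gs)$lambda
#> [1] -0.5995
```

G1 fates are near-uniform (feasibility-adjusted), later generations shift
toward direct N divisions, and the mean neuron output per lineage decays
exponentially with generation (decay index λ ≈ −0.60 for the illustrative
default transition matrix; exited lineages count as zero output).

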