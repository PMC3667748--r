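# sfsmix

Maximum-likelihood inference of **strong purifying selection** from deep
population polymorphism data, built around the folded site frequency
spectrum (SFS) *extended with the zero-frequency class*.

## The problem

Strong purifying selection (|4 N<sub>e</sub> s| ≫ 1) removes deleterious
variants so efficiently that almost none appear in a population sample:
it barely changes the *shape* of the observed SFS and instead erases
polymorphism outright. Classic SFS methods, which look only at the shape
of the spectrum of segregating sites, therefore miss it entirely — and a
locally reduced mutation rate produces a deceptively similar deficit of
SNPs. With a deep sample (here 130 chromosomes) and a genome-wide set of
sites, the two become distinguishable: under strong-but-finite selection a
few ultra-rare variants must still be observed, while a mutational cold
spot yields none beyond the neutral expectation.

The package implements this inference for the canonical *Drosophila*
setting: four-fold degenerate (4D) synonymous sites as the test class,
short-intron interiors (introns < 86 bp, trimmed 16 bp from the 5' and
6 bp from the 3' end) as the neutral reference, and a matched bootstrap
that pairs each test site with nearby (< 1 kb) reference sites carrying
the same major allele, controlling GC-dependent mutation rate and
regional variation in diversity.

## The model

For a sample of *n* chromosomes, the expected fraction of sites with a
derived allele in *i* copies, for scaled selection γ = 4 N<sub>e</sub> s
and scaled mutation rate θ = 4 N<sub>e</sub> μ, is the Wright
stationary density integrated against binomial sampling:

```
g(i) = ∫₀¹ θ (e^{γq} − e^{γ}) / ((1 − e^{γ}) q(1−q)) · C(n,i) qⁱ(1−q)^{n−i} dq ,
g(0) = 1 − Σ_{i≥1} g(i)            (the monomorphic, "amplitude" class)
```

(neutral limit g(i) = θ/i). The spectrum is folded on minor-allele
counts. Test sites follow a mixture of selection categories — neutral
(γ = 0), weak (0 < |γ| < 5), strong (|γ| > 100, capped at a computational
limit of 700) — with fractions f<sub>c</sub>; reference sites are fully
neutral with the same θ. The joint likelihood is the product of
multinomial likelihoods of the two observed spectra (zero class
included), maximized by multi-start Nelder–Mead on transformed
coordinates. An optional per-frequency-class modifier α<sub>x</sub>
(shared by both spectra, α₀ = 1) absorbs demography and other common
distortions.

## Worked example

Generate a synthetic panel at the default study conditions scaled to
200,000 sites per class (θ = 0.0132, 22.6% of test sites at γ = −283,
GC 64% vs 31%, GC-dependent mutation rate, 1-kb regional rate variation,
depths 100–168), normalize to 130 chromosomes, run the matched bootstrap,
and fit one replicate:

```r
library(sfsmix)
cfg   <- sim_config(n_fourfold = 2e5, n_intron = 2e5)
sim   <- simulate_sites(cfg, seed = 42)
sites <- resample_sites(sim$sites, seed = 43)
test  <- sites[sites$site_class == "FOURFOLD", ]
ref   <- sites[sites$site_class == "SHORT_INTRON", ]

idx <- pair_index(test, ref, mode = "major_allele", max_dist = 1000)
idx
#> Pair index (mode major_allele, max_dist 1000): 200,054 of 200,067 test sites pairable (100.0%), mean 20.1 partners

bootstrap_deficit(idx, n_boot = 10, seed = 44)
#> Matched-bootstrap missing polymorphism: 0.1981 (se 0.0099, 10 replicates, 200,054 pairs/replicate)

sp  <- paired_spectra(idx, n_boot = 10, seed = 44)
fit <- sfs_selection_fit(sp[[1]]$test, sp[[1]]$ref)
summary(fit)
#> Extended-SFS selection mixture fit (n = 130 chromosomes)
#>   theta (4*Ne*mu): 0.0131
#>         fraction     gamma
#> neutral   0.7993    0.0000
#> weak      0.0000        NA
#> strong    0.2007 -352.7191
#>   model: reduced (weak-category LRT p = 0.996)
#>   log-likelihood: -186733.71
#>   observed SNP density: test 0.0578, reference 0.0712
#>   retention ratio of the strong category: 0.0579
#>   implied missing polymorphism (f_strong * (1 - r)): 0.1891
```

Reading the output: test sites carry ~20% fewer SNPs than their matched
neutral partners (the bootstrap deficit), and the likelihood attributes
this to ~20% of test sites under strong purifying selection; the
weak-selection category is not supported by the likelihood-ratio test and
is reported as zero. At this reduced number of sites the strength
estimate γ̂ is noisy (the strong category's SFS signature is concentrated
in a handful of ultra-rare classes); at the full study scale of ~8.6×10⁵
sites per class, γ̂ concentrates around the generating value.
`plot(fit)` overlays observed and fitted spectra; `coef()`, `logLik()`,
`fitted()`, `residuals()`, `simulate()` and `predict()` behave as usual
for a fitted model. `run_pipeline()` chains the stages above and writes
all artifacts as plain text with a provenance record.

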