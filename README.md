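# mitodemix

Probabilistic deconvolution of mitochondrial DNA mixtures from amplicon
MPS data.

Mitochondrial DNA is haploid — each person contributes a single
16,569 bp circular haplotype — which makes it unusually well suited to
mixture interpretation in forensic and clinical genetics. `mitodemix`
takes paired-end reads from a suspected mtDNA mixture, reduces noise
(paired-read error correction, primer trimming, and removal of nuclear
mitochondrial segment (NUMT) reads by differential alignment), and then
jointly estimates the contributing haplogroups and their mixture
proportions, reporting the diagnostic SNPs behind each call as a partial
haplotype. Known contributor haplotypes can be grafted into the candidate
set, which resolves spurious haplogroup calls caused by private mutations
and improves recovery of trace (1–2%) contributors.

## The model

Every haplogroup *h* of a phylotree implies an expected mitogenome (the
reference with the cumulative root-to-*h* variants applied). A fragment
*i* with observed base *b<sub>ip</sub>* and Phred error probability
*ε<sub>ip</sub>* = 10^(−Q/10) at diagnostic position *p* scores

&nbsp;&nbsp;ℓ<sub>ih</sub> = Σ<sub>p</sub> log(1 − ε<sub>ip</sub>) if
*b<sub>ip</sub>* matches the expected allele of *h*, else
log(ε<sub>ip</sub>/3).

Mixture proportions **π** over the candidate set maximise
Σ<sub>i</sub> log Σ<sub>h</sub> π<sub>h</sub> exp(ℓ<sub>ih</sub>) via EM
(responsibilities in the E-step, proportion averages in the M-step;
log-space, deterministic uniform initialisation). Contributors are then
selected by iterative filtering on the estimated proportion and on the
number of fragments uniquely supporting each candidate. Everything is
seeded and reproducible byte for byte.

A bundled synthetic study system (a 16,569-base reference-shaped sequence,
a 23-haplogroup mini phylotree, primer set and NUMT catalogue) plus a
seeded amplicon-mixture generator make the whole pipeline testable without
any external data.

## Worked example

Simulate a 70:30 two-person mixture at ~110x coverage, preprocess it, and
deconvolute:

```r
library(mitodemix)

ref  <- synthetic_reference()
tree <- synthetic_phylotree(ref)

s1  <- simulate_sole_source(ref, tree, haplogroup = "L0a1", n_fragments = 7000, seed = 11)
s2  <- simulate_sole_source(ref, tree, haplogroup = "U5a",  n_fragments = 3000, seed = 12)
mix <- mix_fastqs(list(s1, s2), ratio = c(7, 3), total = 10000, seed = 13)

pre <- preprocess_pipeline(mix$pairs, synthetic_primer_set(ref), ref,
                           build_numt_catalogue(ref)$sequences)
obs <- build_observations(merge_pairs(pre), tree, ref)
res <- deconvolute(obs, tree)
res
#> <deconv_result> 2 contributor(s)
#>   L0a1            0.713  [11 diagnostic SNPs]
#>   U5a             0.287  [8 diagnostic SNPs]
```

Both haplogroups are recovered and the proportions land within ~0.015 of
the simulated 0.70/0.30 truth. The diagnostic report shows, per expected
SNP, the fraction of covering fragments carrying the derived allele —
for the 30% contributor those fractions sit near 0.3, and the observed
SNPs form its partial haplotype:

```r
head(res$diagnostics[["U5a"]]$snps, 4)
#>   position expected_allele observed_fraction n_covering n_derived
#> 1     3197               G         0.2583333        120        31
#> 2     9477               T         0.1858407        113        21
#> 3    11467               C         0.2967033         91        27
#> 4    12372               A         0.2452830        106        26
res$diagnostics[["U5a"]]$partial_haplotype
#> [1] "3197G" "9477T" "11467C" "12372A" "13617T" "14793A" "16256A" "16270C"
```

With suspected contributors in hand, graft their full haplotypes (private
mutations included) to resolve spurious calls and trace contributors:

```r
res2 <- deconvolute_with_knowns(obs, tree,
                                list(known_haplotype("suspect1", expected_variants(tree, "L0a1")),
                                     known_haplotype("suspect2", expected_variants(tree, "U5a"))))
```

A file-based interface (`run_pipeline()` on a YAML config) and a thin CLI
(`exec/mitodemix` with verbs `simulate`, `preprocess`, `run`,
`deconvolute`, `report`; exit codes 0/2/3 for success/config/data errors)
wrap the same functions for shell use.

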