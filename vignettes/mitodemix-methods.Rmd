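---
title: "Deconvoluting mitochondrial DNA mixtures: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvoluting mitochondrial DNA mixtures: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodemix)
```

## The problem

Human mitochondrial DNA is a 16,569 bp circular genome inherited as a single
haplotype per individual. When a forensic or clinical sample contains DNA
from several people, the sequencing reads are a mixture of two or more
mitogenome haplotypes, typically at unequal proportions, confounded by
sequencing error, degenerate-primer artifacts, nuclear copies of
mitochondrial segments (NUMTs) and point heteroplasmy. `mitodemix` jointly
estimates *which* haplogroups contributed and *how much* each contributed,
from paired-end amplicon MPS data, and reports the diagnostic SNPs behind
each call as a partial haplotype.

## The mixture model

Every haplogroup `h` in a phylotree implies an expected mitogenome: the
reference sequence with the cumulative variants of the root-to-`h` path
applied (a back mutation, written `"X!"`, removes the variant at `X`; a later
assignment at a position overrides an earlier one). For a fragment `i` with
observed base `b_ip` and Phred-derived error probability
`eps_ip = 10^(-Q/10)` at each covered diagnostic position `p`, the
log-likelihood under haplogroup `h` is the independent-error model

```
l_ih = sum_p [ log(1 - eps_ip)   if b_ip equals the expected allele of h at p
               log(eps_ip / 3)   otherwise ]
```

Only substitutions enter this likelihood; insertions and deletions are
parsed and carried through the phylotree model but do not participate,
reflecting the SNP-only character of haplogroup diagnostics in amplicon
panels.

With mixture proportions `pi` over a candidate set `H`, the data
log-likelihood is `sum_i log sum_h pi_h exp(l_ih)`, maximised by EM:

* E-step: responsibilities `r_ih = pi_h exp(l_ih) / sum_h' pi_h' exp(l_ih')`
  (computed in log space);
* M-step: `pi_h = mean_i r_ih`.

Initialisation is uniform (deterministic; seeded random restarts are
available behind `n_restarts`). Convergence is declared when
`max_h |delta pi_h| < 1e-4` (`tol`), capped at 500 iterations; mini-tree
instances converge in tens of iterations. The log-likelihood is asserted to
be non-decreasing at every step, and fragments covering no diagnostic
position are flagged uninformative and excluded (they carry no signal and
would only dilute the responsibilities).

### Contributor selection

The EM fit assigns some proportion to every candidate. Reported
contributors are chosen by iterative filtering: a candidate is discarded
when its proportion falls below `min_prop` **or** fewer than
`min_unique_frags` fragments give it responsibility above 0.5; EM is then
re-run on the survivors until the set is stable. The unique-fragment count
is the primary evidence filter (default 10 fragments). The proportion floor
defaults to `min_prop = 0.005`: the floor must sit strictly below the
smallest contribution the tool is expected to resolve, because the
proportion estimate of a true 1% trace contributor is centred at 0.01 —
a floor at exactly 0.01 would turn trace detection into a coin flip driven
by sampling noise rather than evidence. Both thresholds are configurable.

Candidates with identical cumulative variant sets are collapsed before
fitting (keeping the known-haplotype label when a grafted known duplicates
a tree node); two genuinely duplicated candidates passed directly to
`em_fit()` split responsibility but conserve their summed proportion. For
very large candidate sets (more than 200), a coarse pruning pass
(`prune_candidates()`) first drops haplogroups that are never within a
factor of two of any fragment's best likelihood; at the bundled mini-tree
scale (23 haplogroups) this is unnecessary and skipped.

### Known haplotypes, spurious haplogroups and trace contributors

Amplicon fragments are short (about 167 bp on average), so a private
mutation that happens to coincide with another clade's diagnostic SNP is
usually observed on fragments that carry no other informative position.
Those fragments support the unrelated haplogroup almost exclusively, and
the selection step can report it as an extra contributor supported by one
or two diagnostic SNPs — the spurious-haplogroup phenomenon. The report
flags such contributors (`few_snp_support`), counting only observed SNPs
not shared with the other reported contributors' expected haplotypes.

Grafting the suspected contributors' full haplotypes
(`graft_known_haplotype()`, `deconvolute_with_knowns()`) resolves this: the
grafted known, which carries the private mutation, out-competes the
spurious branch for exactly those fragments. Grafting also adds the knowns'
private positions to the diagnostic position set (observations are rebuilt
on the augmented tree), which is what makes 1% trace contributors
recoverable: the extra private positions multiply the number of fragments
that distinguish the trace haplotype from the major one.

## Preprocessing

Stage order is fixed: pair error correction, primer trimming, NUMT removal.

* **Pair correction.** Both mates of an amplicon pair observe the same
  molecule. The reverse read is reverse-complemented and overlap-aligned to
  the forward read (ungapped sliding offset maximising matches, seeded by
  shared 15-mers, minimum overlap 20 bases, minimum identity 0.75 —
  amplicons average ~167 bp against 2x150 reads, so overlap is the norm).
  If the mates disagree at two or fewer positions, each disagreement is
  replaced in both mates by the higher-quality call (ties keep read 1, for
  determinism). Pairs with more than two disagreements or no acceptable
  overlap pass through unchanged and are counted; discarding them would
  bias the EM, which already models error.
* **Primer trimming.** The longest primer variant (IUPAC-degenerate bases
  pre-expanded) or its reverse complement matching at a read terminus
  within one mismatch (configurable) is removed; interior occurrences are
  untouched. One mismatch is allowed precisely because degenerate primers
  are expected to mismatch the template.
* **NUMT removal.** Reads are aligned to a nuclear reference (a NUMT
  catalogue) and to the circularized mitochondrial reference. Candidates
  are reads mapping to the nuclear side without soft-clipping at a
  Levenshtein distance below three; a candidate is removed when its
  nuclear distance is strictly smaller than its mitochondrial distance
  (ties keep the read; an unmapped side counts as infinite distance). A
  pair is removed when either mate is classified as NUMT. Distances are
  recomputed from the sequences even for SAM/BAM input, so results do not
  depend on aligner tag dialects.

Alignment here is a deliberately small placement routine — exact 15-mer
seeding at staggered offsets plus Levenshtein verification of the spanned
window, with soft-clipping declared when more than two terminal bases fall
outside the reference span. External aligners remain pluggable through
SAM/BAM input; the built-in routine exists so that the whole pipeline is
exercisable on synthetic data without genome-scale references. The
mitochondrial reference is circularized by appending its first 200 bases
(longer than any amplicon), so control-region fragments align contiguously;
coordinates are folded back modulo the genome length.

Alignment-file (BAM) input skips correction and trimming with a warning —
those stages need the original FASTQ pairs — but the NUMT stage still runs.

## The synthetic study system

All validation runs on generated data; nothing external is downloaded.

* **Reference**: a seeded random 16,569-base sequence
  (`synthetic_reference()`, bundled as `extdata/synthetic_mito.fasta`).
  It reproduces the length and coordinate conventions of the real
  mitogenome, not its composition.
* **Tree**: 23 haplogroups in four clades (`synthetic_phylotree()`,
  bundled as `extdata/mini_phylotree.tsv`): two deep clades (L0, M) with
  7-11 cumulative variants at the leaves, an intermediate R clade, and a
  shallow H clade with single-SNP branches (H3a at 1018, H27 at 16093)
  included specifically so spurious-haplogroup fixtures are constructible.
  Derived alleles are transitions of the reference base, mirroring real
  mtDNA mutational bias.
* **Reads**: amplicon lengths are normal with mean 167 and sd 15, clamped
  to [120, 250]; fragments tile the circular genome uniformly; reads are
  2x150 with a constant Q30 profile and independent per-base substitution
  errors at the implied rate of 0.001 (a constant-quality profile is
  sufficient because both the correction rule and the likelihood only
  require Phred consistency). Heteroplasmy is applied per fragment — both
  mates carry the minor allele — at the configured MAF. NUMT reads are
  sampled from catalogue records whose mito-derived segments carry one
  edit every 35 bases, which guarantees at least three edits in every
  read-length window: implanted NUMT reads (0-2 extra errors) are always
  strictly closer to the nuclear copy, and true mitochondrial reads never
  are, so the filter's truth conditions are exact by construction.
* **Mixtures**: per-source counts follow largest-remainder apportionment
  (exact totals, deterministic), subsets are drawn without replacement,
  and the mixture order is seeded-shuffled so no downstream step can
  exploit file order.

What the generator does **not** emulate: real base-composition and
coverage non-uniformity of amplicon panels, position-dependent quality
decay, indel sequencing errors, PCR chimeras/amplicon concatenation, and
platform-specific error profiles. Passing tests therefore demonstrate the
correctness of the algorithms under an idealised error model, not
performance on real instrument data.

## Validation studies and problem sizes

The packaged studies (also recomputed by `scripts/acceptance.R`) use
20,000 fragments per mixture — roughly 215x mitogenome coverage at
167-base amplicons, the depth regime where random reduction experiments
retain correct haplogroup calls:

* `detection_study()`: 10 two-person mixtures, minor fractions cycling
  {5, 10, 25, 50}%, full preprocessing; scores exact haplogroup recovery.
* `ratio_panel_study()`: one mixture per canonical ratio (1:1, 1:3, 3:1;
  1:1:1, 1:3:3, 3:3:1); scores exact-or-adjacent (parent/child) recovery.
* `proportion_study()`: 20 two-person mixtures, minor uniform in
  [5, 50]%; reports mean absolute proportion error. Preprocessing is
  skipped here (its inputs contain no primers or NUMTs, so the stages are
  no-ops by construction).

Numerical choices worth noting: error probabilities are capped at 0.75 so
`log(1 - eps)` stays finite for pathological quality strings; EM ties among
equal-proportion candidates are broken lexicographically by name; the
`derive_seed()` helper keeps all derived seeds below 2^31; and every
randomised generator saves and restores the caller's RNG state, so
identical configuration plus seed reproduces output byte for byte.

## Known limitations

* Heteroplasmy is not modelled in the likelihood; a minor allele behaves
  as position-level noise or a low-proportion signal, which is also what
  produces H27-style spurious calls from heteroplasmic positions.
* The number of contributors is not formally tested; selection is a
  threshold heuristic, not a model-comparison procedure.
* Full haplotype reconstruction is out of scope: the report's partial
  haplotype covers observed diagnostic SNPs only.
* The built-in placement routine assumes substitution-dominated reads; for
  indel-rich data, supply external alignments via SAM/BAM.
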