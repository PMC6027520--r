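---
title: "Estimating microbial relative abundance from core-genome alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating microbial relative abundance from core-genome alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Shotgun metagenomic reads rarely identify their source species uniquely.
Related clades share genes — core genomes (the genes common to all strains
of a clade) overlap between relatives by construction — so a sizeable
fraction of reads aligns to several references at comparable quality.
Discarding those reads wastes signal and biases abundance estimates;
assigning each to its best hit double-counts shared regions. `coremix`
instead treats the origin of every read as a latent variable and infers the
species mixture jointly.

## The generative model and its assumptions

A community over $M$ reference species (concatenated core genomes
$g_1,\dots,g_M$ with base lengths $l_1,\dots,l_M$) emits reads by a
two-stage draw: a species index from mixture weights
$\theta = (\theta_1,\dots,\theta_M)$, then a read sequence from that
species' read-composition distribution $\varphi_{\cdot,g}$. The weights get
a Dirichlet($\alpha$) prior. The model assumes reads are generated
independently, and that a species' read output is proportional to its cell
abundance times its reference length, $\theta_i \propto a_i l_i$, which is
inverted after fitting:

$$a_i = \frac{\theta_i / l_i}{\sum_s \theta_s / l_s}.$$

$\varphi$ is not given a prior; it is plugged in from the alignments as a
hit-count ratio: for distinct read sequence $r$ and reference $g$,
$\varphi_{r,g}$ is the number of read occurrences with sequence $r$ that hit
$g$ with high quality, divided by the number of occurrences that hit $g$ at
all (high quality = edit-distance rate $\le$ `max_error_rate`). Every
reference column with at least one hit therefore sums to one. A read
occurrence counts once per reference however many alignment records it has
there, and the ratio uses occurrence counts, not distinct-sequence counts.

Note the model has no outlier component: reads with no high-quality hit on
any reference cannot be explained and are excluded from inference. Their
fraction is reported in `glance()` and in the output header — a large value
means the reference set does not cover the community.

## Inference

Conjugacy lets $\theta$ be integrated out exactly, leaving a collapsed Gibbs
sampler over the hidden labels only. One sweep visits every read occurrence
in index order (a systematic scan, which keeps runs reproducible):
decrement the current label's count, redraw from

$$p(z_i = t \mid z_{\neg i}) \propto \varphi_{r_i, g_t}\,(n_{t,\neg i} + \alpha_t),$$

increment. Candidates are the references with $\varphi > 0$ for the read's
sequence; identical sequences share one $\varphi$ row, but every occurrence
carries its own label. Labels are initialised uniformly at random over each
read's candidate set — a label outside it has zero conditional mass and
would be abandoned in the first sweep anyway, so nothing is lost by never
proposing it. After `burn_in_sweeps` sweeps, the per-species counts are
recorded every `thinning` sweeps until `kept_samples` snapshots are
collected; their average $\bar n$ gives

$$\hat\theta_k = \frac{\bar n_k + \alpha_k}{\sum_i (\bar n_i + \alpha_i)}$$

and $\hat a$ by length correction. The sweep kernel is compiled (Rcpp) and
driven by R's RNG, so a fixed seed makes the whole run — including the
written TSV — byte-identical across machines.

For small instances `exact_posterior_oracle()` enumerates all assignments
and computes the posterior exactly (each assignment weighted by
$\prod_i \varphi_{r_i,z_i} \cdot \Delta(n(z)+\alpha)/\Delta(\alpha)$, with
$\Delta$ the Dirichlet normaliser). It exists to validate the sampler — the
test suite checks Gibbs mean counts against it on randomised instances —
and refuses instances beyond about $10^6$ assignments.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 1 (flat) | Dirichlet prior pseudo-counts per species; symmetric 1 adds one phantom read each, configurable per species |
| `max_error_rate` | 0.10 | high-quality hit threshold on edit distance / aligned length; MAPQ is deliberately unused because multi-hit output makes it uninformative |
| `burn_in_sweeps` | 1000 | discarded sweeps |
| `kept_samples` | 1000 | count snapshots averaged for $\bar n$ |
| `thinning` | 1 | sweeps between snapshots |
| `seed` | none | seeds initialisation and all sweeps |
| `convergence_tolerance` | off | post-hoc diagnostic: warns if the running-mean $\hat\theta$ still moves more than this over the last 100 kept sweeps; it never changes the sample count, so fits stay reproducible |

References that attract no reads keep prior-driven mass ($\alpha_k$ phantom
reads); `drop_undetected()` zeroes species below a mean-count floor and
renormalises, for reporting only.

## The simulator, and what passing tests do not show

`make_fixture()` builds the validation world: random references assembled
from 1 kb blocks, a chosen fraction of which is copied verbatim from a
common pool — emulating core genes shared between clades, the mechanism
that creates multi-mapping reads. Defaults mirror the validation protocol:
10 species, ~50 kb references, 20% shared blocks, 100 bp single-ended
reads with i.i.d. 1% substitutions, and a Zipf-like preset abundance
profile ($a_i \propto 1/i$), chosen as a realistic uneven community.
`simulate_reads()` draws the species from $\theta$, a uniform start
position, and applies substitutions (uniformly to a different base; a
position-dependent rate profile can be supplied). Indels are not simulated,
reads are forward-strand by default (`reverse_complement = TRUE` flips each
read with probability 0.5), and read length is fixed rather than averaged.

The internal matcher closes the loop without an external mapper: a
(read, reference) pair hits when some offset aligns the read with mismatch
rate at most `max_error_rate`, keeping the best offset per pair. The
default seed-and-extend route indexes all reference k-mers with
$k = \lfloor L/(e+1)\rfloor$ ($e$ = allowed mismatches), which by the q-gram
lemma guarantees every qualifying ungapped alignment shares an exact k-mer
with the reference on the same diagonal — so its results are exactly those
of the exhaustive scan (`method = "exhaustive"`, kept as the oracle in the
tests). Ties are broken deterministically: fewer mismatches, then forward
strand, then smaller offset.

What this synthetic world leaves out: real core genes are not i.i.d. random
sequence (repeats and low-complexity regions make real ambiguity patterns
lumpier), sharing in nature is clade-structured rather than drawn from one
common pool, the error model has no indels or quality structure, and there
are no reads from species missing from the reference set. Passing the
recovery tests therefore shows the estimator is correct under its own
model, not that real-data accuracy will match the simulated numbers.

## Numerical choices and degenerate inputs

- In the full conditional, the prior term uses $\alpha_t$ — the candidate
  species' own pseudo-count — also when $\alpha$ is asymmetric.
- Unambiguous data are handled exactly: a single-candidate read is never
  resampled, so with every read unambiguous the sampler output reduces
  bit-exactly to the closed form $(n+\alpha)/(N+\Sigma\alpha)$.
- Genes are concatenated with no spacer by default; a run of `N` characters
  (`spacer`) can be inserted to suppress alignments spanning gene junctions.
  Reference lengths count all bases, including `N` and spacer characters,
  since the length correction normalises by alignment-target length.
- Zero-length references, empty read sets, reads longer than a reference,
  constant profiles in the Spearman distance, and truth vectors with zeros
  in the RRMSE are all rejected with explicit errors rather than propagating
  NaN.
- Output TSVs format numbers with 15 significant digits so that seeded
  reruns are byte-identical.

## Validation problem sizes

The test suite validates the sampler against exact enumeration on 20
randomised instances ($M \in \{2,3\}$, up to 8 reads, 50,000 kept samples),
and runs the full pipeline on five replicate fixtures per read depth at
1,000 / 10,000 / 50,000 reads, checking that the replicate-mean relative
root-mean-square error decreases with depth and is below 10% at 50,000
reads. RRMSE is
$100\sqrt{\tfrac1M \sum_i ((\hat a_i - a_i)/a_i)^2}$, averaged across
replicates — the convention for replicated accuracy curves in this
literature. `scripts/acceptance.R` recomputes the same quantities from
scratch.

## Known limitations

- The plug-in $\varphi$ is a finite-sample approximation, and it attenuates
  the allocation of shared reads: for a read shared by species $A$ and $B$
  the conditional ratio is $(n_A/D_A):(n_B/D_B)$, where $D$ counts all
  reads hitting the reference, rather than the ideal $n_A:n_B$. Rare
  species that share sequence with abundant ones are therefore somewhat
  inflated. This is inherent to estimating $\varphi$ by hit ratios; it
  shrinks with read depth and with the fraction of species-specific
  sequence.
- The matcher is ungapped; indel-containing alignments must come from an
  external mapper (any SAM with NM or MD tags works).
- Inference assumes the reference set covers the community; unassigned
  reads are reported but not modelled.
- `parse_sam` measures aligned query length from the CIGAR (M/=/X/I
  operations), so heavily soft-clipped alignments are filtered on their
  aligned portion only.
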