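# coremix

Estimate the relative abundances of microbial species in a shotgun
metagenomic sample from reads aligned to **concatenated core-genome
references**, using a finite mixture model with a Dirichlet prior and
**collapsed Gibbs sampling** over the hidden origin of every read.

## Who this is for

Microbiome researchers who have (or can simulate) a set of per-species core
gene catalogs and a SAM file of read alignments against them — produced by
any mapper that reports all multi-mapping hits (e.g. `bwa mem -a`) — and who
want species-level relative abundances that handle ambiguous, multi-mapping
reads probabilistically instead of discarding them. Core genomes (the genes
shared by all strains of a clade) are small, stable under strain-level
variation, and still share genes between related clades; those shared genes
are exactly what makes a probabilistic read-assignment model necessary.

## The model

A metagenome over M reference species is a mixture: each read is generated
by first drawing its source species from mixture weights θ (Σθᵢ = 1) and
then drawing the read sequence r from that species' read-composition
distribution φ·ᵢ. The weights carry a Dirichlet(α) prior. Because a species'
read output scales with both how abundant it is and how long its reference
is, θᵢ ∝ aᵢ·lᵢ, and the relative abundance is recovered by length
correction:

    aᵢ = (θᵢ / lᵢ) / Σₛ (θₛ / lₛ)

φ is approximated from the alignments: φ_{r,g} is the fraction of
high-quality hits on reference g that come from reads with sequence r
(a hit is high quality when edit_distance / aligned_length ≤ 0.1 by
default). Integrating θ out analytically (Dirichlet–multinomial conjugacy)
leaves only the hidden origin labels zᵢ, which are sampled by systematic
Gibbs sweeps from

    p(zᵢ = t | z₋ᵢ) ∝ φ_{rᵢ,t} · (n_{t,¬i} + α_t)

Averaging the per-species counts over the kept sweeps gives posterior mean
counts n̄, mixture weights θ̂ = (n̄ + α)/Σ(n̄ + α), and abundances â by
length correction.

## Worked example

Everything below is synthetic and reproducible — the package ships a
community simulator (used for all of its own validation) and an internal
ungapped read matcher, so no external mapper is needed to try it:

```r
library(coremix)

fx <- make_fixture(n_species = 3, ref_length = 5000, n_reads = 500, seed = 42)
rt   <- build_read_table(fx$reads)
hits <- simulate_alignment(fx$reads, fx$refset)       # internal matcher
phi  <- estimate_phi(rt, filter_high_quality(hits), fx$refset)
fit  <- run_gibbs(rt, phi, config = gibbs_config(200, 200, seed = 5))
tidy(fit)
```

```
# A tibble: 3 × 5
  species_id length mean_count theta_hat abundance_hat
  <chr>       <int>      <dbl>     <dbl>         <dbl>
1 species_01   5000        265     0.529         0.529
2 species_02   5000        145     0.290         0.290
3 species_03   5000         90     0.181         0.181
```

`mean_count` is the posterior mean number of reads assigned to each
species, `theta_hat` the mixture weight, and `abundance_hat` the
length-corrected relative abundance (here lengths are equal, so the two
coincide). The preset truth was (0.545, 0.273, 0.182):

```r
evaluate_rrmse(fit$abundance_hat, fx$truth$abundance)
#> [1] 4.117445
```

i.e. a 4.1% relative root-mean-square error at only 500 reads. `glance(fit)`
summarises the run (reads, unassigned fraction, sweeps, seed) and
`autoplot(fit, truth = fx$truth$abundance)` draws the abundance bars with
the preset values overlaid. With real data, replace `simulate_alignment()`
by `parse_sam("alignments.sam", refset)` on any mapper's multi-hit SAM
output; `aggregate_abundance()` rolls species up to higher taxa, and
`sample_distance_matrix()` computes 1 − Spearman correlation distances
between samples for clustering.

A command-line interface wrapping the same functions (subcommands
`build-ref`, `simulate`, `profile`, `estimate`, `run`, `evaluate`,
`distances`) is installed at:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/coremix.R", package = "coremix"))') run \
  --reference refs.fasta --reads reads.fastq --sam aln.sam \
  --seed 1 --output abundance.tsv
```

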