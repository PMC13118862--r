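# holo2brad

Hologenome profiling and host genotyping from type IIB restriction
site-associated DNA (2bRAD) sequencing.

## The problem

Holobiont samples — a coral, scallop or shrimp together with its symbiotic
microbiota — yield DNA that is overwhelmingly host-derived (often ~99 %),
which defeats shotgun metagenomics and limits amplicon methods to coarse,
bacteria-only profiles. Type IIB restriction enzymes such as BcgI excise a
uniform-length fragment around every recognition site
(`CGANNNNNNTGC`, 10-nt flanks, 32-nt tags), so each genome — host or
microbe — is represented by an enumerable set of fixed-length *tags*. With
a database that separates host-unique tags from microbial taxa-specific
tags, one sequencing library simultaneously supports:

* **microbial community profiling** — species presence by the G score
  `G_i = sqrt(reads_i × tags_hit_i) ≥ 5`, and relative abundance
  `p_i ∝ reads_i / T_i` where `T_i` is species *i*'s theoretical
  (database) count of species-specific tags;
* **host genotyping** — codominant calls at tag loci from a binomial
  likelihood contest between the two top alleles
  (het iff `Binom(n2; n1+n2, 0.5) > Binom(n2; n1+n2, err)`), gated at
  ≥ 4× coverage;
* **downstream statistics** — Shannon/Simpson/Chao1 alpha diversity,
  Bray–Curtis dissimilarity, PERMANOVA, allele-sharing distances,
  neighbor-joining trees, PCA, and replicate-concordance metrics.

The package is written for microbiome and population-genetics researchers
working with host-contaminated, low-biomass libraries. It also ships a
MAG (metagenome-assembled genome) quality filter with the 57-MAG coral
cohort table as a fixture, and a synthetic holobiont generator with exact
truth tables used throughout the test suite.

## Worked example

Simulate a holobiont library under the default study conditions (20-species
log-normal community, 99 % host reads, 0.5 % base error), build the
database, and process the sample end to end:

```r
library(holo2brad)

cfg <- sim_config(seed = 42, total_reads = 200000L)
gs  <- simulate_genomes(cfg)
hs  <- simulate_diploid_host(cfg)

digests <- sapply(names(gs$genomes), function(g)
  digest_genome(setNames(gs$genomes[[g]], "chr1"), g), simplify = FALSE)
db <- run_build_db(digests, gs$lineages,
                   digest_genome(setNames(hs$reference, "chr1"), "host"))
db
#> <holodb> BcgI | 600 microbial tags (20 species), 200 host tags [cross-deredundant]

rd  <- simulate_reads(gs, hs, cfg)
out <- run_sample(rd$reads, db, sample_id = "rep1")
out$qc
#>   sample_id raw_reads high_quality_reads high_quality_rate tags_with_site
#> 1      rep1    200000             200000                 1         194169
#>   mapping_rate_microbial mapping_rate_host
#> 1                0.00892            0.5438

head(out$profile[order(-out$profile$relative_abundance), ], 5)
#>   species reads tags_hit g_score relative_abundance
#> 1 s_14      397       30   109.              0.230
#> 2 s_16      162       30    69.7             0.0937
#> 3 s_6       155       30    68.2             0.0896
#> 4 s_11      105       29    55.2             0.0607
#> 5 s_12      101       27    52.2             0.0584
```

Reading the output: 97 % of high-quality reads carry a BcgI site; about
0.9 % of site-bearing tags map to microbial species-specific markers (the
rest are host tags, host SNP alleles recovered later by Hamming matching,
or sequencing-error variants). All 20 planted species are detected, and
the estimated abundances track the per-read truth table closely:

```r
ta <- truth_abundance(rd$truth)
m  <- merge(ta, out$profile, by = "species")
cor(m$true_abundance, m$relative_abundance)
#> 0.999

sum(out$genotypes$status == "called")
#> 200        # all 200 host loci genotyped at this depth
```

`run_cohort()` assembles multiple processed samples into diversity tables,
a Bray–Curtis matrix with PERMANOVA, an NJ tree and a PCA;
`autoplot()` methods draw abundance bars and PCA scatter plots, and
`tidy()`/`glance()` tidy the PERMANOVA fit.

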