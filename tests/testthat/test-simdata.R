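small_cfg <- function(...) {
  sim_config(seed = 23, n_species = 4, sites_per_genome = 5,
             genome_length = 1200, host_sites = 24, n_host_snps = 12,
             host_genome_length = 2600, total_reads = 4000,
             host_fraction = 0.6, base_error_rate = 0, ...)
}

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_host_snps = 300, host_sites = 200),
               "exceeds")
  expect_error(sim_config(host_fraction = 1.2))
  expect_error(simulate_genomes(sim_config(genome_length = 100,
                                           sites_per_genome = 10)),
               "too short")
})

test_that("simulated genomes digest to exactly the planted tags", {
  gs <- simulate_genomes(small_cfg())
  for (gid in names(gs$genomes)) {
    d <- digest_genome(setNames(gs$genomes[[gid]], "chr1"), gid)
    want <- sort(gs$truth_tags$canonical_tag[gs$truth_tags$genome_id == gid])
    expect_equal(d$counts$canonical_tag, want)
    expect_true(all(d$counts$count == 1L))
  }
  expect_equal(sum(gs$abundance$true_abundance), 1, tolerance = 1e-12)
})

test_that("generation is deterministic per seed and varies across seeds", {
  cfg <- small_cfg()
  expect_identical(simulate_genomes(cfg), simulate_genomes(cfg))
  cfg2 <- small_cfg(); cfg2$seed <- 99L
  expect_false(identical(simulate_genomes(cfg)$genomes[[1]],
                         simulate_genomes(cfg2)$genomes[[1]]))
  hs <- simulate_diploid_host(cfg)
  expect_identical(hs, simulate_diploid_host(cfg))
  rd <- simulate_reads(simulate_genomes(cfg), hs, cfg)
  expect_identical(rd, simulate_reads(simulate_genomes(cfg), hs, cfg))
})

test_that("host SNPs sit inside tag windows off the fixed recognition bases", {
  cfg <- small_cfg()
  hs <- simulate_diploid_host(cfg)
  loci <- hs$loci
  expect_equal(sum(loci$class != "hom_ref"), cfg$n_host_snps)
  het <- loci[loci$class == "het", ]
  expect_true(all(het$allele1 != het$allele2))
  snp <- loci[loci$class != "hom_ref", ]
  for (i in seq_len(nrow(snp))) {
    a <- strsplit(snp$ref_allele[i], "")[[1]]
    b <- strsplit(ifelse(snp$class[i] == "het", snp$allele2[i],
                         snp$allele1[i]), "")[[1]]
    diff <- which(a != b)
    expect_length(diff, 1L)
    # fixed recognition bases occupy window positions 11-13 and 20-22; the
    # set maps onto itself under reverse complement, so the check holds in
    # either stored orientation
    expect_false(diff %in% c(11:13, 20:22))
  }
  # both haplotypes digest to full locus sets (sites survive the SNPs)
  d1 <- digest_genome(setNames(hs$hap1, "c"), "h1")
  d2 <- digest_genome(setNames(hs$hap2, "c"), "h2")
  expect_equal(d1$total, cfg$host_sites)
  expect_equal(d2$total, cfg$host_sites)
})

test_that("heterozygosity zero means identical haplotypes", {
  cfg <- small_cfg(snp_heterozygosity = 0)
  hs <- simulate_diploid_host(cfg)
  expect_identical(hs$hap1, hs$hap2)
  expect_false(any(hs$loci$class == "het"))
})

test_that("read origins follow the host fraction", {
  cfg <- small_cfg()
  cfg$host_fraction <- 1
  gs <- simulate_genomes(cfg)
  hs <- simulate_diploid_host(cfg)
  rd <- simulate_reads(gs, hs, cfg)
  expect_true(all(rd$truth$origin == "host"))

  cfg2 <- small_cfg()
  cfg2$host_fraction <- 0.99
  cfg2$total_reads <- 100000L
  rd2 <- simulate_reads(simulate_genomes(cfg2), simulate_diploid_host(cfg2),
                        cfg2)
  share <- mean(rd2$truth$origin == "host")
  se <- sqrt(0.99 * 0.01 / 1e5)
  expect_lt(abs(share - 0.99), 3 * se)
})

test_that("at zero noise the pipeline recovers the realized truth exactly", {
  cfg <- small_cfg()
  gs <- simulate_genomes(cfg)
  hs <- simulate_diploid_host(cfg)
  rd <- simulate_reads(gs, hs, cfg)
  digests <- sapply(names(gs$genomes), function(g)
    digest_genome(setNames(gs$genomes[[g]], "chr1"), g), simplify = FALSE)
  hd <- digest_genome(setNames(hs$reference, "chr1"), "host")
  db <- run_build_db(digests, gs$lineages, hd)
  out <- run_sample(rd$reads, db, sample_id = "S")
  ta <- truth_abundance(rd$truth)
  m <- dplyr::inner_join(ta, out$profile, by = "species")
  # equal theoretical tag counts per species + error-free reads:
  # estimated abundance equals the realized read share exactly
  expect_equal(nrow(m), nrow(ta))
  expect_equal(m$relative_abundance, m$true_abundance, tolerance = 1e-12)
  expect_equal(sum(out$profile$relative_abundance), 1, tolerance = 1e-9)
})

test_that("truth tables are internally consistent", {
  cfg <- small_cfg()
  rd <- simulate_reads(simulate_genomes(cfg), simulate_diploid_host(cfg), cfg)
  expect_equal(nrow(rd$truth), cfg$total_reads)
  expect_equal(nrow(rd$reads), cfg$total_reads)
  expect_true(all(nchar(rd$reads$sequence) == cfg$read_length))
  expect_true(all(nchar(rd$reads$quality) == cfg$read_length))
  expect_true(all(is.na(rd$truth$haplotype[rd$truth$origin == "microbial"])))
  expect_true(all(rd$truth$haplotype[rd$truth$origin == "host"] %in% 1:2))
})
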