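#' Configuration for the synthetic holobiont generator
#'
#' The defaults emulate the study conditions of a holobiont 2bRAD library:
#' overwhelming host contamination (99 % of reads host-derived), a planted
#' microbial community of 20 species with log-normal relative abundances, a
#' diploid host with SNPs planted strictly inside tag windows, and a per-base
#' substitution error rate of 0.5 %. All outputs are deterministic given
#' `seed`.
#'
#' @param seed Integer master seed.
#' @param n_species Number of microbial species (one genome each).
#' @param species_per_genus Lineage shape: species are nested two-per-genus,
#'   then two-per-family and so on up the seven ranks.
#' @param genome_length Microbial genome length (nt).
#' @param gc_fraction GC content of background sequence.
#' @param sites_per_genome Enzyme sites (= single-copy tags) planted per
#'   microbial genome; also each species' theoretical tag count.
#' @param host_genome_length,host_sites Host genome length and number of
#'   planted host tag loci.
#' @param n_host_snps Number of host loci carrying a planted SNP.
#' @param snp_heterozygosity Fraction of SNP loci that are heterozygous
#'   (the rest are homozygous for the alternative allele).
#' @param host_fraction Probability a read is host-derived (default 0.99).
#' @param total_reads Reads to simulate.
#' @param read_length Read length (nt); must exceed the tag length.
#' @param base_error_rate Per-base substitution error probability.
#' @param quality Quality model: `list(model = "constant", q = 38)` or
#'   `list(model = "two_tier", q_high = 38, q_low = 2, frac_low = 0.05)`.
#' @param abundance_sdlog Log-SD of the log-normal community abundances.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_species = 20L, species_per_genus = 2L,
                       genome_length = 4000L, gc_fraction = 0.42,
                       sites_per_genome = 30L,
                       host_genome_length = 16000L, host_sites = 200L,
                       n_host_snps = 100L, snp_heterozygosity = 0.5,
                       host_fraction = 0.99, total_reads = 100000L,
                       read_length = 50L, base_error_rate = 0.005,
                       quality = list(model = "constant", q = 38L),
                       abundance_sdlog = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_species >= 1, cfg$sites_per_genome >= 1,
            cfg$host_sites >= 1, cfg$total_reads >= 1,
            cfg$host_fraction >= 0, cfg$host_fraction <= 1,
            cfg$base_error_rate >= 0, cfg$base_error_rate < 1,
            cfg$snp_heterozygosity >= 0, cfg$snp_heterozygosity <= 1)
  if (cfg$n_host_snps > cfg$host_sites) {
    stop("n_host_snps exceeds the number of planted host loci", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

IUPAC_CHOICES <- list(A = "A", C = "C", G = "G", T = "T",
                      R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                      W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                      B = c("C", "G", "T"), D = c("A", "G", "T"),
                      H = c("A", "C", "T"), V = c("A", "C", "G"),
                      N = c("A", "C", "G", "T"))

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# site-free background: draw random sequence, then mutate one fixed base of
# every residual recognition match until the digest is clean
clean_background <- function(len, gc, enzyme) {
  seq <- random_dna(len, gc)
  for (iter in 1:50) {
    sites <- find_sites(seq, enzyme)
    if (nrow(sites) == 0L) return(seq)
    for (k in seq_len(nrow(sites))) {
      pos <- sites$recognition_start[k] + 1L  # mutate the first fixed base
      cur <- substr(seq, pos, pos)
      substr(seq, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
  }
  stop("could not produce a site-free background", call. = FALSE)
}

# all spacers of a genome from one site-free pool (any substring of a
# site-free sequence is itself site-free)
clean_background_pool <- function(lens, gc, enzyme) {
  pool <- clean_background(sum(lens), gc, enzyme)
  ends <- cumsum(lens)
  substring(pool, c(1L, utils::head(ends, -1) + 1L), ends)
}

# Planted tags are screened so that, guarded by the worst-case junction base
# (a "C": in an A/C filler only a C can complete the first or last pattern
# position, and no interior pattern position can fall in the filler), the tag
# window carries exactly one recognition site, at the intended offset, in
# both orientations — and no homopolymer a quality filter would reject.
tag_is_clean <- function(tag, enzyme) {
  if (grepl("(.)\\1{10}", tag, perl = TRUE)) return(FALSE)
  ok <- function(x, strand, off) {
    s <- find_sites(paste0("C", x, "C"), enzyme)
    nrow(s) == 1L && s$recognition_start == off + 1L && s$strand == strand
  }
  ok(tag, "+", enzyme$left_flank) && ok(revcomp(tag), "-", enzyme$right_flank)
}

# screen a batch of candidate tags with two concatenated scans ("CC"
# separators reproduce the guard); any unexpected site condemns every tag it
# overlaps, which can only over-reject
screen_tags <- function(tags, enzyme) {
  m <- length(tags)
  L <- enzyme$tag_length
  bad <- grepl("(.)\\1{10}", tags, perl = TRUE)
  offs <- 2L + (seq_len(m) - 1L) * (L + 2L)  # 0-based tag starts in the text
  flag <- function(seqs, strand, rec_off) {
    sites <- find_sites(paste0("CC", paste(seqs, collapse = "CC"), "CC"),
                        enzyme)
    expected <- offs + rec_off
    planted <- sites$strand == strand & sites$recognition_start %in% expected
    seen <- rep(FALSE, m)
    seen[match(sites$recognition_start[planted], expected)] <- TRUE
    b <- !seen
    extra <- sites[!planted, , drop = FALSE]
    if (nrow(extra) > 0L) {
      l_rec <- nchar(enzyme$recognition)
      for (k in seq_len(nrow(extra))) {
        s0 <- extra$recognition_start[k]
        hitk <- which(offs < s0 + l_rec & offs + L > s0)
        b[hitk] <- TRUE
      }
    }
    b
  }
  bad <- bad | flag(tags, "+", enzyme$left_flank)
  bad | flag(revcomp(tags), "-", enzyme$right_flank)
}

# generate n clean, canonically unique tags (realized recognition site with
# random flanks), batch-screened
make_tags <- function(n, enzyme, avoid = character(0), gc = 0.5) {
  rec_chars <- strsplit(enzyme$recognition, "")[[1]]
  out <- character(0)
  for (round in 1:50) {
    need <- n - length(out)
    if (need == 0L) break
    m <- need + ceiling(need / 4) + 8L
    flanks <- enzyme$left_flank + enzyme$right_flank
    rowpaste <- function(M) {
      if (ncol(M) == 0L) rep("", nrow(M)) else apply(M, 1, paste, collapse = "")
    }
    fl <- matrix(sample(c("A", "C", "G", "T"), m * flanks, replace = TRUE,
                        prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
                 nrow = m)
    rec <- matrix(vapply(rec_chars, function(ch) {
      ch <- IUPAC_CHOICES[[ch]]
      if (length(ch) == 1L) rep(ch, m) else sample(ch, m, replace = TRUE)
    }, character(m)), nrow = m)
    cand <- paste0(
      rowpaste(fl[, seq_len(enzyme$left_flank), drop = FALSE]),
      rowpaste(rec),
      rowpaste(fl[, enzyme$left_flank + seq_len(enzyme$right_flank),
                  drop = FALSE]))
    cand <- cand[!screen_tags(cand, enzyme)]
    keep <- !duplicated(canonical_tag(cand)) &
      !(canonical_tag(cand) %in% c(avoid, canonical_tag(out)))
    out <- c(out, cand[keep][seq_len(min(need, sum(keep)))])
  }
  if (length(out) < n) stop("could not generate enough clean tags",
                            call. = FALSE)
  out
}

# assemble spacer/tag/spacer/.../tag/spacer and repair any junction-borne
# extra site by redrawing; returns the sequence once its digest is exactly
# the planted tag set
assemble_genome <- function(tags, total_len, gc, enzyme, genome_id) {
  assemble_haplotypes(list(tags), total_len, gc, enzyme, genome_id)[[1]]
}

# several haplotypes share one spacer backbone (same chromosome); each must
# digest to exactly its own planted allele set
assemble_haplotypes <- function(tag_sets, total_len, gc, enzyme, genome_id) {
  n <- length(tag_sets[[1]])
  stopifnot(all(lengths(tag_sets) == n))
  min_len <- n * enzyme$tag_length + (n + 1L) * 10L
  if (total_len < min_len) {
    stop(sprintf("genome_length %d too short for %d sites (need >= %d)",
                 total_len, n, min_len), call. = FALSE)
  }
  spacer_total <- total_len - n * enzyme$tag_length
  base_len <- spacer_total %/% (n + 1L)
  lens <- rep(base_len, n + 1L)
  lens[1] <- lens[1] + spacer_total - sum(lens)
  for (try in 1:50) {
    spacers <- clean_background_pool(lens, gc, enzyme)
    seqs <- lapply(tag_sets, function(tags) {
      paste0(paste0(spacers[seq_len(n)], tags, collapse = ""),
             spacers[n + 1L])
    })
    ok <- all(vapply(seq_along(seqs), function(i) {
      dg <- digest_genome(stats::setNames(seqs[[i]], "chr1"), genome_id,
                          enzyme)
      want <- sort(unique(canonical_tag(tag_sets[[i]])))
      dg$total == n && identical(dg$counts$canonical_tag, want)
    }, logical(1)))
    if (ok) return(seqs)
  }
  stop("could not assemble a genome with exactly the planted sites",
       call. = FALSE)
}

nested_lineage <- function(n_species, species_per_genus = 2L) {
  i <- seq_len(n_species)
  lv <- list(species = i)
  up <- ceiling(i / species_per_genus)
  for (r in c("genus", "family", "order", "class", "phylum", "kingdom")) {
    lv[[r]] <- up
    up <- ceiling(up / 2)
  }
  tibble::tibble(
    genome_id = paste0("g_", i),
    kingdom = paste0("k_", lv$kingdom), phylum = paste0("p_", lv$phylum),
    class = paste0("c_", lv$class), order = paste0("o_", lv$order),
    family = paste0("f_", lv$family), genus = paste0("g_", lv$genus),
    species = paste0("s_", lv$species))
}

#' Simulate microbial genomes with planted enzyme sites
#'
#' Each genome is a single contig holding exactly `sites_per_genome`
#' non-overlapping enzyme windows with full flanks, separated by site-free
#' background; the assembly is verified by digestion, so the truth table is
#' exact. The community's true relative abundances are drawn log-normal.
#'
#' @param config A [sim_config()].
#' @param enzyme An [enzyme_spec()].
#' @return A list with `genomes` (named list genome_id -> sequence),
#'   `truth_tags` (tibble `genome_id`, `species`, `canonical_tag`),
#'   `lineages` (seven-rank tibble), `abundance` (tibble `species`,
#'   `true_abundance` summing to 1), and `enzyme`.
#' @export
simulate_genomes <- function(config, enzyme = bcgi()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    lineages <- nested_lineage(config$n_species, config$species_per_genus)
    all_tags <- make_tags(config$n_species * config$sites_per_genome,
                          enzyme, gc = config$gc_fraction)
    genomes <- list(); truth <- list()
    for (i in seq_len(config$n_species)) {
      gid <- lineages$genome_id[i]
      tags <- all_tags[(i - 1L) * config$sites_per_genome +
                         seq_len(config$sites_per_genome)]
      genomes[[gid]] <- assemble_genome(tags, config$genome_length,
                                        config$gc_fraction, enzyme, gid)
      truth[[gid]] <- tibble::tibble(genome_id = gid,
                                     species = lineages$species[i],
                                     canonical_tag = canonical_tag(tags))
    }
    ab <- stats::rlnorm(config$n_species, 0, config$abundance_sdlog)
    list(genomes = genomes,
         truth_tags = dplyr::bind_rows(truth),
         lineages = lineages,
         abundance = tibble::tibble(species = lineages$species,
                                    true_abundance = ab / sum(ab)),
         enzyme = enzyme)
  })
}

#' Simulate a diploid host with SNPs inside tag windows
#'
#' Builds a host reference genome with `host_sites` planted tag loci, then
#' places `n_host_snps` single-base substitutions strictly inside tag
#' windows and never on a fixed recognition base (so the site survives on
#' both haplotypes). A `snp_heterozygosity` fraction of SNP loci are
#' heterozygous (haplotypes differ); the rest carry the alternative allele
#' on both haplotypes. Loci without a SNP are homozygous reference.
#'
#' @inheritParams simulate_genomes
#' @return A list with `reference`, `hap1`, `hap2` (sequences), `loci`
#'   (truth tibble `locus_id` = reference canonical tag, `ref_allele`,
#'   `allele1`, `allele2` in reference orientation, `class` in
#'   hom_ref/hom_alt/het), and `enzyme`.
#' @export
simulate_diploid_host <- function(config, enzyme = bcgi()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1000L, {
    rec_chars <- strsplit(enzyme$recognition, "")[[1]]
    fixed_rec <- lengths(IUPAC_CHOICES[rec_chars]) == 1L
    mutable <- c(seq_len(enzyme$left_flank),
                 enzyme$left_flank + which(!fixed_rec),
                 enzyme$left_flank + length(rec_chars) +
                   seq_len(enzyme$right_flank))
    ref_tags <- make_tags(config$host_sites, enzyme,
                          gc = config$gc_fraction)
    seen <- canonical_tag(ref_tags)
    snp_idx <- sort(sample.int(config$host_sites, config$n_host_snps))
    n_het <- round(config$snp_heterozygosity * config$n_host_snps)
    het <- rep(FALSE, config$n_host_snps)
    if (n_het > 0L) het[sample.int(config$n_host_snps, n_het)] <- TRUE
    alt_tags <- ref_tags
    for (j in seq_along(snp_idx)) {
      k <- snp_idx[j]
      repeat {
        pos <- sample(mutable, 1)
        cur <- substr(ref_tags[k], pos, pos)
        alt <- ref_tags[k]
        substr(alt, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
        if (tag_is_clean(alt, enzyme) &&
            !(canonical_tag(alt) %in% c(seen, canonical_tag(alt_tags[-k])))) {
          alt_tags[k] <- alt
          break
        }
      }
    }
    allele1 <- ref_tags; allele2 <- ref_tags
    allele2[snp_idx] <- alt_tags[snp_idx]           # het: hap2 carries alt
    hom_alt <- snp_idx[!het]
    allele1[hom_alt] <- alt_tags[hom_alt]           # hom-alt: both carry alt
    cls <- rep("hom_ref", config$host_sites)
    cls[snp_idx[het]] <- "het"
    cls[hom_alt] <- "hom_alt"
    haps <- assemble_haplotypes(list(ref_tags, allele1, allele2),
                                config$host_genome_length,
                                config$gc_fraction, enzyme, "host")
    reference <- haps[[1]]; hap1 <- haps[[2]]; hap2 <- haps[[3]]
    # truth alleles are reported in the canonical reference orientation:
    # that is the orientation genotype calls are expressed in
    canon <- canonical_tag(ref_tags)
    flip <- canon != ref_tags
    orient <- function(x) ifelse(flip, revcomp(x), x)
    list(reference = reference, hap1 = hap1, hap2 = hap2,
         loci = tibble::tibble(
           locus_id = canon,
           ref_allele = orient(ref_tags),
           allele1 = orient(allele1), allele2 = orient(allele2),
           class = cls),
         enzyme = enzyme)
  })
}

phred_char <- function(q) {
  vapply(q, function(x) rawToChar(as.raw(33L + x)), character(1))
}

#' Simulate holobiont sequencing reads with per-read truth
#'
#' Each read carries one planted tag (a haplotype-sampled allele for host
#' loci), in random orientation, at a random offset, padded with inert
#' filler that cannot complete a recognition site; substitution errors are
#' applied at `base_error_rate` and phred+33 quality strings are attached
#' per the quality model. Read origin is host with probability
#' `host_fraction`, otherwise a species drawn by true abundance.
#'
#' @param genomes_sim Result of [simulate_genomes()].
#' @param host_sim Result of [simulate_diploid_host()].
#' @param config A [sim_config()].
#' @param seed Seed for this sequencing run; vary it to produce technical
#'   replicates of the same truth. Defaults to `config$seed + 2000`.
#' @return A list with `reads` (tibble `read_id`, `sequence`, `quality`)
#'   and `truth` (tibble `read_id`, `origin` = host/microbial, `source`
#'   = "host" or species label, `canonical_tag` of the planted tag,
#'   `haplotype` 1/2 for host reads).
#' @export
simulate_reads <- function(genomes_sim, host_sim, config,
                           seed = config$seed + 2000L) {
  stopifnot(inherits(config, "sim_config"))
  enzyme <- genomes_sim$enzyme
  L <- config$read_length
  tl <- enzyme$tag_length
  if (L < tl) stop("read_length shorter than tag length", call. = FALSE)
  with_seed(seed, {
    n <- config$total_reads
    is_host <- stats::runif(n) < config$host_fraction
    n_host <- sum(is_host)
    source <- character(n)
    tag <- character(n)
    hap <- rep(NA_integer_, n)
    if (n_host > 0L) {
      li <- sample.int(nrow(host_sim$loci), n_host, replace = TRUE)
      hp <- sample.int(2L, n_host, replace = TRUE)
      tag[is_host] <- ifelse(hp == 1L, host_sim$loci$allele1[li],
                             host_sim$loci$allele2[li])
      hap[is_host] <- hp
      source[is_host] <- "host"
    }
    if (n_host < n) {
      sp <- sample(genomes_sim$abundance$species, n - n_host, replace = TRUE,
                   prob = genomes_sim$abundance$true_abundance)
      by_sp <- split(genomes_sim$truth_tags$canonical_tag,
                     genomes_sim$truth_tags$species)
      tag[!is_host] <- vapply(sp, function(s) sample(by_sp[[s]], 1),
                              character(1))
      source[!is_host] <- sp
    }
    flip <- stats::runif(n) < 0.5
    ins <- ifelse(flip, revcomp(tag), tag)
    offset <- sample.int(L - tl + 1L, n, replace = TRUE) - 1L
    # inert filler: strict A/C alternation cannot complete a recognition site
    phase <- stats::runif(n) < 0.5
    ac <- strrep("AC", L); ca <- strrep("CA", L)
    seqs <- paste0(substr(ifelse(phase, ac, ca), 1L, offset),
                   ins,
                   substr(ifelse(phase, ca, ac), 1L, L - tl - offset))
    if (config$base_error_rate > 0) {
      big <- charToRaw(paste(seqs, collapse = ""))
      n_err <- stats::rbinom(1L, length(big), config$base_error_rate)
      if (n_err > 0L) {
        pos <- sample.int(length(big), n_err)
        bases <- charToRaw("ACGT")
        repl <- bases[sample.int(4L, n_err, replace = TRUE)]
        clash <- repl == big[pos]
        while (any(clash)) {
          repl[clash] <- bases[sample.int(4L, sum(clash), replace = TRUE)]
          clash <- repl == big[pos]
        }
        big[pos] <- repl
        seqs <- substring(rawToChar(big), (seq_len(n) - 1L) * L + 1L,
                          seq_len(n) * L)
      }
    }
    qual <- if (identical(config$quality$model, "constant")) {
      rep(strrep(phred_char(config$quality$q), L), n)
    } else {
      qhi <- charToRaw(strrep(phred_char(config$quality$q_high), n * L))
      n_low <- stats::rbinom(1L, n * L, config$quality$frac_low)
      if (n_low > 0L) {
        qhi[sample.int(n * L, n_low)] <- charToRaw(
          phred_char(config$quality$q_low))
      }
      substring(rawToChar(qhi), (seq_len(n) - 1L) * L + 1L, seq_len(n) * L)
    }
    ids <- sprintf("read_%08d", seq_len(n))
    list(reads = tibble::tibble(read_id = ids, sequence = seqs,
                                quality = qual),
         truth = tibble::tibble(
           read_id = ids,
           origin = ifelse(is_host, "host", "microbial"),
           source = source,
           canonical_tag = canonical_tag(tag),
           haplotype = hap))
  })
}

#' Realized community abundance of a simulated run
#'
#' The realized truth: microbial read counts per species from the per-read
#' truth table, normalised to sum 1.
#'
#' @param truth Truth tibble from [simulate_reads()].
#' @return Tibble `species`, `reads`, `true_abundance`.
#' @export
truth_abundance <- function(truth) {
  truth |>
    dplyr::filter(.data$origin == "microbial") |>
    dplyr::count(species = .data$source, name = "reads") |>
    dplyr::mutate(true_abundance = .data$reads / sum(.data$reads))
}
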