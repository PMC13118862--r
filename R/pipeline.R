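write_manifest <- function(out_dir, stage, counts, params = list()) {
  lines <- c(
    sprintf("tool\tholo2brad %s",
            as.character(utils::packageVersion("holo2brad"))),
    sprintf("stage\t%s", stage),
    sprintf("date\t%s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    vapply(names(params), function(k) sprintf("param.%s\t%s", k,
                                              paste(params[[k]],
                                                    collapse = ",")),
           character(1)),
    vapply(names(counts), function(k) sprintf("count.%s\t%s", k,
                                              format(counts[[k]])),
           character(1)))
  writeLines(lines, file.path(out_dir, "MANIFEST.tsv"))
}

#' Build a hologenome database from genome FASTAs
#'
#' End-to-end database construction: digest every microbial genome and the
#' host genome, keep single-copy tags, assign per-tag taxonomic specificity,
#' build the host-unique tag set, remove host/microbe shared tags (the
#' second round of redundancy removal), and optionally persist the database
#' and a statistics report.
#'
#' @param genome_fastas Named character vector of microbial genome FASTA
#'   paths (names = genome ids), or a named list of pre-digested
#'   `digest_summary` objects.
#' @param taxonomy Taxonomy tibble (as [read_taxonomy()]) or a path to the
#'   taxonomy TSV.
#' @param host_fasta Path to the host genome FASTA, or a `digest_summary`.
#' @param enzyme An [enzyme_spec()].
#' @param out_dir Optional output directory; when given, the database,
#'   statistics and a run manifest are written there.
#' @return The cross-deredundant `holodb`.
#' @export
run_build_db <- function(genome_fastas, taxonomy, host_fasta,
                         enzyme = bcgi(), out_dir = NULL) {
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)
  if (nrow(taxonomy) == 0L) stop("empty taxonomy", call. = FALSE)
  digests <- if (is.list(genome_fastas) &&
                 inherits(genome_fastas[[1]], "digest_summary")) {
    genome_fastas
  } else {
    purrr::imap(as.list(genome_fastas),
                function(p, id) digest_fasta(p, id, enzyme))
  }
  tag_sets <- purrr::map(digests, single_copy_tags)
  db <- assign_specificity(tag_sets, taxonomy, enzyme, digests = digests)
  host_digest <- if (inherits(host_fasta, "digest_summary")) host_fasta
  else digest_fasta(host_fasta, "host", enzyme)
  if (!same_enzyme(host_digest$enzyme, enzyme)) {
    stop("build-db: host digest enzyme mismatch", call. = FALSE)
  }
  host <- build_host_tagset(host_digest)
  db <- cross_deredundancy(db, host$tags)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_holodb(db, file.path(out_dir, "holodb.tsv.gz"))
    st <- db_statistics(db)
    readr::write_tsv(st$per_rank, file.path(out_dir, "db_rank_stats.tsv"))
    write_manifest(out_dir, "build-db",
                   counts = list(genomes = length(digests),
                                 microbial_tags = nrow(db$microbial),
                                 host_tags = length(db$host_tags),
                                 species = nrow(db$theoretical)),
                   params = list(enzyme = enzyme$name))
  }
  db
}

#' Process one sample: QC, tag extraction, classification, profiling,
#' genotyping
#'
#' The per-sample half of the workflow: quality-filter the reads, extract
#' one canonical tag per site-bearing read, route tags to host or microbial
#' streams, profile the microbial community, and call host genotypes.
#' The QC summary mirrors per-library sequencing statistics: raw reads,
#' high-quality reads and rate, site-bearing tags, and both mapping rates.
#'
#' @param fastq Path to a FASTQ file, or a reads tibble (`read_id`,
#'   `sequence`, `quality`).
#' @param db A `holodb` (or path to one saved with [write_holodb()]).
#' @param sample_id Sample label.
#' @param enzyme Enzyme; must match the database geometry.
#' @param g_threshold Species presence threshold (G score).
#' @param min_depth,err Genotype-calling parameters (see [call_genotypes()]).
#' @param max_mismatch Locus-assignment Hamming radius.
#' @param out_dir Optional output directory for TSV outputs and manifest.
#' @return A list with `qc` (one-row tibble of the Table-style summary),
#'   `classified` (`classified_sample`), `profile` (`abundance_profile`),
#'   `genotypes` (call tibble) and `sample_id`.
#' @export
run_sample <- function(fastq, db, sample_id = "sample", enzyme = db$enzyme,
                       g_threshold = 5.0, min_depth = 4L, err = 0.01,
                       max_mismatch = 2L, out_dir = NULL) {
  if (is.character(db)) db <- read_holodb(db)
  if (!same_enzyme(enzyme, db$enzyme)) {
    stop("sample enzyme does not match database enzyme", call. = FALSE)
  }
  reads <- if (is.character(fastq)) read_fastq(fastq) else fastq
  qcres <- quality_filter(reads)
  ext <- extract_read_tags(qcres$kept, enzyme)
  cls <- classify_observations(ext$observations, db, sample_id, enzyme)
  profile <- profile_sample(cls, db, g_threshold)
  # genotyping also sees unassigned tags: a host SNP allele differs from its
  # locus reference and is recovered by Hamming matching, not exact routing
  loci <- assign_to_loci(dplyr::bind_rows(cls$host_obs, cls$unassigned_obs),
                         db$host_tags, max_mismatch)
  genotypes <- call_genotypes(loci$pileups, min_depth, err)
  qc <- tibble::tibble(
    sample_id = sample_id,
    raw_reads = nrow(reads),
    high_quality_reads = nrow(qcres$kept),
    high_quality_rate = if (nrow(reads) > 0) nrow(qcres$kept) / nrow(reads)
    else NA_real_,
    tags_with_site = ext$n_reads_with_site,
    mapping_rate_microbial = cls$mapping_rate_microbial,
    mapping_rate_host = cls$mapping_rate_host)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(qc, file.path(out_dir, "qc_summary.tsv"))
    write_abundance(list(profile), file.path(out_dir, "abundance.tsv"))
    readr::write_tsv(genotypes, file.path(out_dir, "genotypes.tsv"))
    write_manifest(out_dir, "sample",
                   counts = list(raw = nrow(reads),
                                 kept = nrow(qcres$kept),
                                 dropped = nrow(reads) - nrow(qcres$kept),
                                 site_bearing = ext$n_reads_with_site,
                                 host = sum(cls$host_obs$count),
                                 microbial = sum(cls$microbial_obs$count),
                                 unassigned = cls$unassigned_count),
                   params = list(sample_id = sample_id,
                                 g_threshold = g_threshold,
                                 min_depth = min_depth))
  }
  list(sample_id = sample_id, qc = qc, classified = cls, profile = profile,
       genotypes = genotypes)
}

#' Cohort-level analysis across processed samples
#'
#' Assembles diversity tables, the Bray-Curtis distance matrix, PERMANOVA
#' across groups, the host genotype matrix with its allele-sharing
#' neighbor-joining tree and PCA, and pairwise replicate concordance.
#'
#' @param samples List of [run_sample()] results (at least 2).
#' @param groups Named character vector sample_id -> group label; PERMANOVA
#'   is skipped (with a note) unless at least 2 groups have 2+ members.
#' @param n_permutations,seed PERMANOVA parameters.
#' @param out_dir Optional output directory.
#' @return A list with `alpha` (tibble), `bray_curtis` (matrix),
#'   `permanova` (or NULL), `genotype_matrix`, `nj_newick` (or NULL when
#'   < 3 samples), `pca` (or NULL), `concordance` (pairwise tibble).
#' @export
run_cohort <- function(samples, groups = NULL, n_permutations = 999L,
                       seed = 1L, out_dir = NULL) {
  if (length(samples) < 2L) stop("cohort needs >= 2 samples", call. = FALSE)
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  if (!is.null(groups)) {
    unknown <- setdiff(names(groups), ids)
    if (length(unknown) > 0L) {
      stop("group file references unknown sample(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  profiles <- purrr::map(samples, "profile")
  alpha <- alpha_diversity(profiles)
  bc <- bray_curtis_matrix(abundance_table(profiles))
  pmv <- NULL
  if (!is.null(groups)) {
    g <- groups[ids]
    if (length(unique(g)) >= 2L && all(table(g) >= 2L)) {
      pmv <- permanova(bc, g, n_permutations, seed)
    }
  }
  gm <- genotype_matrix(stats::setNames(purrr::map(samples, "genotypes"),
                                        ids))
  nj <- NULL; pca <- NULL
  asd <- tryCatch(allele_sharing_distance(gm), error = function(e) NULL)
  if (!is.null(asd) && length(ids) >= 3L) nj <- neighbor_joining(asd)
  pca <- tryCatch(genotype_pca(gm), error = function(e) NULL)
  pairs <- utils::combn(seq_along(samples), 2)
  conc <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    dplyr::bind_cols(
      tibble::tibble(sample_1 = ids[i], sample_2 = ids[j]),
      replicate_concordance(profiles[[i]], profiles[[j]]),
      genotype_agreement =
        concordance(samples[[i]]$genotypes,
                    samples[[j]]$genotypes)$agreement[1])
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(alpha, file.path(out_dir, "alpha_diversity.tsv"))
    utils::write.table(bc, file.path(out_dir, "bray_curtis.tsv"),
                       sep = "\t", quote = FALSE)
    readr::write_tsv(conc, file.path(out_dir, "concordance.tsv"))
    if (!is.null(nj)) writeLines(nj, file.path(out_dir, "nj_tree.nwk"))
    if (!is.null(pca)) {
      readr::write_tsv(pca$scores, file.path(out_dir, "pca_scores.tsv"))
    }
    write_manifest(out_dir, "cohort",
                   counts = list(samples = length(samples)),
                   params = list(seed = seed,
                                 n_permutations = n_permutations))
  }
  list(alpha = alpha, bray_curtis = bc, permanova = pmv,
       genotype_matrix = gm, nj_newick = nj, pca = pca, concordance = conc)
}
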