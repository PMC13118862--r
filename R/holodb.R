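TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

#' Read a genome taxonomy table
#'
#' Expects a TSV with two columns and no header:
#' `genome_id<TAB>kingdom;phylum;class;order;family;genus;species`.
#' Labels such as `s_unresolved19` are ordinary labels: two genomes share a
#' rank only when the literal labels are equal.
#'
#' @param path Path to the taxonomy TSV.
#' @return A tibble with columns `genome_id` and the seven rank labels.
#' @export
read_taxonomy <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("genome_id", "lineage"),
                         col_types = "cc", progress = FALSE)
  parts <- stringr::str_split(raw$lineage, ";")
  bad <- which(lengths(parts) != 7L)
  if (length(bad) > 0L) {
    stop(sprintf("taxonomy line %d does not have 7 ranks", bad[1]), call. = FALSE)
  }
  mat <- do.call(rbind, parts)
  colnames(mat) <- TAX_RANKS
  dplyr::bind_cols(tibble::tibble(genome_id = raw$genome_id),
                   tibble::as_tibble(mat))
}

#' Single-copy tags of a digested genome
#'
#' Taxa-specific markers are required to exist as a single copy per genome;
#' this returns exactly the canonical tags with occurrence count 1.
#'
#' @param digest A `digest_summary` from [digest_genome()].
#' @return Character vector of single-copy canonical tags (sorted).
#' @export
single_copy_tags <- function(digest) {
  stopifnot(inherits(digest, "digest_summary"))
  sort(digest$counts$canonical_tag[digest$counts$count == 1L])
}

genome_status <- function(n_total, n_single) {
  dplyr::case_when(n_total == 0L ~ "no_site",
                   n_single == 0L ~ "no_unique_tag",
                   TRUE ~ "included")
}

#' Assign taxonomic specificity to single-copy tags
#'
#' For every canonical tag, the specificity rank is the deepest taxonomic rank
#' at which all genomes carrying the tag share the same label, scanning
#' kingdom -> species and stopping at the first disagreement (a lowest common
#' ancestor over lineage tuples). Tags whose genomes disagree already at
#' kingdom are `nonspecific`: they are excluded from the profiling map but
#' retained in the database statistics.
#'
#' @param tag_sets Named list: genome_id -> character vector of that genome's
#'   single-copy canonical tags (see [single_copy_tags()]).
#' @param lineages Tibble from [read_taxonomy()] (columns `genome_id` +
#'   seven ranks); every genome in `tag_sets` must be present.
#' @param enzyme The [enzyme_spec()] the digests were produced with.
#' @param digests Optional named list of `digest_summary` objects used to fill
#'   per-genome totals in the genome table.
#' @return An object of class `holodb` with elements `microbial` (tibble
#'   `canonical_tag`, `specificity_rank`, `taxon_label`, `n_genomes`,
#'   `genome_ids`), `nonspecific` (tibble of excluded tags), `host_tags`
#'   (empty until set), `theoretical` (species -> number of species-specific
#'   tags), `genomes`, `enzyme`, and `dereplicated = FALSE`.
#' @export
assign_specificity <- function(tag_sets, lineages, enzyme = bcgi(),
                               digests = NULL) {
  stopifnot(is.list(tag_sets), !is.null(names(tag_sets)))
  missing_lin <- setdiff(names(tag_sets), lineages$genome_id)
  if (length(missing_lin) > 0L) {
    stop("genome(s) without lineage: ", paste(missing_lin, collapse = ", "),
         call. = FALSE)
  }
  long <- tibble::tibble(
    genome_id = rep(names(tag_sets), lengths(tag_sets)),
    canonical_tag = unlist(tag_sets, use.names = FALSE)
  ) |>
    dplyr::distinct() |>
    dplyr::left_join(lineages, by = "genome_id")

  agg <- long |>
    dplyr::group_by(.data$canonical_tag) |>
    dplyr::summarise(
      n_genomes = dplyr::n(),
      genome_ids = paste(sort(.data$genome_id), collapse = ";"),
      dplyr::across(dplyr::all_of(TAX_RANKS),
                    list(nd = dplyr::n_distinct, lab = dplyr::first)),
      .groups = "drop"
    )

  nd <- as.matrix(agg[paste0(TAX_RANKS, "_nd")])
  lab <- as.matrix(agg[paste0(TAX_RANKS, "_lab")])
  ok <- rep(TRUE, nrow(agg))
  depth <- integer(nrow(agg))
  for (j in seq_along(TAX_RANKS)) {
    ok <- ok & nd[, j] == 1L
    depth <- depth + ok
  }
  spec_rank <- ifelse(depth == 0L, "nonspecific", TAX_RANKS[pmax(depth, 1L)])
  taxon <- ifelse(depth == 0L, NA_character_,
                  lab[cbind(seq_len(nrow(agg)), pmax(depth, 1L))])
  tags <- tibble::tibble(
    canonical_tag = agg$canonical_tag,
    specificity_rank = spec_rank,
    taxon_label = taxon,
    n_genomes = agg$n_genomes,
    genome_ids = agg$genome_ids
  ) |>
    dplyr::arrange(.data$canonical_tag)

  genomes <- tibble::tibble(genome_id = names(tag_sets),
                            n_single_copy_tags = unname(lengths(tag_sets))) |>
    dplyr::left_join(lineages, by = "genome_id")
  genomes$n_total_tags <- if (!is.null(digests)) {
    vapply(genomes$genome_id,
           function(g) as.integer(digests[[g]]$total), integer(1),
           USE.NAMES = FALSE)
  } else {
    NA_integer_
  }
  genomes$source <- "reference"
  genomes$status <- genome_status(
    ifelse(is.na(genomes$n_total_tags), genomes$n_single_copy_tags,
           genomes$n_total_tags),
    genomes$n_single_copy_tags
  )

  db <- structure(
    list(
      microbial = dplyr::filter(tags, .data$specificity_rank != "nonspecific"),
      nonspecific = dplyr::filter(tags, .data$specificity_rank == "nonspecific"),
      host_tags = character(0),
      theoretical = NULL,
      genomes = genomes,
      enzyme = enzyme,
      dereplicated = FALSE,
      dedup_report = NULL
    ),
    class = "holodb"
  )
  db$theoretical <- theoretical_counts(db)
  db
}

theoretical_counts <- function(db) {
  db$microbial |>
    dplyr::filter(.data$specificity_rank == "species") |>
    dplyr::count(species = .data$taxon_label, name = "n_tags") |>
    dplyr::arrange(.data$species)
}

#' @export
print.holodb <- function(x, ...) {
  cat(sprintf(
    "<holodb> %s | %d microbial tags (%d species), %d host tags%s\n",
    x$enzyme$name, nrow(x$microbial), nrow(x$theoretical),
    length(x$host_tags),
    if (x$dereplicated) " [cross-deredundant]" else ""))
  invisible(x)
}

#' Build the host-unique tag set
#'
#' Single-copy canonical tags of the host genome: distinct tags occurring
#' exactly once. These are the loci later used for codominant genotyping.
#'
#' @param host_digest A `digest_summary` of the host genome.
#' @return A list with `tags` (sorted character vector of unique host tags),
#'   `n_distinct` (all distinct canonical tags seen) and `n_unique`.
#' @export
build_host_tagset <- function(host_digest) {
  stopifnot(inherits(host_digest, "digest_summary"))
  tags <- single_copy_tags(host_digest)
  list(tags = tags,
       n_distinct = nrow(host_digest$counts),
       n_unique = length(tags))
}

#' Remove tags shared between host and microbial sides
#'
#' The second round of redundancy removal: any canonical tag present in both
#' the host tag set and the microbial map is deleted from both sides, so the
#' final database routes every tag unambiguously. Microbial genomes (and
#' species) left without any species-specific tag are marked
#' `removed_by_deredundancy` and excluded from the theoretical counts.
#'
#' @param db A `holodb` whose microbial map is built.
#' @param host_tags Character vector of host-unique canonical tags (e.g.
#'   `build_host_tagset(...)$tags`). Defaults to `db$host_tags`.
#' @return The updated `holodb`, with a `dedup_report` list recording host
#'   and microbial tags removed, genomes removed, species retained, and the
#'   per-rank retained fractions.
#' @export
cross_deredundancy <- function(db, host_tags = db$host_tags) {
  stopifnot(inherits(db, "holodb"))
  host_before <- length(host_tags)
  micro_before <- nrow(db$microbial)
  shared <- intersect(host_tags, db$microbial$canonical_tag)

  species_tags_per_genome <- function(micro) {
    micro |>
      dplyr::filter(.data$specificity_rank == "species") |>
      dplyr::mutate(genome_id = strsplit(.data$genome_ids, ";", fixed = TRUE)) |>
      tidyr::unnest("genome_id") |>
      dplyr::count(.data$genome_id, name = "n_species_tags")
  }
  before_pg <- species_tags_per_genome(db$microbial)

  rank_before <- dplyr::count(db$microbial, .data$specificity_rank)
  db$host_tags <- setdiff(host_tags, shared)
  db$microbial <- dplyr::filter(db$microbial,
                                !.data$canonical_tag %in% shared)
  rank_after <- dplyr::count(db$microbial, .data$specificity_rank)

  after_pg <- species_tags_per_genome(db$microbial)
  removed_genomes <- setdiff(before_pg$genome_id, after_pg$genome_id)
  db$genomes <- db$genomes |>
    dplyr::mutate(status = ifelse(.data$genome_id %in% removed_genomes,
                                  "removed_by_deredundancy", .data$status))
  th_before <- db$theoretical
  db$theoretical <- theoretical_counts(db)

  per_rank <- dplyr::full_join(
    dplyr::rename(rank_before, n_before = "n"),
    dplyr::rename(rank_after, n_after = "n"),
    by = "specificity_rank") |>
    tidyr::replace_na(list(n_before = 0L, n_after = 0L)) |>
    dplyr::mutate(fraction_retained = ifelse(.data$n_before > 0,
                                             .data$n_after / .data$n_before,
                                             NA_real_))
  db$dereplicated <- TRUE
  db$dedup_report <- list(
    host_tags_before = host_before,
    host_tags_removed = length(intersect(shared, host_tags)),
    host_tags_retained = length(db$host_tags),
    microbial_tags_before = micro_before,
    microbial_tags_removed = micro_before - nrow(db$microbial),
    microbial_tags_retained = nrow(db$microbial),
    genomes_removed = length(removed_genomes),
    species_before = nrow(th_before),
    species_retained = nrow(db$theoretical),
    per_rank = per_rank
  )
  db
}

#' Summary statistics of a hologenome database
#'
#' Reports the database composition the way tag-database builds are usually
#' described: mean tags per genome, tag counts at each specificity rank
#' (exact and cumulative at-or-deeper fractions over all single-copy tags,
#' nonspecific included in the denominator), genome and species retention,
#' and host tag counts before/after cross-deredundancy.
#'
#' @param db A `holodb`.
#' @return A list with `mean_tags_per_genome`, `per_rank` (tibble), `n_genomes`,
#'   `n_genomes_retained`, `n_species`, `host_tags`, `dedup_report`.
#' @export
db_statistics <- function(db) {
  stopifnot(inherits(db, "holodb"))
  n_all <- nrow(db$microbial) + nrow(db$nonspecific)
  rank_n <- vapply(TAX_RANKS, function(r) {
    sum(db$microbial$specificity_rank == r)
  }, integer(1), USE.NAMES = FALSE)
  at_or_deeper <- rev(cumsum(rev(rank_n)))
  per_rank <- tibble::tibble(
    rank = TAX_RANKS,
    n_tags = rank_n,
    fraction = if (n_all > 0) rank_n / n_all else NA_real_,
    fraction_at_or_deeper = if (n_all > 0) at_or_deeper / n_all else NA_real_
  )
  totals <- db$genomes$n_total_tags
  list(
    mean_tags_per_genome = if (all(is.na(totals))) NA_real_ else
      mean(totals, na.rm = TRUE),
    n_tags_total = n_all,
    n_nonspecific = nrow(db$nonspecific),
    per_rank = per_rank,
    n_genomes = nrow(db$genomes),
    n_genomes_retained = sum(db$genomes$status == "included"),
    n_species = nrow(db$theoretical),
    host_tags = length(db$host_tags),
    dedup_report = db$dedup_report
  )
}

DB_FORMAT_VERSION <- "holo2brad-db\tv1"

#' Save / load a hologenome database
#'
#' The database is stored as a gzip-compressed, sorted, versioned TSV with a
#' `#`-prefixed header block (enzyme geometry, build date) and sections
#' `MICROBIAL`, `HOST` and `GENOMES`, terminated by `#END`. `read_holodb()`
#' of a `write_holodb()` file reproduces the database (round-trip identity);
#' a version mismatch, truncation, or a malformed line raises a format error
#' naming the line.
#'
#' @param db A `holodb`.
#' @param path Output (input) path; written gzip-compressed.
#' @return `write_holodb()` returns `path` invisibly; `read_holodb()` returns
#'   a `holodb`.
#' @export
write_holodb <- function(db, path) {
  stopifnot(inherits(db, "holodb"))
  con <- gzfile(path, "wb")
  on.exit(close(con))
  w <- function(...) writeLines(paste(..., sep = "\t"), con)
  w(paste0("#", DB_FORMAT_VERSION))
  w("#enzyme", db$enzyme$name)
  w("#recognition", db$enzyme$recognition)
  w("#left_flank", db$enzyme$left_flank)
  w("#right_flank", db$enzyme$right_flank)
  w("#dereplicated", as.character(db$dereplicated))
  w("#built", format(Sys.Date()))
  w("#SECTION", "MICROBIAL")
  m <- dplyr::arrange(db$microbial, .data$canonical_tag)
  if (nrow(m) > 0L) {
    writeLines(paste(m$canonical_tag, m$specificity_rank, m$taxon_label,
                     m$n_genomes, m$genome_ids, sep = "\t"), con)
  }
  w("#SECTION", "HOST")
  if (length(db$host_tags) > 0L) writeLines(sort(db$host_tags), con)
  w("#SECTION", "GENOMES")
  g <- dplyr::arrange(db$genomes, .data$genome_id)
  if (nrow(g) > 0L) {
    lin <- apply(as.matrix(g[TAX_RANKS]), 1, paste, collapse = ";")
    writeLines(paste(g$genome_id, g$source, g$status,
                     g$n_total_tags, g$n_single_copy_tags, lin, sep = "\t"), con)
  }
  w("#END")
  invisible(path)
}

#' @rdname write_holodb
#' @export
read_holodb <- function(path) {
  lines <- readLines(gzfile(path))
  if (length(lines) == 0L || lines[1] != paste0("#", DB_FORMAT_VERSION)) {
    stop("not a holo2brad database (version line missing or mismatched)",
         call. = FALSE)
  }
  if (lines[length(lines)] != "#END") {
    stop("database file is truncated (missing #END)", call. = FALSE)
  }
  kv <- list()
  sec <- NULL
  micro <- list(); host <- character(0); genomes <- list()
  for (i in seq_along(lines)[-1]) {
    ln <- lines[i]
    if (ln == "#END") break
    if (startsWith(ln, "#SECTION\t")) {
      sec <- sub("^#SECTION\t", "", ln)
      next
    }
    if (startsWith(ln, "#")) {
      f <- strsplit(sub("^#", "", ln), "\t", fixed = TRUE)[[1]]
      kv[[f[1]]] <- f[2]
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (identical(sec, "MICROBIAL")) {
      if (length(f) != 5L) stop(sprintf("malformed MICROBIAL line %d", i),
                                call. = FALSE)
      micro[[length(micro) + 1L]] <- f
    } else if (identical(sec, "HOST")) {
      if (length(f) != 1L) stop(sprintf("malformed HOST line %d", i),
                                call. = FALSE)
      host <- c(host, f)
    } else if (identical(sec, "GENOMES")) {
      if (length(f) != 6L) stop(sprintf("malformed GENOMES line %d", i),
                                call. = FALSE)
      genomes[[length(genomes) + 1L]] <- f
    } else {
      stop(sprintf("data outside any section at line %d", i), call. = FALSE)
    }
  }
  mm <- if (length(micro) > 0L) do.call(rbind, micro) else
    matrix(character(0), ncol = 5)
  microbial <- tibble::tibble(
    canonical_tag = mm[, 1], specificity_rank = mm[, 2],
    taxon_label = mm[, 3], n_genomes = as.integer(mm[, 4]),
    genome_ids = mm[, 5])
  gm <- if (length(genomes) > 0L) do.call(rbind, genomes) else
    matrix(character(0), ncol = 6)
  lin <- do.call(rbind, strsplit(gm[, 6], ";", fixed = TRUE))
  gtbl <- tibble::tibble(genome_id = gm[, 1],
                         n_single_copy_tags = as.integer(gm[, 5]))
  if (length(genomes) > 0L) {
    colnames(lin) <- TAX_RANKS
    gtbl <- dplyr::bind_cols(gtbl, tibble::as_tibble(lin))
  } else {
    for (r in TAX_RANKS) gtbl[[r]] <- character(0)
  }
  gtbl$n_total_tags <- if (length(genomes) > 0L)
    suppressWarnings(as.integer(gm[, 4])) else integer(0)
  gtbl$source <- if (length(genomes) > 0L) gm[, 2] else character(0)
  gtbl$status <- if (length(genomes) > 0L) gm[, 3] else character(0)
  db <- structure(
    list(microbial = microbial,
         nonspecific = microbial[0, ],
         host_tags = host,
         theoretical = NULL,
         genomes = gtbl,
         enzyme = enzyme_spec(kv$enzyme, kv$recognition,
                              as.integer(kv$left_flank),
                              as.integer(kv$right_flank)),
         dereplicated = identical(kv$dereplicated, "TRUE"),
         dedup_report = NULL),
    class = "holodb")
  db$theoretical <- theoretical_counts(db)
  db
}
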