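#' Route tag observations to host, microbial, or unassigned
#'
#' Each canonical tag observed in a sample is routed to the host stream if it
#' is in the database's host tag set, to the microbial stream if it is in the
#' microbial map, and is otherwise unassigned (after cross-deredundancy the
#' two sides are disjoint, so routing is unambiguous). Mapping rates are
#' fractions of all site-bearing tag observations.
#'
#' @param observations Tibble `canonical_tag`, `count` (from
#'   [extract_read_tags()]).
#' @param db A `holodb`.
#' @param sample_id Sample label carried into the result.
#' @param enzyme Enzyme the observations were extracted with; checked against
#'   the database geometry.
#' @return An object of class `classified_sample`: list with `sample_id`,
#'   `host_obs` and `microbial_obs` tibbles (`canonical_tag`, `count`),
#'   `unassigned_count`, `total`, `mapping_rate_host`,
#'   `mapping_rate_microbial`.
#' @export
classify_observations <- function(observations, db, sample_id = "sample",
                                  enzyme = db$enzyme) {
  stopifnot(inherits(db, "holodb"))
  if (!same_enzyme(enzyme, db$enzyme)) {
    stop("enzyme geometry of observations does not match the database",
         call. = FALSE)
  }
  in_host <- observations$canonical_tag %in% db$host_tags
  in_micro <- observations$canonical_tag %in% db$microbial$canonical_tag
  host_obs <- observations[in_host & !in_micro, ]
  micro_obs <- observations[in_micro & !in_host, ]
  unassigned_obs <- observations[!in_host & !in_micro, ]
  total <- sum(observations$count)
  unassigned <- total - sum(host_obs$count) - sum(micro_obs$count)
  structure(
    list(sample_id = sample_id,
         host_obs = host_obs, microbial_obs = micro_obs,
         unassigned_obs = unassigned_obs,
         unassigned_count = unassigned, total = total,
         mapping_rate_host = if (total > 0) sum(host_obs$count) / total else NA_real_,
         mapping_rate_microbial = if (total > 0) sum(micro_obs$count) / total else NA_real_),
    class = "classified_sample")
}

#' @export
print.classified_sample <- function(x, ...) {
  cat(sprintf(
    "<classified_sample> %s: %d obs | host %.4f, microbial %.4f, unassigned %d\n",
    x$sample_id, x$total, x$mapping_rate_host, x$mapping_rate_microbial,
    x$unassigned_count))
  invisible(x)
}

#' Aggregate per-species evidence from microbial observations
#'
#' Sums read counts and distinct tag hits over each species' species-specific
#' tags (only species-rank tags are quantitative evidence) and computes the
#' presence statistic `G = sqrt(reads * tags_hit)`.
#'
#' @param microbial_obs Tibble `canonical_tag`, `count` of microbial-routed
#'   observations.
#' @param db A `holodb`.
#' @return Tibble `species`, `reads`, `tags_hit`, `g_score`.
#' @export
species_evidence <- function(microbial_obs, db) {
  sp_map <- dplyr::filter(db$microbial, .data$specificity_rank == "species")
  microbial_obs |>
    dplyr::inner_join(sp_map, by = "canonical_tag") |>
    dplyr::group_by(species = .data$taxon_label) |>
    dplyr::summarise(reads = sum(.data$count),
                     tags_hit = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(g_score = sqrt(.data$reads * .data$tags_hit)) |>
    dplyr::arrange(.data$species)
}

#' Call species presence from G scores
#'
#' A species is detected iff its `G = sqrt(reads * tags_hit)` reaches
#' `g_threshold`. The default of 5 requires e.g. 25 reads on one tag or 5
#' reads spread over 5 tags, suppressing spurious single-read assignments.
#'
#' @param evidence Tibble from [species_evidence()].
#' @param g_threshold Minimum G score (default 5).
#' @return The detected subset of `evidence` (same columns).
#' @export
species_presence <- function(evidence, g_threshold = 5.0) {
  dplyr::filter(evidence, .data$g_score >= g_threshold)
}

#' Estimate taxon-specific relative abundances
#'
#' For each detected species, read counts are normalised by the number of
#' species-specific tags the database holds for it (its theoretical tag
#' count): `c_i = reads_i / theoretical_i`, then `p_i = c_i / sum(c)` over
#' detected species. Read counts (not distinct tags) carry the quantitative
#' signal; distinct tags feed only the G score.
#'
#' @param evidence Tibble from [species_evidence()].
#' @param db A `holodb` providing `theoretical` counts.
#' @param g_threshold Presence threshold passed to [species_presence()].
#' @param sample_id Sample label.
#' @return An `abundance_profile`: tibble `species`, `reads`, `tags_hit`,
#'   `g_score`, `theoretical_tags`, `relative_abundance`, with attribute
#'   `sample_id`. Abundances sum to 1 over detected species.
#' @export
relative_abundance <- function(evidence, db, g_threshold = 5.0,
                               sample_id = "sample") {
  detected <- species_presence(evidence, g_threshold) |>
    dplyr::left_join(db$theoretical, by = "species")
  if (any(is.na(detected$n_tags) | detected$n_tags == 0L)) {
    stop("species with zero theoretical tags in the database: ",
         paste(detected$species[is.na(detected$n_tags) |
                                  detected$n_tags == 0L], collapse = ", "),
         call. = FALSE)
  }
  ci <- detected$reads / detected$n_tags
  out <- detected |>
    dplyr::rename(theoretical_tags = "n_tags") |>
    dplyr::mutate(relative_abundance = if (nrow(detected) > 0) ci / sum(ci)
                  else numeric(0))
  attr(out, "sample_id") <- sample_id
  class(out) <- c("abundance_profile", class(out))
  out
}

#' Profile one classified sample
#'
#' Convenience wrapper: [species_evidence()] then [relative_abundance()].
#'
#' @param classified A `classified_sample`.
#' @param db A `holodb`.
#' @param g_threshold Presence threshold.
#' @return An `abundance_profile`.
#' @export
profile_sample <- function(classified, db, g_threshold = 5.0) {
  relative_abundance(species_evidence(classified$microbial_obs, db), db,
                     g_threshold, sample_id = classified$sample_id)
}

#' Concordance between two abundance profiles
#'
#' Compares detected species sets and abundance vectors of two profiles from
#' the same database: shared species, Jaccard index, and Pearson's r over the
#' union of detected species (a species absent from one profile contributes
#' abundance 0). With an empty profile or a degenerate (zero-variance)
#' abundance vector r is undefined and reported as `NA`.
#'
#' @param profile1,profile2 `abundance_profile` objects.
#' @return A one-row tibble: `n_species_1`, `n_species_2`, `n_shared`,
#'   `jaccard`, `pearson_r`.
#' @export
replicate_concordance <- function(profile1, profile2) {
  s1 <- profile1$species; s2 <- profile2$species
  un <- union(s1, s2)
  shared <- intersect(s1, s2)
  r <- NA_real_
  if (length(s1) > 0L && length(s2) > 0L && length(un) >= 2L) {
    v1 <- profile1$relative_abundance[match(un, s1)]
    v2 <- profile2$relative_abundance[match(un, s2)]
    v1[is.na(v1)] <- 0; v2[is.na(v2)] <- 0
    if (stats::sd(v1) > 0 && stats::sd(v2) > 0) {
      r <- stats::cor(v1, v2)
    }
  }
  tibble::tibble(
    n_species_1 = length(s1), n_species_2 = length(s2),
    n_shared = length(shared),
    jaccard = if (length(un) > 0L) length(shared) / length(un) else NA_real_,
    pearson_r = r)
}

#' Write abundance and count tables across samples
#'
#' `abundance_table()` assembles profiles into a species-by-sample tibble of
#' relative abundances (and a companion read-count table for external
#' differential-abundance tools); `write_abundance()` writes it as TSV.
#'
#' @param profiles List of `abundance_profile` objects.
#' @param value `"relative_abundance"` or `"reads"`.
#' @return A tibble with a `species` column and one column per sample.
#' @export
abundance_table <- function(profiles, value = c("relative_abundance", "reads")) {
  value <- match.arg(value)
  purrr::map_dfr(profiles, function(p) {
    tibble::tibble(sample_id = attr(p, "sample_id"), species = p$species,
                   value = p[[value]])
  }) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value",
                       values_fill = 0) |>
    dplyr::arrange(.data$species)
}

#' @rdname abundance_table
#' @param path Output path.
#' @export
write_abundance <- function(profiles, path,
                            value = c("relative_abundance", "reads")) {
  readr::write_tsv(abundance_table(profiles, value), path)
  invisible(path)
}

#' Stacked-bar plot of abundance profiles
#'
#' @param object An `abundance_profile` or a list of them.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abundance_profile <- function(object, ...) {
  profiles <- if (inherits(object, "abundance_profile")) list(object) else object
  long <- purrr::map_dfr(profiles, function(p) {
    tibble::tibble(sample_id = attr(p, "sample_id"), species = p$species,
                   relative_abundance = p$relative_abundance)
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                     y = .data$relative_abundance,
                                     fill = .data$species)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Relative abundance", fill = "Species") +
    ggplot2::theme_minimal()
}
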