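#' Read a MAG quality table
#'
#' Accepts the package's canonical columns (`mag_id`, `completeness`,
#' `contamination`, `genome_size`) or CheckM-style headers (`Completeness`,
#' `Contamination`, `Genome size`); percentages, genome size in Mb.
#' The coral MAG quality table shipped at
#' `system.file("extdata", "coral_mag_qc.tsv", package = "holo2brad")`
#' is the post-filter cohort of 57 coral-derived MAGs.
#'
#' @param path Path to a TSV.
#' @return Tibble `mag_id`, `completeness`, `contamination`, `genome_size`.
#' @export
read_mag_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  names(raw) <- tolower(gsub("[ _]+", "_", names(raw)))
  alias <- c(id = "mag_id", bin_id = "mag_id", genome_size_m = "genome_size",
             "genome_size_(m)" = "genome_size")
  for (a in names(alias)) {
    if (a %in% names(raw)) names(raw)[names(raw) == a] <- alias[[a]]
  }
  need <- c("mag_id", "completeness", "contamination", "genome_size")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("MAG table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- raw[need]
  for (col in need[-1]) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    if (anyNA(v)) {
      stop(sprintf("malformed value in column '%s' at row %d", col,
                   which(is.na(v))[1]), call. = FALSE)
    }
    out[[col]] <- v
  }
  if (any(out$completeness < 0 | out$completeness > 100)) {
    stop("completeness must be in [0, 100]", call. = FALSE)
  }
  if (any(out$contamination < 0) || any(out$genome_size <= 0)) {
    stop("contamination must be >= 0 and genome_size > 0", call. = FALSE)
  }
  out
}

#' Filter MAGs on completeness, contamination and genome size
#'
#' A record is retained iff completeness is strictly above `comp_min`,
#' contamination strictly below `cont_max`, and genome size within
#' `size_range` inclusive (defaults: > 20 %, < 10 %, 1-6 Mb) — the usual
#' quality gate for database-grade metagenome-assembled genomes.
#'
#' @param records Tibble from [read_mag_table()].
#' @param comp_min Exclusive lower completeness bound (percent).
#' @param cont_max Exclusive upper contamination bound (percent).
#' @param size_range Inclusive genome size range in Mb, length 2.
#' @return A list with `retained` (tibble) and `rejected` (tibble with a
#'   `reasons` column listing every failed criterion, `;`-separated).
#' @export
filter_mags <- function(records, comp_min = 20, cont_max = 10,
                        size_range = c(1, 6)) {
  ok_comp <- records$completeness > comp_min
  ok_cont <- records$contamination < cont_max
  ok_size <- records$genome_size >= size_range[1] &
    records$genome_size <= size_range[2]
  keep <- ok_comp & ok_cont & ok_size
  reasons <- purrr::pmap_chr(
    list(ok_comp, ok_cont, ok_size),
    function(a, b, c) paste(c("completeness", "contamination",
                              "genome_size")[!c(a, b, c)], collapse = ";"))
  list(retained = records[keep, ],
       rejected = dplyr::mutate(records[!keep, ],
                                reasons = reasons[!keep]))
}

#' Summarise a MAG cohort
#'
#' Arithmetic mean and sample (n-1) standard deviation of completeness,
#' contamination and genome size; SD is `NA` for a single record. Values in
#' reports are conventionally rounded to 2 decimals.
#'
#' @param records Tibble from [read_mag_table()].
#' @return Tibble `metric`, `mean`, `sd` with one row per quality metric,
#'   plus an `n` attribute.
#' @export
summarize_mags <- function(records) {
  if (nrow(records) == 0L) stop("no MAG records", call. = FALSE)
  one <- function(col) {
    tibble::tibble(metric = col, mean = mean(records[[col]]),
                   sd = if (nrow(records) > 1L) stats::sd(records[[col]])
                   else NA_real_)
  }
  out <- dplyr::bind_rows(one("completeness"), one("contamination"),
                          one("genome_size"))
  attr(out, "n") <- nrow(records)
  out
}
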