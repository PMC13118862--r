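#' Read a FASTQ file into a tibble
#'
#' Plain or gzipped FASTQ, phred+33 qualities. Paired-end mates are treated
#' as independent reads throughout the package (the sequenced insert is a
#' single restriction tag).
#'
#' @param path Path to a FASTQ file.
#' @return A tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Write reads as FASTQ
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                    reads$quality), con)
  invisible(path)
}

# counts characters with phred < low_q by deleting everything else:
# phred+33 chars below threshold occupy ASCII 33 .. (33 + low_q - 1)
n_low_quality <- function(quality, low_q) {
  hi <- rawToChar(as.raw(33L + low_q - 1L))
  nchar(gsub(sprintf("[^!-%s]", hi), "", quality))
}

#' Quality-filter sequencing reads
#'
#' A read is dropped iff it (a) contains at least one ambiguous base call
#' (`N`), (b) contains a homopolymer run strictly longer than
#' `max_homopolymer` bases, or (c) has strictly more than `max_low_frac` of
#' its bases below phred `low_q`. Every read failing any rule is dropped;
#' the drop report attributes each dropped read to the first matching rule
#' in the order N, homopolymer, low-quality.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` (phred+33).
#' @param low_q Phred score counted as low quality (default 10: scores
#'   below 10 are "low").
#' @param max_low_frac Maximum tolerated fraction of low-quality bases
#'   (default 0.20, strict inequality).
#' @param max_homopolymer Longest tolerated homopolymer run (default 10 nt;
#'   runs of 11+ identical bases are dropped).
#' @return A list with `kept` (tibble of passing reads) and `report`
#'   (tibble `rule`, `n` with rules `N`, `homopolymer`, `low_quality` and a
#'   `kept` row).
#' @export
quality_filter <- function(reads, low_q = 10L, max_low_frac = 0.20,
                           max_homopolymer = 10L) {
  bad_len <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad_len)) {
    stop("sequence/quality length mismatch for read ",
         reads$read_id[which(bad_len)[1]], call. = FALSE)
  }
  has_n <- grepl("N", reads$sequence, fixed = TRUE)
  homopat <- sprintf("(.)\\1{%d}", max_homopolymer)
  has_homo <- grepl(homopat, reads$sequence, perl = TRUE)
  low_frac <- n_low_quality(reads$quality, low_q) / nchar(reads$quality)
  too_low <- low_frac > max_low_frac
  rule <- dplyr::case_when(has_n ~ "N",
                           has_homo ~ "homopolymer",
                           too_low ~ "low_quality",
                           TRUE ~ NA_character_)
  kept <- reads[is.na(rule), ]
  report <- tibble::tibble(
    rule = c("N", "homopolymer", "low_quality", "kept"),
    n = c(sum(rule == "N", na.rm = TRUE),
          sum(rule == "homopolymer", na.rm = TRUE),
          sum(rule == "low_quality", na.rm = TRUE),
          nrow(kept))
  )
  list(kept = kept, report = report)
}

#' Extract enzyme tags from reads
#'
#' For each read, the leftmost recognition-site match on either strand whose
#' full tag window lies inside the read yields one canonical tag observation;
#' reads without any valid window are dropped and counted. One tag per read:
#' the physical insert of a type IIB library is a single tag, so additional
#' matches are ignored.
#'
#' @param reads Tibble of quality-filtered reads (`read_id`, `sequence`).
#' @inheritParams find_sites
#' @return A list with `observations` (tibble `canonical_tag`, `count`),
#'   `per_read` (tibble `read_id`, `canonical_tag` for reads with a tag),
#'   `n_reads_with_site` and `n_reads_no_site`.
#' @export
extract_read_tags <- function(reads, enzyme = bcgi()) {
  n <- nrow(reads)
  if (n == 0L) {
    return(list(observations = tibble::tibble(canonical_tag = character(),
                                              count = integer()),
                per_read = tibble::tibble(read_id = character(),
                                          canonical_tag = character()),
                n_reads_with_site = 0L, n_reads_no_site = 0L))
  }
  seqs <- toupper(reads$sequence)
  subj <- Biostrings::DNAStringSet(seqs)
  pat <- Biostrings::DNAString(enzyme$recognition)
  l_rec <- nchar(enzyme$recognition)
  rl <- nchar(seqs)

  # earliest in-window site start (1-based) per read and strand, NA if none
  best_start <- function(p) {
    m <- Biostrings::vmatchPattern(p, subj, fixed = "subject")
    st <- Biostrings::startIndex(m)
    len <- lengths(st)                     # NULL entries count as 0
    idx <- rep.int(seq_len(n), len)
    s <- unlist(st, use.names = FALSE)
    out <- rep(NA_integer_, n)
    if (length(s) == 0L) return(out)
    ok <- s - enzyme$left_flank >= 1L &
      s + l_rec + enzyme$right_flank - 1L <= rl[idx]
    idx <- idx[ok]; s <- s[ok]
    first <- !duplicated(idx)              # starts are sorted within a read
    out[idx[first]] <- s[first]
    out
  }
  sp <- best_start(pat)
  sm <- best_start(Biostrings::reverseComplement(pat))
  use_minus <- !is.na(sm) & (is.na(sp) | sm < sp)
  start <- ifelse(use_minus, sm, sp)
  has <- !is.na(start)

  ws <- start[has] - enzyme$left_flank
  windows <- substring(seqs[has], ws, ws + enzyme$tag_length - 1L)
  oriented <- ifelse(use_minus[has], revcomp(windows), windows)
  valid <- !grepl("[^ACGT]", oriented)
  per_read <- tibble::tibble(read_id = reads$read_id[has][valid],
                             canonical_tag = canonical_tag(oriented[valid]))
  obs <- per_read |>
    dplyr::count(.data$canonical_tag, name = "count") |>
    dplyr::arrange(.data$canonical_tag)
  list(observations = obs,
       per_read = per_read,
       n_reads_with_site = nrow(per_read),
       n_reads_no_site = n - nrow(per_read))
}
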