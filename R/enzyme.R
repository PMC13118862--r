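#' Define a type IIB restriction enzyme tag geometry
#'
#' Type IIB enzymes (such as BcgI) cleave on both sides of a bipartite
#' recognition site, excising a fragment of uniform length. For tag-based
#' analyses the informative unit is the fixed-geometry window
#' `left_flank + recognition + right_flank`; [bcgi()] returns the default
#' 10 + 12 + 10 = 32 nt geometry used throughout the package.
#'
#' @param name Enzyme name (informational).
#' @param recognition Recognition site as an IUPAC nucleotide pattern
#'   (degenerate positions, typically `N`, are wildcards).
#' @param left_flank,right_flank Number of bases excised on each side of the
#'   recognition site; both must be non-negative.
#'
#' @return An object of class `enzyme_spec` with fields `name`, `recognition`,
#'   `left_flank`, `right_flank` and the derived `tag_length`.
#' @examples
#' bcgi()
#' enzyme_spec("toy", "ACGT", 2, 2)
#' @export
enzyme_spec <- function(name, recognition, left_flank, right_flank) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(recognition), length(recognition) == 1L)
  recognition <- toupper(recognition)
  iupac <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  bad <- setdiff(strsplit(recognition, "")[[1]], iupac)
  if (length(bad) > 0L) {
    stop("recognition contains non-IUPAC symbol(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  left_flank <- as.integer(left_flank)
  right_flank <- as.integer(right_flank)
  if (left_flank < 0L || right_flank < 0L) {
    stop("flank lengths must be non-negative", call. = FALSE)
  }
  tag_length <- left_flank + nchar(recognition) + right_flank
  if (tag_length <= 0L) stop("tag_length must be positive", call. = FALSE)
  structure(
    list(name = name, recognition = recognition,
         left_flank = left_flank, right_flank = right_flank,
         tag_length = tag_length),
    class = "enzyme_spec"
  )
}

#' @rdname enzyme_spec
#' @export
bcgi <- function() enzyme_spec("BcgI", "CGANNNNNNTGC", 10L, 10L)

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("<enzyme_spec> %s: %d + %s (%d nt) + %d = %d nt tag\n",
              x$name, x$left_flank, x$recognition, nchar(x$recognition),
              x$right_flank, x$tag_length))
  invisible(x)
}

same_enzyme <- function(a, b) {
  identical(a$recognition, b$recognition) &&
    identical(a$left_flank, b$left_flank) &&
    identical(a$right_flank, b$right_flank)
}

#' Reverse complement of nucleotide strings
#'
#' Vectorised over `x`; IUPAC ambiguity codes are complemented correctly.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "AAAC"))
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical (orientation-free) form of tag sequences
#'
#' The canonical form is the lexicographically smaller of a sequence and its
#' reverse complement; sequencing observes tags in unknown orientation, so all
#' databases and counts in the package are keyed on canonical sequence.
#'
#' @param x Character vector of tag sequences (A/C/G/T).
#' @return Character vector of canonical sequences.
#' @examples
#' canonical_tag("TTTT")  # "AAAA"
#' @export
canonical_tag <- function(x) {
  if (length(x) == 0L) return(character(0))
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

validate_seq <- function(seq, allow_n = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  allowed <- if (allow_n) "ACGTN" else "ACGT"
  bad <- regexpr(sprintf("[^%s]", allowed), seq)
  if (bad > 0L) {
    stop(sprintf("invalid character '%s' at position %d",
                 substr(seq, bad, bad), bad), call. = FALSE)
  }
  seq
}

#' Locate recognition sites of a type IIB enzyme on both strands
#'
#' Scans a sequence for all (possibly overlapping) matches of the enzyme's
#' IUPAC recognition pattern on the plus strand and of its reverse complement
#' (a minus-strand site). Degenerate pattern positions are wildcards; an `N`
#' in the sequence never satisfies a fixed pattern position.
#'
#' @param seq A single nucleotide string over A/C/G/T/N (case-insensitive;
#'   soft-masked lowercase is uppercased).
#' @param enzyme An [enzyme_spec()].
#' @return A tibble with columns `recognition_start` (0-based plus-strand
#'   offset of the match) and `strand` (`"+"` or `"-"`), sorted by offset.
#' @examples
#' find_sites("CGAACGTACTGC", bcgi())
#' @export
find_sites <- function(seq, enzyme = bcgi()) {
  seq <- validate_seq(seq)
  subj <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(enzyme$recognition)
  fwd <- Biostrings::start(
    Biostrings::matchPattern(pat, subj, fixed = "subject")) - 1L
  rev <- Biostrings::start(
    Biostrings::matchPattern(Biostrings::reverseComplement(pat), subj,
                             fixed = "subject")) - 1L
  pos <- c(fwd, rev)
  strand <- rep(c("+", "-"), c(length(fwd), length(rev)))
  o <- order(pos, strand)
  tibble::tibble(recognition_start = pos[o], strand = strand[o])
}

#' Excise fixed-geometry tags around recognition sites
#'
#' For every site found by [find_sites()], the tag window
#' `[recognition_start - left_flank, recognition_start + L_rec + right_flank)`
#' is excised when it lies fully inside the contig and contains no non-ACGT
#' base; minus-strand tags are reported as the reverse complement of the
#' plus-strand window, so `sequence` is always in the site's own orientation.
#' Sites whose window fails either condition are skipped and tallied.
#'
#' @param contig_id Contig identifier carried into the output.
#' @param seq Contig sequence (A/C/G/T/N, case-insensitive).
#' @inheritParams find_sites
#' @return A list with `tags`, a tibble of tag occurrences (`contig_id`,
#'   `window_start` 0-based plus-strand, `strand`, `sequence`, `canonical`),
#'   and `skips`, a tibble of per-reason skip counts
#'   (reasons `flank`, `ambiguous_base`).
#' @examples
#' ctg <- paste0(strrep("A", 10), "CGAACGTACTGC", strrep("C", 10))
#' extract_tags("c1", ctg, bcgi())$tags
#' @export
extract_tags <- function(contig_id, seq, enzyme = bcgi()) {
  seq <- validate_seq(seq)
  sites <- find_sites(seq, enzyme)
  l_rec <- nchar(enzyme$recognition)
  skip <- c(flank = 0L, ambiguous_base = 0L)
  if (nrow(sites) == 0L) {
    return(list(tags = empty_tags(), skips = skip_tbl(skip)))
  }
  ws <- sites$recognition_start - enzyme$left_flank          # 0-based
  we <- sites$recognition_start + l_rec + enzyme$right_flank # exclusive
  inside <- ws >= 0L & we <= nchar(seq)
  skip[["flank"]] <- sum(!inside)
  sites <- sites[inside, ]
  ws <- ws[inside]
  if (nrow(sites) == 0L) {
    return(list(tags = empty_tags(), skips = skip_tbl(skip)))
  }
  windows <- substring(seq, ws + 1L, ws + enzyme$tag_length)
  clean <- !grepl("[^ACGT]", windows)
  skip[["ambiguous_base"]] <- sum(!clean)
  sites <- sites[clean, ]
  ws <- ws[clean]
  windows <- windows[clean]
  oriented <- ifelse(sites$strand == "+", windows, revcomp(windows))
  tags <- tibble::tibble(
    contig_id = rep(contig_id, length(windows)),
    window_start = ws,
    strand = sites$strand,
    sequence = oriented,
    canonical = canonical_tag(oriented)
  )
  list(tags = tags, skips = skip_tbl(skip))
}

empty_tags <- function() {
  tibble::tibble(contig_id = character(), window_start = integer(),
                 strand = character(), sequence = character(),
                 canonical = character())
}

skip_tbl <- function(skip) {
  tibble::tibble(reason = names(skip), n = as.integer(skip))
}

#' In silico digestion of a whole genome
#'
#' Digests every contig with [extract_tags()] and aggregates occurrences by
#' canonical tag sequence. A genome yielding zero valid tags is flagged
#' `no_site`, mirroring the exclusion of reference genomes that lack
#' recognition sites.
#'
#' @param records Contig sequences: a named character vector
#'   (names = contig ids) or a data frame with columns `contig_id`, `seq`.
#' @param genome_id Genome identifier.
#' @inheritParams find_sites
#' @return An object of class `digest_summary`: a list with `genome_id`,
#'   `counts` (tibble `canonical_tag`, `count`), `total` valid tag
#'   occurrences, `no_site` flag, `skips` tibble and the `enzyme` used.
#' @export
digest_genome <- function(records, genome_id, enzyme = bcgi()) {
  if (is.data.frame(records)) {
    records <- stats::setNames(records$seq, records$contig_id)
  }
  if (length(records) == 0L) stop("no contigs supplied", call. = FALSE)
  if (is.null(names(records)) || anyNA(names(records))) {
    names(records) <- paste0("contig_", seq_along(records))
  }
  per <- purrr::imap(records, function(s, id) extract_tags(id, s, enzyme))
  occ <- purrr::map(per, "tags") |> dplyr::bind_rows()
  skips <- purrr::map(per, "skips") |>
    dplyr::bind_rows() |>
    dplyr::count(.data$reason, wt = .data$n, name = "n")
  counts <- occ |>
    dplyr::count(canonical_tag = .data$canonical, name = "count") |>
    dplyr::arrange(.data$canonical_tag)
  structure(
    list(genome_id = genome_id, counts = counts,
         total = nrow(occ), no_site = nrow(occ) == 0L,
         skips = skips, enzyme = enzyme),
    class = "digest_summary"
  )
}

#' @export
print.digest_summary <- function(x, ...) {
  cat(sprintf("<digest_summary> %s: %d tag occurrences, %d distinct canonical tags%s\n",
              x$genome_id, x$total, nrow(x$counts),
              if (x$no_site) " [no-site]" else ""))
  invisible(x)
}

#' Digest a genome FASTA file
#'
#' Reads a (possibly gzipped) FASTA and runs [digest_genome()].
#'
#' @param path Path to a FASTA file.
#' @param genome_id Genome identifier; defaults to the file name without
#'   extensions.
#' @inheritParams find_sites
#' @return A `digest_summary`; see [digest_genome()].
#' @export
digest_fasta <- function(path, genome_id = NULL, enzyme = bcgi()) {
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  }
  dna <- Biostrings::readDNAStringSet(path)
  recs <- stats::setNames(as.character(dna),
                          sub("\\s.*$", "", names(dna)))
  digest_genome(recs, genome_id, enzyme)
}

#' Write a digest summary as TSV
#'
#' Columns `canonical_tag`, `count`, `genome_id`; deterministic row order.
#'
#' @param digest A `digest_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_digest <- function(digest, path) {
  out <- dplyr::mutate(digest$counts, genome_id = digest$genome_id)
  readr::write_tsv(out, path)
  invisible(path)
}
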