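# Independent oracles, deliberately naive and separate from the package code.

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# complement an IUPAC pattern by hand (reverse + per-code complement)
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D")
  vapply(x, function(s) {
    ch <- rev(strsplit(toupper(s), "")[[1]])
    paste(comp[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_canonical <- function(x) {
  rc <- oracle_revcomp(x)
  ifelse(x <= rc, x, rc)
}

# subject char matches a pattern code iff its base set is a subset of the
# code's (so a subject N satisfies only a pattern N)
subject_chars_for <- function(code) {
  set <- IUPAC_SETS[[code]]
  ok <- vapply(names(IUPAC_SETS), function(s) all(IUPAC_SETS[[s]] %in% set),
               logical(1))
  names(IUPAC_SETS)[ok]
}

# naive both-strand sliding-window scan
oracle_find_sites <- function(seq, enzyme) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  scan <- function(pattern) {
    pc <- strsplit(pattern, "")[[1]]
    lp <- length(pc)
    npos <- length(chars) - lp + 1L
    if (npos < 1L) return(integer(0))
    ok <- rep(TRUE, npos)
    for (j in seq_len(lp)) {
      ok <- ok & chars[seq_len(npos) + j - 1L] %in% subject_chars_for(pc[j])
    }
    which(ok) - 1L
  }
  fwd <- scan(enzyme$recognition)
  rev <- scan(oracle_revcomp(enzyme$recognition))
  df <- rbind(data.frame(recognition_start = fwd,
                         strand = rep("+", length(fwd))),
              data.frame(recognition_start = rev,
                         strand = rep("-", length(rev))))
  df[order(df$recognition_start, df$strand), , drop = FALSE]
}

# naive tag excision following the window rules
oracle_tag_multiset <- function(seq, enzyme) {
  seq <- toupper(seq)
  sites <- oracle_find_sites(seq, enzyme)
  out <- character(0)
  for (k in seq_len(nrow(sites))) {
    ws <- sites$recognition_start[k] - enzyme$left_flank
    we <- ws + enzyme$tag_length
    if (ws < 0 || we > nchar(seq)) next
    w <- substr(seq, ws + 1, we)
    if (grepl("[^ACGT]", w)) next
    if (sites$strand[k] == "-") w <- oracle_revcomp(w)
    out <- c(out, oracle_canonical(w))
  }
  out
}

# exhaustive per-tag lowest common ancestor over lineage tuples
oracle_lca <- function(lineages_of_tag) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  deepest <- "nonspecific"
  label <- NA_character_
  for (r in ranks) {
    labs <- unique(lineages_of_tag[[r]])
    if (length(labs) == 1L) {
      deepest <- r
      label <- labs
    } else {
      break
    }
  }
  list(rank = deepest, label = label)
}

# path-length matrix of a Newick string (via the reference phylo tooling)
nwk_dist <- function(nwk) {
  testthat::skip_if_not_installed("ape")
  tr <- ape::read.tree(text = nwk)
  m <- ape::cophenetic.phylo(tr)
  m[order(rownames(m)), order(colnames(m))]
}

random_seq <- function(len, with_n = 0) {
  alpha <- c("A", "C", "G", "T")
  s <- sample(alpha, len, replace = TRUE)
  if (with_n > 0) {
    s[sample.int(len, max(1, round(with_n * len)))] <- "N"
  }
  paste(s, collapse = "")
}

# digest summaries straight from a named count vector (unit-test shortcut)
fake_digest <- function(counts, genome_id = "g", enzyme = bcgi()) {
  structure(list(
    genome_id = genome_id,
    counts = tibble::tibble(
      canonical_tag = if (length(counts)) names(counts) else character(0),
      count = as.integer(counts)) |>
      dplyr::arrange(.data$canonical_tag),
    total = as.integer(sum(counts)), no_site = length(counts) == 0L,
    skips = tibble::tibble(reason = character(), n = integer()),
    enzyme = enzyme), class = "digest_summary")
}

toy_lineages <- function(df) {
  # df: tibble(genome_id, k, p, c, o, f, g, s) in shorthand columns
  names(df) <- c("genome_id", "kingdom", "phylum", "class", "order",
                 "family", "genus", "species")
  tibble::as_tibble(df)
}
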