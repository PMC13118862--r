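#' Assign host tag observations to reference loci
#'
#' Each host-routed canonical tag is matched against the host reference tag
#' set (one locus per reference tag) by Hamming distance, considering both
#' orientations. Exact matches always win; otherwise the closest locus within
#' `max_mismatch` is taken, and an observation equidistant from two or more
#' loci is discarded as ambiguous (counted). Allele sequences are stored in
#' the reference orientation so SNP alleles at a locus align letter by
#' letter.
#'
#' @param host_obs Tibble `canonical_tag`, `count` of host-routed
#'   observations.
#' @param reference_tags Character vector of host-unique canonical tags
#'   (the locus universe); all the same length as the observations.
#' @param max_mismatch Maximum Hamming distance for assignment (default 2).
#' @return A list with `pileups` (tibble `locus_id`, `allele`, `count`),
#'   `n_ambiguous` and `n_unassigned` observation counts (in reads).
#' @export
assign_to_loci <- function(host_obs, reference_tags, max_mismatch = 2L) {
  lens <- unique(c(nchar(host_obs$canonical_tag), nchar(reference_tags)))
  if (length(lens) > 1L) {
    stop("internal error: tag/reference length mismatch", call. = FALSE)
  }
  refs <- sort(unique(reference_tags))
  obs <- host_obs
  exact <- match(obs$canonical_tag, refs)
  hit <- !is.na(exact)
  pile <- tibble::tibble(locus_id = refs[exact[hit]],
                         allele = obs$canonical_tag[hit],
                         count = obs$count[hit])
  rest <- obs[!hit, ]
  n_ambiguous <- 0L; n_unassigned <- 0L
  if (nrow(rest) > 0L && length(refs) > 0L) {
    L <- lens
    enc <- function(x) {
      matrix(utf8ToInt(paste(x, collapse = "")), nrow = length(x),
             ncol = L, byrow = TRUE)
    }
    R <- enc(refs)
    hamming <- function(tags) {
      O <- enc(tags)
      D <- matrix(0L, nrow(O), nrow(R))
      for (j in seq_len(L)) {
        D <- D + outer(O[, j], R[, j], "!=")
      }
      D
    }
    d_fwd <- hamming(rest$canonical_tag)
    d_rev <- hamming(revcomp(rest$canonical_tag))
    D <- pmin(d_fwd, d_rev)
    best <- apply(D, 1, min)
    n_min <- rowSums(D == best)
    assignable <- best <= max_mismatch & n_min == 1L
    ambiguous <- best <= max_mismatch & n_min > 1L
    n_ambiguous <- sum(rest$count[ambiguous])
    n_unassigned <- sum(rest$count[best > max_mismatch])
    if (any(assignable)) {
      loc <- max.col(-D[assignable, , drop = FALSE], ties.method = "first")
      use_rev <- d_rev[cbind(which(assignable), loc)] <
        d_fwd[cbind(which(assignable), loc)]
      allele <- ifelse(use_rev, revcomp(rest$canonical_tag[assignable]),
                       rest$canonical_tag[assignable])
      pile <- dplyr::bind_rows(pile, tibble::tibble(
        locus_id = refs[loc], allele = allele,
        count = rest$count[assignable]))
    }
  } else {
    n_unassigned <- sum(rest$count)
  }
  pileups <- pile |>
    dplyr::count(.data$locus_id, .data$allele, wt = .data$count,
                 name = "count") |>
    dplyr::arrange(.data$locus_id, .data$allele)
  list(pileups = pileups, n_ambiguous = n_ambiguous,
       n_unassigned = n_unassigned)
}

#' Codominant genotype calls from locus pileups
#'
#' At each locus the two most frequent alleles (counts `n1 >= n2`, ties
#' broken lexicographically for determinism) contest a binomial likelihood:
#' the locus is heterozygous if `dbinom(n2, n1+n2, 0.5) >
#' dbinom(n2, n1+n2, err)` and homozygous for the major allele otherwise
#' (ties go to homozygote). Loci with total depth below `min_depth` are
#' `undetermined` — the >= 4x coverage gate for high-confidence genotypes.
#' Alleles beyond the top two contribute to depth but not to the contest.
#'
#' @param pileups Tibble `locus_id`, `allele`, `count`.
#' @param min_depth Minimum total depth to call (default 4).
#' @param err Sequencing error rate of the homozygote model (default 0.01).
#' @return Tibble `locus_id`, `status` (`called`/`undetermined`), `allele1`,
#'   `allele2` (lexicographically ordered, NA when undetermined), `depth`.
#' @export
call_genotypes <- function(pileups, min_depth = 4L, err = 0.01) {
  if (nrow(pileups) == 0L) {
    return(tibble::tibble(locus_id = character(), status = character(),
                          allele1 = character(), allele2 = character(),
                          depth = integer()))
  }
  top2 <- pileups |>
    dplyr::arrange(.data$locus_id, dplyr::desc(.data$count), .data$allele) |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      depth = sum(.data$count),
      a1 = .data$allele[1],
      n1 = .data$count[1],
      a2 = dplyr::nth(.data$allele, 2, default = NA_character_),
      n2 = dplyr::nth(.data$count, 2, default = 0L),
      .groups = "drop")
  m <- top2$n1 + top2$n2
  het <- stats::dbinom(top2$n2, m, 0.5) > stats::dbinom(top2$n2, m, err)
  undet <- top2$depth < min_depth
  allele1 <- ifelse(het, pmin(top2$a1, top2$a2), top2$a1)
  allele2 <- ifelse(het, pmax(top2$a1, top2$a2), top2$a1)
  tibble::tibble(
    locus_id = top2$locus_id,
    status = ifelse(undet, "undetermined", "called"),
    allele1 = ifelse(undet, NA_character_, allele1),
    allele2 = ifelse(undet, NA_character_, allele2),
    depth = top2$depth)
}

#' @rdname call_genotypes
#' @param pileup Tibble `allele`, `count` for a single locus (a `locus_id`
#'   column is optional).
#' @export
call_genotype <- function(pileup, min_depth = 4L, err = 0.01) {
  if (nrow(pileup) == 0L) stop("empty pileup", call. = FALSE)
  if (!"locus_id" %in% names(pileup)) pileup$locus_id <- "locus"
  call_genotypes(pileup, min_depth, err)
}

genotype_class <- function(calls) {
  ifelse(calls$status != "called", NA_character_,
         ifelse(calls$allele1 == calls$allele2, "homozygote", "heterozygote"))
}

#' Genotype concordance between two call sets
#'
#' Compares only loci called in both sets; a pair agrees when the unordered
#' allele pairs are identical. Agreement is reported overall and stratified
#' by the genotype class (homozygote/heterozygote) of the first call set.
#' Strata with zero jointly called loci get `NA` agreement.
#'
#' @param calls1,calls2 Call tibbles from [call_genotypes()] over the same
#'   locus universe.
#' @return Tibble `stratum` (`all`, `homozygote`, `heterozygote`),
#'   `genotyped`, `same`, `different`, `agreement`.
#' @export
concordance <- function(calls1, calls2) {
  j <- dplyr::inner_join(
    dplyr::filter(calls1, .data$status == "called"),
    dplyr::filter(calls2, .data$status == "called"),
    by = "locus_id", suffix = c("_1", "_2"))
  same <- j$allele1_1 == j$allele1_2 & j$allele2_1 == j$allele2_2
  cls <- ifelse(j$allele1_1 == j$allele2_1, "homozygote", "heterozygote")
  one <- function(keep, label) {
    n <- sum(keep); s <- sum(same[keep])
    tibble::tibble(stratum = label, genotyped = n, same = s,
                   different = n - s,
                   agreement = if (n > 0) s / n else NA_real_)
  }
  dplyr::bind_rows(one(rep(TRUE, nrow(j)), "all"),
                   one(cls == "homozygote", "homozygote"),
                   one(cls == "heterozygote", "heterozygote"))
}

#' Combine per-sample genotype calls into a matrix
#'
#' @param calls_by_sample Named list of call tibbles (one per sample, from
#'   [call_genotypes()]).
#' @return An object of class `genotype_matrix`: list with `calls` (long
#'   tibble with `sample_id`), `samples`, `loci` (union of loci).
#' @export
genotype_matrix <- function(calls_by_sample) {
  stopifnot(is.list(calls_by_sample), !is.null(names(calls_by_sample)))
  calls <- purrr::imap_dfr(calls_by_sample, function(cl, s) {
    dplyr::mutate(cl, sample_id = s)
  })
  structure(list(calls = calls,
                 samples = names(calls_by_sample),
                 loci = sort(unique(calls$locus_id))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d loci (%d called genotypes)\n",
              length(x$samples), length(x$loci),
              sum(x$calls$status == "called")))
  invisible(x)
}

# samples x loci dosage matrix: copies of the non-major allele (0/1/2),
# NA where undetermined/uncalled. Major allele = most frequent allele copy
# over called genotypes at the locus, ties to the lexicographically smaller.
dosage_matrix <- function(gm) {
  called <- dplyr::filter(gm$calls, .data$status == "called")
  major <- called |>
    tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele") |>
    dplyr::count(.data$locus_id, .data$allele) |>
    dplyr::arrange(.data$locus_id, dplyr::desc(.data$n), .data$allele) |>
    dplyr::distinct(.data$locus_id, .keep_all = TRUE) |>
    dplyr::select("locus_id", major = "allele")
  d <- called |>
    dplyr::left_join(major, by = "locus_id") |>
    dplyr::mutate(dosage = (.data$allele1 != .data$major) +
                    (.data$allele2 != .data$major))
  M <- matrix(NA_real_, length(gm$samples), length(gm$loci),
              dimnames = list(gm$samples, gm$loci))
  M[cbind(match(d$sample_id, gm$samples), match(d$locus_id, gm$loci))] <-
    d$dosage
  M
}

#' Allele-sharing distance between samples
#'
#' `d(s, t) = 1 - mean over loci called in both of (shared allele copies / 2)`
#' where shared copies is the multiset intersection of the two allele pairs
#' (0, 1 or 2) — an identity-by-state distance. A sample pair with no jointly
#' called locus has no defined distance and raises an error.
#'
#' @param gm A `genotype_matrix`.
#' @return A symmetric base-R matrix with zero diagonal.
#' @export
allele_sharing_distance <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ns <- length(gm$samples)
  if (ns < 2L) stop("need at least 2 samples", call. = FALSE)
  called <- dplyr::filter(gm$calls, .data$status == "called")
  A1 <- A2 <- matrix(NA_character_, ns, length(gm$loci),
                     dimnames = list(gm$samples, gm$loci))
  idx <- cbind(match(called$sample_id, gm$samples),
               match(called$locus_id, gm$loci))
  A1[idx] <- called$allele1
  A2[idx] <- called$allele2
  D <- matrix(0, ns, ns, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      both <- !is.na(A1[i, ]) & !is.na(A1[j, ])
      if (!any(both)) {
        stop(sprintf("samples %s and %s share no called locus",
                     gm$samples[i], gm$samples[j]), call. = FALSE)
      }
      # alleles within a call are lexicographically ordered, so the multiset
      # intersection size has a closed form
      a1 <- A1[i, both]; a2 <- A2[i, both]
      b1 <- A1[j, both]; b2 <- A2[j, both]
      # multiset intersection of two allele pairs = best of the two pairings
      shared <- pmax((a1 == b1) + (a2 == b2), (a1 == b2) + (a2 == b1))
      D[i, j] <- D[j, i] <- 1 - mean(shared / 2)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: repeatedly joins the pair minimising the Q
#' criterion, with the standard branch-length and distance-update formulas.
#' Negative branch lengths are clamped to zero; ties in Q are broken toward
#' the smallest index pair so the output is deterministic. The tree is
#' returned unrooted in Newick format (trifurcating root).
#'
#' @param d Symmetric distance matrix with zero diagonal and no negative
#'   entries, `n >= 3`.
#' @param labels Taxon labels; default from `rownames(d)`.
#' @return A Newick string (with trailing `;`).
#' @export
neighbor_joining <- function(d, labels = rownames(d)) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (any(d < 0)) stop("distance matrix has negative entries", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12 || any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nodes <- as.list(labels)
  fmt <- function(x) format(max(x, 0), digits = 10, scientific = FALSE,
                            trim = TRUE)
  while (n > 3L) {
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    # smallest (i, j), i < j, among minimisers (within numerical tolerance)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    new_node <- sprintf("(%s:%s,%s:%s)", nodes[[i]], fmt(li),
                        nodes[[j]], fmt(lj))
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nodes <- c(nodes[keep], new_node)
    d <- d2
    n <- n - 1L
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  sprintf("(%s:%s,%s:%s,%s:%s);", nodes[[1]], fmt(la),
          nodes[[2]], fmt(lb), nodes[[3]], fmt(lc))
}

#' Principal component analysis of a genotype matrix
#'
#' Genotypes are coded as 0/1/2 copies of the non-major allele; loci that are
#' monomorphic or entirely undetermined are dropped, and missing calls are
#' imputed to the locus mean (or incomplete loci dropped with
#' `impute = "drop"`). Coordinates come from the eigendecomposition of the
#' sample covariance of the mean-centred coding; each component's sign is
#' fixed so its largest-magnitude loading is positive.
#'
#' @param gm A `genotype_matrix`.
#' @param impute `"mean"` (default) or `"drop"`.
#' @return Object of class `genotype_pca`: list with `scores` (tibble
#'   `sample_id`, `PC1`, ...) and `explained` (variance fractions,
#'   non-increasing, summing to at most 1).
#' @export
genotype_pca <- function(gm, impute = c("mean", "drop")) {
  impute <- match.arg(impute)
  M <- dosage_matrix(gm)
  if (impute == "drop") {
    M <- M[, colSums(is.na(M)) == 0L, drop = FALSE]
  } else {
    mu <- colMeans(M, na.rm = TRUE)
    nai <- which(is.na(M), arr.ind = TRUE)
    if (nrow(nai) > 0L) M[nai] <- mu[nai[, 2]]
  }
  keep <- apply(M, 2, function(x) !anyNA(x) && stats::var(x) > 0)
  M <- M[, keep, drop = FALSE]
  if (ncol(M) < 2L) stop("fewer than 2 informative loci", call. = FALSE)
  p <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, "*")
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(sample_id = rownames(M)),
                              tibble::as_tibble(scores)),
    explained = p$sdev^2 / sum(p$sdev^2),
    n_loci = ncol(M)),
    class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("<genotype_pca> %d samples, %d loci; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), x$n_loci, 100 * x$explained[1],
              100 * ifelse(length(x$explained) > 1, x$explained[2], 0)))
  invisible(x)
}

#' @rdname genotype_pca
#' @param object A `genotype_pca`.
#' @param ... Unused.
#' @export
autoplot.genotype_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               label = .data$sample_id)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])) +
    ggplot2::theme_minimal()
}

#' Write genotype calls as TSV or minimal VCF
#'
#' The VCF is tag-space: one record per polymorphic locus with the locus
#' major allele as REF and observed alternatives as ALT (full tag strings),
#' and GT/DP per sample.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  readr::write_tsv(
    dplyr::select(gm$calls, "locus_id", "sample_id", "allele1", "allele2",
                  "depth", "status"), path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
write_vcf <- function(gm, path) {
  called <- dplyr::filter(gm$calls, .data$status == "called")
  alleles_by_locus <- called |>
    tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele") |>
    dplyr::count(.data$locus_id, .data$allele) |>
    dplyr::arrange(.data$locus_id, dplyr::desc(.data$n), .data$allele)
  poly <- alleles_by_locus |>
    dplyr::count(.data$locus_id) |>
    dplyr::filter(.data$n > 1L) |>
    dplyr::pull("locus_id")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=holo2brad",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples), collapse = "\t")), con)
  for (loc in poly) {
    al <- alleles_by_locus$allele[alleles_by_locus$locus_id == loc]
    ref <- al[1]; alt <- al[-1]
    gt <- vapply(gm$samples, function(s) {
      row <- called[called$locus_id == loc & called$sample_id == s, ]
      if (nrow(row) == 0L) return("./.")
      idx <- function(a) match(a, al) - 1L
      sprintf("%d/%d:%d", idx(row$allele1), idx(row$allele2), row$depth)
    }, character(1))
    writeLines(paste(c(loc, "1", ".", ref, paste(alt, collapse = ","), ".",
                       "PASS", ".", "GT:DP", gt), collapse = "\t"), con)
  }
  invisible(path)
}
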