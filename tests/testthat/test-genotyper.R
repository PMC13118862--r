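# fixed-length toy "tags": 8-nt loci keep Hamming arithmetic easy to read
refA <- "AAAACCCC"
refB <- "GTGTGTGT"

test_that("observations join loci by Hamming distance with exact priority", {
  res <- assign_to_loci(
    tibble::tibble(canonical_tag = c("AAAACCCC", "AAAACCCA", "ACGTACGT"),
                   count = c(5L, 3L, 2L)),
    c(refA, refB))
  p <- res$pileups
  expect_equal(sum(p$count[p$locus_id == refA]), 8L)   # exact + 1-mismatch
  expect_equal(res$n_unassigned, 2L)                   # >2 mismatches from both
  # the observed orientation is reported relative to the reference
  expect_true(all(p$locus_id == refA))
})

test_that("equidistant observations are discarded as ambiguous", {
  r1 <- "AAAAAAAA"; r2 <- "AAAACCCC"
  # two mismatches from each reference
  amb <- "AAAAAACC"
  res <- assign_to_loci(tibble::tibble(canonical_tag = amb, count = 4L),
                        c(r1, r2))
  expect_equal(nrow(res$pileups), 0L)
  expect_equal(res$n_ambiguous, 4L)
  expect_error(assign_to_loci(tibble::tibble(canonical_tag = "AAAA",
                                             count = 1L), c(r1, r2)),
               "length")
})

test_that("codominant calls follow the binomial contest and depth gate", {
  pile <- function(...) {
    x <- c(...)
    tibble::tibble(locus_id = "L", allele = names(x), count = as.integer(x))
  }
  hom <- call_genotype(pile(A = 10))
  expect_equal(hom$status, "called")
  expect_equal(hom$allele1, "A")
  expect_equal(hom$allele2, "A")
  expect_equal(hom$depth, 10L)

  het <- call_genotype(pile(B = 5, A = 5))
  expect_equal(het$allele1, "A")      # lexicographic pair order
  expect_equal(het$allele2, "B")

  low <- call_genotype(pile(A = 2, B = 1))
  expect_equal(low$status, "undetermined")
  expect_true(is.na(low$allele1))

  # minor alleles beyond the top two count toward depth only
  multi <- call_genotype(pile(A = 2, B = 1, C = 1))
  expect_equal(multi$status, "called")
  expect_equal(multi$depth, 4L)
  expect_error(call_genotype(pile()), "empty")
})

test_that("the het/hom decision boundary matches likelihood enumeration", {
  err <- 0.01
  n1 <- 20L
  for (n2 in 0:n1) {
    got <- call_genotype(tibble::tibble(locus_id = "L",
                                        allele = c("A", "B"),
                                        count = c(n1, n2)), err = err)
    m <- n1 + n2
    want_het <- dbinom(n2, m, 0.5) > dbinom(n2, m, err)
    expect_equal(got$allele1 != got$allele2, want_het,
                 info = paste("n2 =", n2))
  }
})

test_that("concordance stratifies by genotype class of the first call set", {
  calls <- function(df) {
    tibble::tibble(locus_id = df$l, status = "called",
                   allele1 = pmin(df$a, df$b), allele2 = pmax(df$a, df$b),
                   depth = 10L)
  }
  g1 <- calls(data.frame(l = paste0("L", 1:10),
                         a = c(rep("A", 6), "A", "A", "A", "A"),
                         b = c(rep("A", 6), "B", "B", "B", "B")))
  self <- concordance(g1, g1)
  expect_equal(self$agreement, c(1, 1, 1))

  # flip one homozygote and one heterozygote in the second set
  g2 <- g1
  g2$allele1[1] <- g2$allele2[1] <- "B"     # hom discordance at L1
  g2$allele2[7] <- "A"; g2$allele1[7] <- "A" # het -> hom at L7
  cc <- concordance(g1, g2)
  expect_equal(cc$genotyped[cc$stratum == "homozygote"], 6L)
  expect_equal(cc$same[cc$stratum == "homozygote"], 5L)
  expect_equal(cc$genotyped[cc$stratum == "heterozygote"], 4L)
  expect_equal(cc$same[cc$stratum == "heterozygote"], 3L)
  expect_equal(cc$agreement[cc$stratum == "all"], 8 / 10)

  # disjoint called loci: agreement undefined
  g3 <- dplyr::mutate(g1, locus_id = paste0("M", 1:10))
  cc3 <- concordance(g1, g3)
  expect_true(all(is.na(cc3$agreement)))
  expect_equal(cc3$genotyped, c(0L, 0L, 0L))
})

test_that("allele-sharing distance counts shared allele copies", {
  mk <- function(a, b) {
    tibble::tibble(locus_id = paste0("L", seq_along(a)), status = "called",
                   allele1 = pmin(a, b), allele2 = pmax(a, b), depth = 10L)
  }
  homA <- mk(rep("A", 5), rep("A", 5))
  homB <- mk(rep("B", 5), rep("B", 5))
  het <- mk(rep("A", 5), rep("B", 5))
  gm <- genotype_matrix(list(s1 = homA, s2 = homA, s3 = homB, s4 = het))
  D <- allele_sharing_distance(gm)
  expect_equal(D["s1", "s2"], 0)     # identical genotypes
  expect_equal(D["s1", "s3"], 1)     # AA vs BB
  expect_equal(D["s1", "s4"], 0.5)   # AA vs AB: one shared copy of two
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 4), c("s1", "s2", "s3", "s4")))
  gm2 <- genotype_matrix(list(
    s1 = homA,
    s2 = dplyr::mutate(homB, locus_id = paste0("M", 1:5))))
  expect_error(allele_sharing_distance(gm2), "no called locus")
})

test_that("neighbor joining recovers 3-taxon branch lengths in closed form", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nwk <- neighbor_joining(d)
  # branch to a = (d_ab + d_ac - d_bc)/2 = 2, b = 3, c = 7
  expect_match(nwk, "a:2")
  expect_match(nwk, "b:3")
  expect_match(nwk, "c:7")
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
  d_bad <- d; d_bad[1, 2] <- 4
  expect_error(neighbor_joining(d_bad), "symmetric")
  d_neg <- d; d_neg[1, 2] <- d_neg[2, 1] <- -1
  expect_error(neighbor_joining(d_neg), "negative")
})

test_that("NJ reproduces additive metrics exactly", {
  # 4-taxon tree ((a:2,b:3):1,(c:4,d:5)) -> additive path metric
  d4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d4["a", "b"] <- d4["b", "a"] <- 5
  d4["a", "c"] <- d4["c", "a"] <- 7
  d4["a", "d"] <- d4["d", "a"] <- 8
  d4["b", "c"] <- d4["c", "b"] <- 8
  d4["b", "d"] <- d4["d", "b"] <- 9
  d4["c", "d"] <- d4["d", "c"] <- 9
  nwk <- neighbor_joining(d4)
  expect_equal(nwk_dist(nwk), d4, tolerance = 1e-9)

  # 6 taxa from a random tree: path metric is reproduced
  skip_if_not_installed("ape")
  set.seed(8)
  tr <- ape::rtree(6, br = function(n) runif(n, 1, 4))
  dm <- ape::cophenetic.phylo(tr)
  dm <- dm[order(rownames(dm)), order(colnames(dm))]
  expect_equal(nwk_dist(neighbor_joining(dm)), dm, tolerance = 1e-9)
  # and agrees with the reference implementation's path metric
  ref <- ape::cophenetic.phylo(ape::nj(dm))
  ref <- ref[order(rownames(ref)), order(colnames(ref))]
  expect_equal(nwk_dist(neighbor_joining(dm)), ref, tolerance = 1e-8)
})

test_that("PCA separates planted populations and orders variance", {
  set.seed(31)
  loci <- paste0("L", 1:60)
  mkcalls <- function(p_alt) {
    dose <- rbinom(60, 2, p_alt)
    tibble::tibble(locus_id = loci, status = "called",
                   allele1 = ifelse(dose >= 1, "B", "A"),
                   allele2 = ifelse(dose == 2, "B", "A"),
                   depth = 10L)
  }
  pops <- c(lapply(1:4, function(i) mkcalls(rep(c(0.05, 0.9), each = 30))),
            lapply(1:4, function(i) mkcalls(rep(c(0.9, 0.05), each = 30))))
  names(pops) <- paste0("s", 1:8)
  pc <- genotype_pca(genotype_matrix(pops))
  pc1 <- pc$scores$PC1
  expect_true(max(pc1[1:4]) < min(pc1[5:8]) || min(pc1[1:4]) > max(pc1[5:8]))
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-9)

  # duplicated samples land on identical coordinates
  dup <- genotype_pca(genotype_matrix(list(a = pops$s1, b = pops$s1,
                                           c = pops$s5, d = pops$s5)))
  expect_equal(dup$scores[dup$scores$sample_id == "a", -1],
               dup$scores[dup$scores$sample_id == "b", -1],
               ignore_attr = TRUE)
  one_locus <- tibble::tibble(locus_id = "L1", status = "called",
                              allele1 = "A", allele2 = "A", depth = 5L)
  expect_error(genotype_pca(genotype_matrix(list(a = one_locus,
                                                 b = one_locus))),
               "informative loci")
})

test_that("genotype TSV and VCF outputs are well formed", {
  g1 <- tibble::tibble(locus_id = c("L1", "L2"), status = "called",
                       allele1 = c("AAAA", "CCCC"),
                       allele2 = c("AAAA", "CCCG"), depth = c(8L, 12L))
  g2 <- tibble::tibble(locus_id = c("L1", "L2"), status = "called",
                       allele1 = c("AAAT", "CCCC"),
                       allele2 = c("AAAT", "CCCC"), depth = c(6L, 9L))
  gm <- genotype_matrix(list(s1 = g1, s2 = g2))
  tsv <- tempfile(fileext = ".tsv")
  write_genotypes(gm, tsv)
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), 4L)
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(gm, vcf)
  lines <- readLines(vcf)
  expect_true(any(startsWith(lines, "##fileformat=VCF")))
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 2L)     # both loci are polymorphic across samples
  expect_match(body[1], "GT:DP")
})
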