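lin6 <- toy_lineages(tibble::tibble(
  genome_id = paste0("g", 1:6),
  k = c("k1", "k1", "k1", "k1", "k1", "k2"),
  p = c("p1", "p1", "p1", "p1", "p2", "p3"),
  c = c("c1", "c1", "c1", "c1", "c2", "c3"),
  o = c("o1", "o1", "o1", "o1", "o2", "o3"),
  f = c("f1", "f1", "f1", "f2", "f3", "f4"),
  g = c("ge1", "ge1", "ge1", "ge3", "ge4", "ge5"),
  s = c("s1", "s1", "s2", "s3", "s4", "s5")))

test_that("single-copy filter keeps exactly the count-1 tags", {
  expect_equal(single_copy_tags(fake_digest(c(t1 = 1, t2 = 2))), "t1")
  empty <- fake_digest(integer(0))
  expect_true(empty$no_site)
  expect_equal(single_copy_tags(empty), character(0))
  set.seed(3)
  counts <- setNames(sample(1:3, 50, replace = TRUE), paste0("tag", 1:50))
  expect_equal(single_copy_tags(fake_digest(counts)),
               sort(names(counts)[counts == 1]))
})

test_that("specificity is the deepest rank shared by carrying genomes", {
  sets <- list(g1 = c("tA", "tB", "tK"), g2 = c("tA", "tC"),
               g3 = c("tB", "tC"), g6 = "tK")
  db <- assign_specificity(sets, lin6)
  m <- db$microbial
  # same species (g1, g2 both s1) -> species-specific
  expect_equal(m$specificity_rank[m$canonical_tag == "tA"], "species")
  expect_equal(m$taxon_label[m$canonical_tag == "tA"], "s1")
  # g1 (s1) and g3 (s2): same genus ge1 -> genus-specific
  expect_equal(m$specificity_rank[m$canonical_tag == "tB"], "genus")
  # g2, g3: same genus too
  expect_equal(m$specificity_rank[m$canonical_tag == "tC"], "genus")
  # g1 (k1) and g6 (k2): kingdom disagreement -> excluded from the map
  expect_false("tK" %in% m$canonical_tag)
  expect_equal(db$nonspecific$canonical_tag, "tK")
  expect_error(assign_specificity(list(gX = "t"), lin6, bcgi()),
               "without lineage.*gX")
})

test_that("specificity map equals an exhaustive per-tag LCA oracle", {
  set.seed(21)
  for (rep in 1:10) {
    tags <- paste0("t", 1:15)
    sets <- lapply(setNames(seq_len(6), lin6$genome_id), function(i) {
      sample(tags, sample(3:10, 1))
    })
    db <- assign_specificity(sets, lin6)
    long <- tibble::tibble(
      genome_id = rep(names(sets), lengths(sets)),
      tag = unlist(sets, use.names = FALSE))
    for (tg in unique(long$tag)) {
      gids <- long$genome_id[long$tag == tg]
      want <- oracle_lca(lin6[lin6$genome_id %in% gids, ])
      row <- db$microbial[db$microbial$canonical_tag == tg, ]
      if (want$rank == "nonspecific") {
        expect_equal(nrow(row), 0L)
        expect_true(tg %in% db$nonspecific$canonical_tag)
      } else {
        expect_equal(row$specificity_rank, want$rank)
        expect_equal(row$taxon_label, want$label)
      }
    }
  }
})

test_that("adding a genome never deepens a tag's specificity", {
  sets <- list(g1 = "tX", g2 = "tX")
  rank_order <- c("nonspecific", "kingdom", "phylum", "class", "order",
                  "family", "genus", "species")
  depth <- function(db, tag) {
    r <- db$microbial$specificity_rank[db$microbial$canonical_tag == tag]
    if (length(r) == 0L) r <- "nonspecific"
    match(r, rank_order)
  }
  d2 <- depth(assign_specificity(sets, lin6), "tX")
  for (extra in c("g3", "g4", "g5", "g6")) {
    sets[[extra]] <- "tX"
    expect_lte(depth(assign_specificity(sets, lin6), "tX"), d2)
  }
})

test_that("host tag set is the single-copy filter of the host digest", {
  h <- build_host_tagset(fake_digest(c(h1 = 1, h2 = 2, h3 = 1), "host"))
  expect_equal(h$tags, c("h1", "h3"))
  expect_equal(h$n_distinct, 3L)
  expect_equal(h$n_unique, 2L)
})

test_that("cross-deredundancy removes shared tags from both sides", {
  sets <- list(g1 = c("tA", "tShared"), g2 = "tA", g3 = "tB")
  db <- assign_specificity(sets, lin6)
  # disjoint: nothing removed
  db0 <- cross_deredundancy(db, c("hostOnly1", "hostOnly2"))
  expect_equal(db0$dedup_report$host_tags_removed, 0L)
  expect_equal(db0$dedup_report$microbial_tags_removed, 0L)
  expect_equal(sort(db0$host_tags), c("hostOnly1", "hostOnly2"))

  # shared tag that is the sole species tag of s1? tShared is s1's only
  # species-specific... tA is species s1 too; engineer g3's sole tag instead
  sets2 <- list(g1 = "tA", g2 = "tA", g3 = "tOnly")
  db2 <- assign_specificity(sets2, lin6)
  db2 <- cross_deredundancy(db2, c("tOnly", "hostX"))
  expect_false("tOnly" %in% db2$microbial$canonical_tag)
  expect_false("tOnly" %in% db2$host_tags)
  expect_equal(db2$genomes$status[db2$genomes$genome_id == "g3"],
               "removed_by_deredundancy")
  expect_false("s2" %in% db2$theoretical$species)
})

test_that("deredundancy obeys set algebra and conservation laws", {
  set.seed(17)
  for (rep in 1:10) {
    tags <- paste0("t", 1:30)
    sets <- lapply(setNames(seq_len(6), lin6$genome_id),
                   function(i) sample(tags, sample(5:15, 1)))
    host <- sample(tags, 10)
    db <- assign_specificity(sets, lin6)
    before_m <- db$microbial$canonical_tag
    db2 <- cross_deredundancy(db, host)
    shared <- intersect(host, before_m)
    expect_equal(sort(db2$host_tags), sort(setdiff(host, shared)))
    expect_equal(sort(db2$microbial$canonical_tag),
                 sort(setdiff(before_m, shared)))
    # partition: no tag on both sides
    expect_length(intersect(db2$host_tags, db2$microbial$canonical_tag), 0)
    r <- db2$dedup_report
    expect_equal(r$host_tags_removed + r$host_tags_retained,
                 r$host_tags_before)
    expect_equal(r$microbial_tags_removed + r$microbial_tags_retained,
                 r$microbial_tags_before)
    # theoretical counts total = number of species-specific tags
    expect_equal(sum(db2$theoretical$n_tags),
                 sum(db2$microbial$specificity_rank == "species"))
  }
})

test_that("database statistics report ranks, retention and means", {
  sets <- list(g1 = c("tA", "tB"), g2 = "tA")
  digests <- list(g1 = fake_digest(c(tA = 1, tB = 1, tX = 2), "g1"),
                  g2 = fake_digest(c(tA = 1), "g2"))
  db <- assign_specificity(sets, lin6, digests = digests)
  st <- db_statistics(db)
  expect_equal(st$mean_tags_per_genome, (4 + 1) / 2)  # 4 occurrences in g1
  pr <- st$per_rank
  expect_equal(pr$n_tags[pr$rank == "species"], 2L)  # tA (s1), tB (genus? )
  # single-genome case: all its single-copy tags are species-specific
  db1 <- assign_specificity(list(g1 = c("u1", "u2")), lin6)
  st1 <- db_statistics(db1)
  expect_equal(st1$per_rank$fraction[st1$per_rank$rank == "species"], 1)
})

test_that("database round-trips through its TSV format", {
  sets <- list(g1 = c("tACGT", "tB"), g2 = "tACGT", g6 = "tB")
  db <- assign_specificity(sets, lin6)
  db <- cross_deredundancy(db, c("hostA", "hostB", "tB"))
  path <- tempfile(fileext = ".tsv.gz")
  write_holodb(db, path)
  db2 <- read_holodb(path)
  expect_equal(db2$microbial, dplyr::arrange(db$microbial, canonical_tag))
  expect_equal(sort(db2$host_tags), sort(db$host_tags))
  expect_equal(db2$theoretical, db$theoretical)
  expect_identical(db2$enzyme$recognition, db$enzyme$recognition)
  expect_true(db2$dereplicated)
  g2 <- dplyr::arrange(db$genomes, genome_id)
  expect_equal(db2$genomes[names(g2)], g2)
})

test_that("malformed database files raise format errors", {
  path <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(path, "wb"); writeLines("#something-else\tv9", con); close(con)
  expect_error(read_holodb(path), "version")
  sets <- list(g1 = "tA", g2 = "tA")
  db <- assign_specificity(sets, lin6)
  write_holodb(db, path)
  lines <- readLines(gzfile(path))
  con <- gzfile(path, "wb")
  writeLines(head(lines, -1), con)  # drop the #END terminator
  close(con)
  expect_error(read_holodb(path), "truncated")
  bad <- lines
  bad[grep("MICROBIAL", bad) + 1L] <- "only_one_field"
  con <- gzfile(path, "wb"); writeLines(bad, con); close(con)
  expect_error(read_holodb(path), "malformed MICROBIAL line")
})
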