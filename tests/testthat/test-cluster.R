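catalog <- load_gene_catalog()
core7 <- c("hpnC", "hpnD", "hpnE", "shc", "hpnG", "hpnH", "hpnI")

test_that("seven genes with locus tags stepping by 5 form one gap-free cluster", {
  tags <- sprintf("ABC_%05d", seq(325, by = 5, length.out = 7))
  hits <- fake_hits(core7, tags)
  feats <- fake_features(tags)
  cl <- cluster_hits(hits, feats)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$members$family_id, core7)
  expect_equal(cl[[1]]$intervening, rep(0, 6))
  ar <- classify_architecture(cl, catalog)
  expect_equal(ar$class, "contiguous")
  expect_equal(ar$order_concordance, 1.0)
})

test_that("the same genes split over two contigs classify as fragmented", {
  tags <- sprintf("ABC_%05d", seq(325, by = 5, length.out = 7))
  hits <- fake_hits(core7, tags)
  feats <- rbind(fake_features(tags[1:4], contig = "c1"),
                 fake_features(tags[5:7], contig = "c2"))
  cl <- cluster_hits(hits, feats)
  expect_length(cl, 2)
  ar <- classify_architecture(cl, catalog)
  expect_equal(ar$class, "fragmented")
  expect_equal(ar$n_fragments, 2)
  expect_equal(ar$order_concordance, 1.0)  # order preserved across fragments
})

test_that("a single accepted hit forms a singleton cluster", {
  hits <- fake_hits("shc", "X_00010")
  cl <- cluster_hits(hits, fake_features("X_00010"))
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]$members), 1)
})

test_that("a hit without a matching feature names the offending protein", {
  hits <- fake_hits(c("shc", "hpnH"), c("X_00010", "X_00015"))
  expect_error(cluster_hits(hits, fake_features("X_00010")), "X_00015")
})

test_that("a minus-strand operon scores the same order concordance as forward", {
  genes <- c("hpnC", "hpnD", "hpnE", "shc", "hpnG", "hpnH")
  tags <- sprintf("M_%05d", seq(100, by = 5, length.out = 6))
  fwd <- classify_architecture(
    cluster_hits(fake_hits(genes, tags), fake_features(tags)), catalog)
  # reversed end-to-end on the minus strand
  rev_feats <- fake_features(tags, strand = "-")
  rev_hits <- fake_hits(rev(genes), tags)
  rev_ar <- classify_architecture(cluster_hits(rev_hits, rev_feats), catalog)
  expect_equal(fwd$order_concordance, 1.0)
  expect_equal(rev_ar$order_concordance, 1.0)
})

test_that("concordance for permuted fragments equals the enumeration oracle", {
  set.seed(19)
  genes <- c("hpnC", "hpnD", "hpnE", "shc", "hpnG", "hpnH")
  ranks <- catalog$canonical_order[match(genes, catalog$family_id)]
  for (i in 1:20) {
    perm <- sample(6)
    split_at <- sample(2:5, 1)
    tags <- sprintf("P_%05d", seq(100, by = 5, length.out = 6))
    feats <- rbind(fake_features(tags[1:split_at], contig = "c1"),
                   fake_features(tags[(split_at + 1):6], contig = "c2"))
    hits <- fake_hits(genes[perm], tags)
    ar <- classify_architecture(cluster_hits(hits, feats), catalog)
    expect_equal(ar$order_concordance,
                 kendall_oracle(seq_len(6), ranks[perm]),
                 label = paste(perm, collapse = ","))
  }
})

test_that("clustering is idempotent and independent of hit order", {
  set.seed(3)
  tags <- sprintf("I_%05d", seq(5, by = 5, length.out = 10))
  genes <- sample(c(core7, "hpnK", "hpnJ", "hpnN"))
  feats <- fake_features(tags)
  h1 <- fake_hits(genes, tags)
  h2 <- h1[sample(nrow(h1)), ]
  c1 <- cluster_hits(h1, feats)
  c2 <- cluster_hits(h2, feats)
  key <- function(cl) lapply(cl, function(x) x$members$protein_id)
  expect_identical(key(c1), key(c2))
})

test_that("raising the gap tolerance never increases the cluster count", {
  set.seed(42)
  for (rep in 1:200) {
    n_path <- sample(3:8, 1)
    n_total <- sample(20:40, 1)
    pos <- sort(sample(n_total, n_path))
    tags <- sprintf("R_%05d", seq(5, by = 5, length.out = n_total))
    feats <- fake_features(tags)
    genes <- sample(catalog$family_id[catalog$canonical_bgc_member], n_path)
    hits <- fake_hits(genes, tags[pos])
    prev <- Inf
    for (G in c(0, 1, 3, 6, 12)) {
      n <- length(cluster_hits(hits, feats, gap_policy(G = G, L = 0)))
      expect_lte(n, prev)
      prev <- n
    }
  }
})
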