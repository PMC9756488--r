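make_table <- function(counts, lineages) {
  dimnames(counts) <- list(paste0("s", seq_len(nrow(counts))),
                           paste0("otu", seq_len(ncol(counts))))
  as_otu_table(counts, stats::setNames(lineages, colnames(counts)))
}

test_that("qc_filter drops low-read samples at the strict <100 boundary and excluded taxa", {
  counts <- rbind(c(50, 49), c(60, 40), c(300, 200))
  tab <- make_table(counts, c("k__Bacteria; p__A; g__X", "k__Bacteria; p__B; g__Methanobrevibacter"))
  out <- qc_filter(tab, min_reads = 100)
  expect_setequal(rownames(out$counts), c("s2", "s3"))  # 99 dropped, 100 kept
  out2 <- qc_filter(tab, exclude_taxa = "g__Methanobrevibacter")
  expect_equal(colnames(out2$counts), "otu1")
  # identity when nothing filters
  out3 <- qc_filter(make_table(rbind(c(200, 200), c(150, 150)),
                               rep("k__Bacteria; p__A", 2)))
  expect_equal(dim(out3$counts), c(2L, 2L))
  expect_error(qc_filter(make_table(rbind(c(1, 1)), rep("k__Bacteria", 2))),
               "every sample")
})

test_that("retention rule follows the strict abundance / inclusive prevalence convention", {
  expect_true(passes_retention(c(0.002, 0.002, rep(0, 8))))       # 2/10 = 20% >= 15%
  expect_false(passes_retention(rep(0.001, 10)))                  # strict "more than"
  expect_false(passes_retention(rep(0, 6)))
  expect_true(passes_retention(c(0.5, rep(0, 5)), prev_thresh = 1 / 6))
  expect_error(passes_retention(c(-0.1, 0.5)), "0, 1")
})

test_that("a single failing pair collapses to its shared genus, passers untouched", {
  # otuA dominant everywhere; otuB/otuC rare (< 0.1%), same genus, species
  # unclassified so the collapse targets the genus directly
  counts <- cbind(A = c(9000, 9000, 9000, 9000), B = c(1, 1, 1, 1), C = c(2, 1, 1, 1))
  lin <- c("k__Bacteria; p__P; g__Y; s__a",
           "k__Bacteria; p__P; g__X; s__",
           "k__Bacteria; p__P; g__X; s__")
  tab <- make_table(counts, lin)
  ft <- amalgamate(tab, n_iter = 1L)
  agg <- ft$info[ft$info$effective_rank == "genus", ]
  expect_equal(nrow(agg), 1L)
  expect_match(agg$lineage, "g__X")
  expect_setequal(strsplit(agg$members, ";")[[1]], c("otu2", "otu3"))
  # otuA passes unaltered; the aggregate carries the summed counts
  expect_true("otu1" %in% colnames(ft$counts))
  expect_equal(unname(ft$excluded[, agg$feature]), c(3, 2, 2, 2))
  # conservation: retained + excluded columns reproduce per-sample totals
  expect_equal(rowSums(cbind(ft$counts, ft$excluded)), rowSums(counts),
               ignore_attr = TRUE)
})

test_that("degenerate thresholds keep every OTU unaltered", {
  rt <- random_otu_table(99)
  tab <- as_otu_table(rt$counts, rt$lineages)
  ft <- amalgamate(tab, abund_thresh = 0, prev_thresh = 0)
  expect_equal(ncol(ft$counts), ncol(rt$counts))
  expect_equal(unname(ft$counts[, order(colnames(ft$counts))]),
               unname(rt$counts[, order(colnames(rt$counts))]))
})

test_that("amalgamation is invariant to OTU and sample order", {
  rt <- random_otu_table(7)
  tab <- as_otu_table(rt$counts, rt$lineages)
  ft1 <- amalgamate(tab)
  perm_o <- sample(ncol(rt$counts)); perm_s <- sample(nrow(rt$counts))
  tab2 <- as_otu_table(rt$counts[perm_s, perm_o], rt$lineages[perm_o])
  ft2 <- amalgamate(tab2)
  reord <- function(ft) {
    cts <- ft$counts[sort(rownames(ft$counts)), , drop = FALSE]
    feat_signature(lapply(ft$info$lineage[ft$info$status == "retained"],
                          parse_lineage),
                   lapply(seq_len(ncol(cts)), function(j) cts[, j]))
  }
  expect_equal(reord(ft1), reord(ft2))
})

test_that("every retained feature passes retention and exclusions failed to the end", {
  for (s in c(11, 23)) {
    rt <- random_otu_table(s)
    tab <- as_otu_table(rt$counts, rt$lineages)
    ft <- amalgamate(tab)
    totals <- rowSums(rt$counts)
    for (j in seq_len(ncol(ft$counts)))
      expect_true(passes_retention(ft$counts[, j] / totals))
    for (j in seq_len(ncol(ft$excluded)))
      expect_false(passes_retention(ft$excluded[, j] / totals))
    expect_equal(rowSums(cbind(ft$counts, ft$excluded)), totals)
  }
})

test_that("diversity metrics match their closed forms", {
  expect_equal(observed_richness(c(5, 5, 5, 5)), 4L)
  expect_equal(shannon(c(5, 5, 5, 5)), log(4))
  expect_equal(observed_richness(c(10, 0, 0)), 1L)
  expect_equal(shannon(c(10, 0, 0)), 0)
  expect_equal(shannon(c(1, 1, 2)), -(2 * 0.25 * log(0.25) + 0.5 * log(0.5)))
  expect_equal(observed_richness(numeric(3)), 0L)
  expect_error(shannon(c(0, 0)), "undefined")
  # Shannon <= log(richness), equality iff uniform
  set.seed(1)
  for (i in 1:20) {
    x <- rpois(8, 20) + 1
    expect_lte(shannon(x), log(observed_richness(x)) + 1e-12)
  }
})

test_that("Bray-Curtis and PCoA behave on canonical configurations", {
  rel <- rbind(a = c(0.5, 0.5, 0), b = c(0.5, 0.5, 0), c = c(0, 0, 1))
  d <- bray_curtis(rel)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)   # disjoint supports
  expect_true(isSymmetric(d))
  # planar configuration: PCoA must reproduce the distances exactly
  set.seed(3)
  pts <- matrix(runif(8), 4)
  D <- as.matrix(dist(pts))
  ord <- pcoa(D, n_axes = 2)
  expect_equal(as.matrix(dist(ord$coords)), D, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("arcsin-sqrt transform hits its boundary values and is monotone", {
  counts <- rbind(c(0, 10), c(5, 15), c(10, 0))
  y <- arcsin_sqrt_tss(counts)
  expect_equal(y[1, 1], 0)
  expect_equal(y[3, 1], pi / 2)
  expect_equal(arcsin_sqrt_tss(rbind(c(1, 3)))[1, 1], asin(sqrt(0.25)))
  expect_equal(asin(sqrt(0.25)), pi / 6)
  set.seed(4)
  p <- sort(runif(20))
  yy <- asin(sqrt(p))
  expect_true(all(diff(yy) > 0))
  expect_error(arcsin_sqrt_tss(rbind(c(0, 0))), "zero-total")
})
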