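test_that("cell filtering keeps cells at or above the UMI floor", {
  counts <- cbind(c1 = c(999, 0, 0), c2 = c(500, 400, 100), c3 = c(0, 2500, 2500))
  rownames(counts) <- paste0("g", 1:3)
  m <- umi_matrix(counts, c("A", "A", "B"))
  kept <- filter_cells_min_umi(m, 1000)
  expect_equal(colnames(kept$counts), c("c2", "c3"))  # exactly 1000 is kept
  expect_equal(rownames(kept$counts), rownames(counts))

  expect_equal(colnames(filter_cells_min_umi(m, 0)$counts), colnames(counts))
  expect_error(filter_cells_min_umi(m, 1e7), "all cells")

  set.seed(2)
  big <- matrix(rpois(50 * 30, 40), 50, 30)
  bm <- make_umi(big, rep("A", 30))
  kept2 <- filter_cells_min_umi(bm, 2000)
  expect_equal(colnames(kept2$counts),
               colnames(bm$counts)[colSums(big) >= 2000])
})

test_that("label exclusion drops the flagged subcluster", {
  m <- make_umi(matrix(5, 3, 6), c("DA", "DA", "astro_like", "DA", "astro_like", "DA"))
  out <- exclude_cell_labels(m, "astro_like")
  expect_equal(ncol(out$counts), 4)
  expect_false("astro_like" %in% levels(out$cell_labels))
})

test_that("binomial specificity equals exact binomial tails", {
  # gene never expressed anywhere: k = 0, upper tail is certain
  m0 <- make_umi(matrix(0, 2, 6), rep(c("A", "B"), each = 3))
  expect_equal(binomial_specificity(m0, "A", "g1"), 1)

  # cluster of 3 with k = 2; 4 of 8 outside cells expressing -> p_out 0.5
  counts <- matrix(0, 1, 11)
  counts[1, c(1, 2)] <- 5          # 2 of 3 in-cluster
  counts[1, 4:7] <- 3              # 4 of 8 outside
  m <- make_umi(counts, c(rep("A", 3), rep("B", 8)))
  expect_equal(binomial_specificity(m, "A", "g1"),
               pbinom(1, 3, 0.5, lower.tail = FALSE))
  expect_equal(binomial_specificity(m, "A", "g1"), 0.5)

  # planted marker: whole 50-cell cluster expressing, 1% of 200 outside
  counts2 <- matrix(0, 1, 250)
  counts2[1, 1:50] <- 2
  counts2[1, 51:52] <- 1
  m2 <- make_umi(counts2, c(rep("DA", 50), rep("rest", 200)))
  expect_lt(binomial_specificity(m2, "DA", "g1"), 1e-60)

  expect_error(binomial_specificity(m2, "DA", "nope"), "unknown gene")
  expect_error(binomial_specificity(m2, "nope", "g1"), "unknown")
})

test_that("the vectorised rank-sum test matches wilcox.test", {
  set.seed(31)
  for (i in 1:8) {
    X <- matrix(rpois(20 * 14, 3), 20, 14)   # heavy ties
    idx_a <- 1:6
    p <- proxcomp:::rank_sum_rows(X, idx_a)
    ref <- apply(X, 1, function(x) {
      suppressWarnings(wilcox.test(x[idx_a], x[-idx_a], exact = FALSE,
                                   correct = TRUE)$p.value)
    })
    ref[is.nan(ref)] <- 1  # all-tied rows
    expect_equal(unname(p), unname(ref), tolerance = 1e-10)
  }
})

test_that("subsampled DE is null on duplicated groups and deterministic", {
  set.seed(6)
  counts <- matrix(rpois(100 * 10, 5), 100, 10)
  m <- make_umi(counts, rep("A", 10))
  cells <- colnames(m$counts)
  d <- subsampled_de(m, cells, cells, seed = 3)
  expect_true(all(d$log2fc == 0))
  expect_true(all(d$p == 1))

  g1 <- cells[1:5]; g2 <- cells[6:10]
  d1 <- subsampled_de(m, g1, g2, seed = 9)
  d2 <- subsampled_de(m, g1, g2, seed = 9)
  expect_identical(d1, d2)
  # cell order within groups is irrelevant: membership is anchored to
  # sorted barcodes
  d3 <- subsampled_de(m, rev(g1), sample(g2), seed = 9)
  expect_identical(d1, d3)

  expect_error(subsampled_de(m, cells[1], cells[2:4], seed = 1), ">= 2")
})

test_that("binomial thinning equalizes mean transcripts per cell", {
  set.seed(13)
  deep <- matrix(rpois(200 * 20, 20), 200, 20)    # ~4000 UMI cells
  shallow <- matrix(rpois(200 * 20, 5), 200, 20)  # ~1000 UMI cells
  counts <- cbind(deep, shallow)
  m <- make_umi(counts, rep(c("deep", "shallow"), each = 20))
  cells <- colnames(m$counts)
  d <- subsampled_de(m, cells[1:20], cells[21:40], seed = 4)
  # after thinning both groups share the shallow group's depth, so the
  # normalized means of an equal-probability gene agree closely
  expect_equal(mean(d$mean_a), mean(d$mean_b), tolerance = 0.05)
  expect_lt(mean(abs(d$log2fc)), 0.25)
})

test_that("a shared-multinomial null produces almost no discoveries", {
  rates <- vapply(1:4, function(s) {
    set.seed(100 + s)
    probs <- rgamma(400, 0.7) + 1e-4
    counts <- vapply(1:120, function(j) {
      rmultinom(1, 1500, probs)[, 1]
    }, integer(400))
    m <- make_umi(counts, rep("A", 120))
    cells <- colnames(m$counts)
    d <- subsampled_de(m, cells[1:60], cells[61:120], seed = s)
    mean(d$q < 0.01)
  }, numeric(1))
  expect_lte(mean(rates), 0.02)
})

test_that("expression bounds summarize the per-gene mean log expression", {
  # equal library sizes: size factors are 1, so means are direct
  counts <- rbind(g1 = c(1, 1), g2 = c(3, 3), g3 = c(7, 7), g4 = c(0, 0))
  colnames(counts) <- c("c1", "c2")
  m <- umi_matrix(counts, c("DA", "DA"))
  b <- expression_bounds(m)
  gm <- log2(c(1, 3, 7) + 1)
  expect_equal(unname(b$means), gm)          # zero-total gene excluded
  expect_equal(b$lower, mean(gm) - sd(gm))
  expect_equal(b$upper, mean(gm) + sd(gm))
  expect_lte(b$lower, b$upper)

  flat_counts <- rbind(g1 = c(2, 2), g2 = c(2, 2))
  colnames(flat_counts) <- c("c1", "c2")
  flat <- umi_matrix(flat_counts, c("DA", "DA"))
  expect_warning(bf <- expression_bounds(flat), "degenerate")
  expect_equal(bf$lower, bf$upper)
})

test_that("roughly the expected fraction of genes clears the lower bound", {
  # per-gene rates spanning ~normal mean log expression: mean - SD should
  # cut about the normal 16% tail
  fracs <- vapply(1:3, function(s) {
    set.seed(s)
    lam <- 2^rnorm(500, 3, 1.5)
    counts <- vapply(1:50, function(j) rpois(500, lam), integer(500))
    rownames(counts) <- paste0("g", 1:500)
    colnames(counts) <- paste0("c", 1:50)
    b <- expression_bounds(umi_matrix(counts, rep("DA", 50)))
    mean(b$means > b$lower)
  }, numeric(1))
  expect_gt(mean(fracs), 0.78)
  expect_lt(mean(fracs), 0.90)
})

test_that("marker selection applies strict eightfold and FDR thresholds", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   log2fc = c(3.0, 3.5, 4.0, 2.9),
                   q = c(0.001, 0.005, 0.01, 0.0001))
  mk <- select_markers(de)
  expect_equal(mk$gene, "b")   # 3.0 excluded (strict), c excluded (q = 0.01)

  set.seed(40)
  de2 <- data.frame(gene = sprintf("g%02d", 1:50),
                    log2fc = runif(50, 0, 6), q = runif(50, 0, 0.02))
  perm <- sample(50)
  expect_identical(select_markers(de2), select_markers(de2[perm, ]))
})

test_that("UMI matrices round-trip through MTX triplet files", {
  set.seed(19)
  counts <- matrix(rpois(30 * 12, 2), 30, 12)
  m <- make_umi(counts, rep(c("DA", "other"), 6))
  dir <- tempfile()
  write_umi_mtx(m, dir)
  back <- read_umi_mtx(file.path(dir, "matrix.mtx"),
                       file.path(dir, "genes.tsv"),
                       file.path(dir, "barcodes.tsv"),
                       file.path(dir, "labels.tsv"))
  expect_equal(as.matrix(back$counts), as.matrix(m$counts))
  expect_equal(back$cell_labels, m$cell_labels)
})
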