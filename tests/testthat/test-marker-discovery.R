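test_that("reversal pairs are exactly the direction-conflicting overlaps", {
  mkset <- function(ga, gb, dir, freq = 0.9)
    ConsistentPairSet(data.frame(gene_a = ga, gene_b = gb, direction = dir,
                                 frequency = freq), threshold = 0.7)
  cancer <- mkset(c("g1", "g3", "g5"), c("g2", "g4", "g6"),
                  c("a_lt_b", "a_lt_b", "a_lt_b"))
  noncancer <- mkset(c("g1", "g3"), c("g2", "g4"),
                     c("a_gt_b", "a_lt_b"))
  rev <- detectReversalPairs(cancer, noncancer)
  # g1-g2 reverses; g3-g4 same direction; g5-g6 only in cancer
  expect_equal(nrow(rev), 1)
  expect_identical(rev$gene_a, "g1")
  expect_identical(rev$cancer_direction, "a_lt_b")
  expect_identical(rev$noncancer_direction, "a_gt_b")
})

test_that("reversal degree reproduces hand-computed rank differences", {
  vc <- matrix(c(1, 5, 3,
                 2, 6, 4), nrow = 3,
               dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  vn <- matrix(c(5, 1, 3,
                 6, 2, 4), nrow = 3,
               dimnames = list(c("g1", "g2", "g3"), c("n1", "n2")))
  rc <- withinSampleRanks(ReoMatrix(vc))
  rn <- withinSampleRanks(ReoMatrix(vn))
  d <- reversalDegree("g1", "g2", rc, rn)
  # |R1 - R2| = 2 in all four samples
  expect_equal(unname(d), c(2, 2, 2))
  # symmetric in the two genes
  expect_equal(reversalDegree("g2", "g1", rc, rn)[["avg_r"]], 2)
  # avg_r = sqrt(4 x 1) = 2 for unequal group means
  vc2 <- matrix(c(1, 9, 2, 3, 4,
                  1, 9, 2, 3, 4), nrow = 5,
                dimnames = list(paste0("g", 1:5), c("c1", "c2")))
  vn2 <- matrix(c(2, 1, 3, 4, 5,
                  2, 1, 3, 4, 5), nrow = 5,
                dimnames = list(paste0("g", 1:5), c("n1", "n2")))
  d2 <- reversalDegree("g1", "g2",
                       withinSampleRanks(ReoMatrix(vc2)),
                       withinSampleRanks(ReoMatrix(vn2)))
  expect_equal(unname(d2), c(4, 1, 2))
  expect_error(reversalDegree("g1", "zz", rc, rn), "zz")
})

test_that("reversal degree matches the naive oracle on random instances", {
  set.seed(303)
  for (trial in 1:40) {
    n <- sample(4:10, 1)
    xc <- randomSmallMatrix(n, sample(3:8, 1))
    xn <- randomSmallMatrix(n, sample(3:8, 1))
    genes <- sample(geneIds(xc), 2)
    got <- reversalDegree(genes[1], genes[2],
                          withinSampleRanks(xc), withinSampleRanks(xn))
    want <- oracleReversalDegree(exprsValues(xc), exprsValues(xn),
                                 genes[1], genes[2])
    expect_equal(unname(got), want)
  }
})

test_that("reversal-degree ranking is descending with lexicographic ties", {
  df <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                   cancer_direction = "a_lt_b",
                   avg_r = c(3.2, 5.1, 3.2))
  r <- rankByReversalDegree(df)
  expect_identical(paste(r$gene_a, r$gene_b), c("a c", "a b", "b c"))
  expect_identical(rankByReversalDegree(df[2, ])$gene_a, "a")
  expect_error(rankByReversalDegree(df[, 1:3]), "scored")
})

test_that("forward selection maximises training gmean, smallest k on ties", {
  # one planted pair separating classes perfectly -> k = 1, gmean = 1
  # (30 samples per class so no spurious background pair clears the
  # consistency threshold in both classes)
  cohort <- smallCohort(5, n_genes = 40, n_planted = 1,
                        n_pos = 30, n_neg = 30, fidelity = 1,
                        tie_fraction = 0)
  fit <- discoverMarkerPanel(cohort$matrix, cohort$annotation)
  expect_equal(panelSize(fit$panel), 1)
  expect_equal(max(fit$per_k$gmean), 1.0)
  # selected gmean dominates the whole per-k table
  expect_true(all(fit$per_k$gmean <=
                  fit$per_k$gmean[panelSize(fit$panel)]))
  expect_error(
    forwardSelectPanel(fit$reversal_pairs, cohort$matrix,
                       transform(cohort$annotation,
                                 binary_label = "positive")),
    "positive and negative")
})

test_that("selected k equals exhaustive search by an independent oracle", {
  set.seed(404)
  for (trial in 1:25) {
    cohort <- smallCohort(trial + 700, n_genes = 50, n_planted = 5,
                          n_pos = 10, n_neg = 10, fidelity = 0.8,
                          tie_fraction = 0.05)
    fit <- try(discoverMarkerPanel(cohort$matrix, cohort$annotation),
               silent = TRUE)
    if (inherits(fit, "try-error")) next  # no reversal pair at low fidelity
    ori <- fit$reversal_pairs
    lt <- ori$cancer_direction == "a_lt_b"
    oracle <- oracleForwardK(ifelse(lt, ori$gene_a, ori$gene_b),
                             ifelse(lt, ori$gene_b, ori$gene_a),
                             exprsValues(cohort$matrix),
                             cohort$annotation$binary_label == "positive")
    expect_equal(panelSize(fit$panel), oracle$k)
    expect_equal(fit$per_k$gmean, oracle$gmeans)
  }
})

test_that("marker panels round-trip through the panel file format", {
  p <- markerPanel(c("LOC100130691", "ZNF232-AS1"),
                   c("LOC441204", "TOB1-AS1"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeMarkerPanel(p, f)
  back <- readMarkerPanel(f)
  expect_identical(panelPairs(back), panelPairs(p))
  expect_error(markerPanel("a", "a"), "differ")
  expect_error(markerPanel(c("a", "b"), c("b", "a")), "duplicate")
})

test_that("the shipped six-pair colorectal panel loads with k = 6", {
  panel <- readMarkerPanel(system.file("extdata", "crc_sixpair_panel.tsv",
                                       package = "reoPairs"))
  expect_equal(panelSize(panel), 6)
  expect_equal(voteThreshold(panel), 3)
  expect_equal(length(unique(unlist(panelPairs(panel)))), 9)
})
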