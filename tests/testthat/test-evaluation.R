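mkTruth <- function(n_pos, n_neg) {
  makeSampleAnnotation(data.frame(
    sample_id = c(sprintf("p%02d", seq_len(n_pos)),
                  sprintf("n%02d", seq_len(n_neg))),
    class_label = c(rep("cancer", n_pos), rep("normal", n_neg))))
}

mkPreds <- function(truth, calls) {
  data.frame(sample_id = truth$sample_id, votes = NA_integer_,
             k = NA_integer_, call = calls, stringsAsFactors = FALSE)
}

test_that("confusion counts follow the positive/negative convention", {
  truth <- mkTruth(10, 10)
  perfect <- mkPreds(truth, c(rep("cancer", 10), rep("non_cancer", 10)))
  cc <- confusionCounts(perfect, truth)
  expect_equal(c(cc@TP, cc@FP, cc@TN, cc@FN), c(10, 0, 10, 0))
  oneFN <- perfect
  oneFN$call[1] <- "non_cancer"
  cc2 <- confusionCounts(oneFN, truth)
  expect_equal(cc2@FN, 1L)
  expect_equal(cc2@TP, 9L)
  expect_error(confusionCounts(perfect[0, ], truth), "no predictions")
  expect_error(confusionCounts(mkPreds(truth, "cancer")[1, ] |>
                                 transform(sample_id = "ghost"), truth),
               "ghost")
  # cancer-adjacent counts as positive, adenoma/ibd as negative
  t2 <- makeSampleAnnotation(data.frame(
    sample_id = c("s1", "s2", "s3"),
    class_label = c("cancer_adjacent", "adenoma", "ibd")))
  cc3 <- confusionCounts(mkPreds(t2, rep("cancer", 3)), t2)
  expect_equal(c(cc3@TP, cc3@FP), c(1L, 2L))
})

test_that("sensitivity/specificity formulas and undefined markers", {
  cc <- new("ConfusionCounts", TP = 9L, FN = 1L, TN = 49L, FP = 1L)
  m <- sensitivitySpecificity(cc)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.98)
  expect_equal(m$gmean, sqrt(0.9 * 0.98))
  expect_equal(m$accuracy, 58 / 60)
  # gmean^2 = sens x spec to machine precision
  expect_equal(m$gmean^2, m$sensitivity * m$specificity,
               tolerance = 1e-15)
  # sens 0.95, spec 0.98 -> gmean = sqrt(0.931)
  cc2 <- new("ConfusionCounts", TP = 95L, FN = 5L, TN = 98L, FP = 2L)
  expect_equal(sensitivitySpecificity(cc2)$gmean, sqrt(0.931))
  # no negatives: specificity and gmean undefined, never silently zero
  cc3 <- new("ConfusionCounts", TP = 5L, FN = 0L, TN = 0L, FP = 0L)
  m3 <- sensitivitySpecificity(cc3)
  expect_identical(m3$specificity, NA_real_)
  expect_identical(m3$gmean, NA_real_)
  expect_equal(m3$sensitivity, 1)
})

test_that("stratified accuracies match direct recounting and recompose", {
  cohort <- smallCohort(21, n_pos = 25, n_neg = 25, fidelity = 1,
                        tie_fraction = 0)
  fit <- discoverMarkerPanel(cohort$matrix, cohort$annotation)
  preds <- classifyMatrix(cohort$matrix, fit$panel)
  truth <- cohort$annotation
  for (field in c("stage", "class_label")) {
    tab <- stratifiedAccuracy(preds, truth, field)
    # brute-force recount per stratum
    strat <- as.character(truth[[field]][match(preds$sample_id,
                                               truth$sample_id)])
    strat[is.na(strat)] <- "unknown"
    correct <- (preds$call == "cancer") ==
      (truth$binary_label[match(preds$sample_id,
                                truth$sample_id)] == "positive")
    for (i in seq_len(nrow(tab))) {
      sel <- strat == tab$stratum[i]
      expect_equal(tab$n[i], sum(sel))
      expect_equal(tab$accuracy[i], mean(correct[sel]))
    }
    expect_equal(sum(tab$n), nrow(preds))
  }
  # class-label strata of the positives recompose to overall sensitivity
  tab <- stratifiedAccuracy(preds, truth, "class_label")
  posTab <- tab[tab$stratum %in% c("cancer", "cancer_adjacent"), ]
  m <- sensitivitySpecificity(confusionCounts(preds, truth))
  expect_equal(sum(posTab$n * posTab$accuracy) / sum(posTab$n),
               m$sensitivity)
})

test_that("reversal Fisher test matches hypergeometric enumeration", {
  # perfectly reversed 10 vs 10: p = 2 / choose(20, 10)
  truth <- mkTruth(10, 10)
  v <- matrix(2, 2, 20, dimnames = list(c("a", "b"), truth$sample_id))
  v["a", 1:10] <- 1   # a < b in all positives
  v["a", 11:20] <- 3  # a > b in all negatives
  ft <- reversalFisherTest(ReoMatrix(v), truth, "a", "b")
  expect_equal(ft$p_value, 2 / choose(20, 10))
  expect_equal(unname(ft$table), matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  # balanced table: no association
  v2 <- v
  v2["a", c(1:5, 11:15)] <- 1
  v2["a", c(6:10, 16:20)] <- 3
  expect_equal(reversalFisherTest(ReoMatrix(v2), truth, "a", "b")$p_value, 1)
  # swapping genes together with columns leaves p unchanged
  expect_equal(reversalFisherTest(ReoMatrix(v), truth, "b", "a")$p_value,
               ft$p_value)
  # all tied -> undefined, ties reported
  tied <- ReoMatrix(matrix(1, 2, 20,
                           dimnames = list(c("a", "b"), truth$sample_id)))
  ftt <- reversalFisherTest(tied, truth, "a", "b")
  expect_identical(ftt$p_value, NA_real_)
  expect_equal(ftt$n_ties_excluded, 20)
})

test_that("Fisher p agrees with the enumeration oracle on random tables", {
  set.seed(505)
  for (trial in 1:100) {
    N <- sample(4:30, 1)
    cells <- as.vector(stats::rmultinom(1, N, prob = runif(4, 0.1, 1)))
    tab <- matrix(cells, 2, 2)
    got <- stats::fisher.test(tab)$p.value
    expect_equal(got, oracleFisherTwoSided(tab), tolerance = 1e-10)
  }
})
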