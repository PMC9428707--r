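test_that("simulation is bit-identical under a fixed config and seed", {
  cfg <- simulationConfig(n_genes = 50, n_planted = 3, n_pos = 8, n_neg = 8,
                          seed = 33)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(exprsValues(a$matrix), exprsValues(b$matrix))
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth$planted_pairs, b$truth$planted_pairs)
  # a different seed changes the draw
  c <- simulateCohort(simulationConfig(n_genes = 50, n_planted = 3,
                                       n_pos = 8, n_neg = 8, seed = 34))
  expect_false(identical(exprsValues(a$matrix), exprsValues(c$matrix)))
  # the caller's RNG stream is not consumed
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulateCohort(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("fidelity 1 with no zeros forces planted orderings exactly", {
  cohort <- smallCohort(12, n_genes = 80, n_planted = 6, fidelity = 1,
                        tie_fraction = 0)
  pos <- cohort$annotation$sample_id[cohort$annotation$binary_label ==
                                       "positive"]
  neg <- setdiff(cohort$annotation$sample_id, pos)
  for (i in seq_len(nrow(cohort$truth$planted_pairs))) {
    pp <- cohort$truth$planted_pairs[i, ]
    fp <- pairDirectionFrequencies(cohort$matrix, pp$gene_a, pp$gene_b, pos)
    fn <- pairDirectionFrequencies(cohort$matrix, pp$gene_a, pp$gene_b, neg)
    expect_equal(unname(fp[["freq_a_lt_b"]]), 1.0)
    expect_equal(unname(fn[["freq_a_gt_b"]]), 1.0)
  }
})

test_that("at fidelity 1 discovery recovers exactly the planted pairs", {
  for (seed in 101:106) {
    cohort <- smallCohort(seed, n_genes = 100, n_planted = 5,
                          n_pos = 50, n_neg = 50, fidelity = 1,
                          tie_fraction = 0)
    fit <- discoverMarkerPanel(cohort$matrix, cohort$annotation)
    got <- paste(fit$reversal_pairs$gene_a, fit$reversal_pairs$gene_b)
    want <- paste(cohort$truth$planted_pairs$gene_a,
                  cohort$truth$planted_pairs$gene_b)
    expect_setequal(got, want)
  }
})

test_that("monotone distortions act per sample and preserve REO", {
  cohort <- smallCohort(44)
  x <- cohort$matrix
  # scale 2 on one sample doubles exactly that column
  params <- data.frame(scale = rep(1, ncol(x)), shift = rep(0, ncol(x)))
  params$scale[3] <- 2
  d <- applyMonotoneDistortion(x, "affine_positive", params = params)
  expect_equal(exprsValues(d)[, 3], exprsValues(x)[, 3] * 2)
  expect_equal(exprsValues(d)[, -3], exprsValues(x)[, -3])
  # power 0.5 then power 2 restores the original values
  s <- ncol(x)
  half <- applyMonotoneDistortion(x, "power",
                                  params = data.frame(exponent = rep(0.5, s)))
  back <- applyMonotoneDistortion(half, "power",
                                  params = data.frame(exponent = rep(2, s)))
  expect_equal(exprsValues(back), exprsValues(x), tolerance = 1e-12)
  # non-monotone parameters are rejected
  expect_error(applyMonotoneDistortion(x, "affine_positive",
                                       params = data.frame(scale = rep(-1, s),
                                                           shift = rep(0, s))),
               "scale")
  expect_error(applyMonotoneDistortion(x, "power",
                                       params = data.frame(exponent = rep(0, s))),
               "exponent")
})

test_that("distorted cohorts yield identical consistent-pair sets", {
  pos <- function(cohort)
    cohort$annotation$sample_id[cohort$annotation$binary_label == "positive"]
  for (seed in 1:5) {
    cohort <- smallCohort(seed + 60)
    fam <- c("affine_positive", "power", "log1p_scale")[(seed %% 3) + 1]
    d <- applyMonotoneDistortion(cohort$matrix, fam, seed = seed)
    s0 <- detectConsistentPairs(cohort$matrix, samples = pos(cohort))
    s1 <- detectConsistentPairs(d, samples = pos(cohort))
    expect_identical(pairTable(s0), pairTable(s1))
  }
})

test_that("platform views partition samples and keep planted genes", {
  cohort <- smallCohort(77, n_genes = 100, n_planted = 5)
  planted <- unique(unlist(cohort$truth$planted_pairs[, c("gene_a",
                                                          "gene_b")]))
  views <- makePlatformViews(cohort$matrix, nViews = 3,
                             geneKeepFraction = 0.6, seed = 2,
                             plantedGenes = planted)
  ids <- lapply(views, sampleIds)
  expect_equal(sum(lengths(ids)), ncol(cohort$matrix))
  expect_equal(anyDuplicated(unlist(ids)), 0)
  expect_setequal(unlist(ids), sampleIds(cohort$matrix))
  for (v in views) {
    expect_true(all(planted %in% geneIds(v)))
    expect_equal(length(geneIds(v)), round(0.6 * 100))
  }
  # single identity view is the input itself
  one <- makePlatformViews(cohort$matrix, nViews = 1, geneKeepFraction = 1,
                           family = "identity", seed = 2,
                           plantedGenes = planted)
  expect_equal(exprsValues(one[[1]])[, sort(sampleIds(cohort$matrix))],
               exprsValues(cohort$matrix)[, sort(sampleIds(cohort$matrix))])
  expect_error(makePlatformViews(cohort$matrix, nViews = 2,
                                 geneKeepFraction = 0.05, seed = 2,
                                 plantedGenes = planted),
               "too small")
})

test_that("hub mode shares one low gene and still yields reversal pairs", {
  cohort <- simulateCohort(simulationConfig(n_genes = 80, n_planted = 4,
                                            fidelity_pos = 1,
                                            fidelity_neg = 1,
                                            tie_fraction = 0,
                                            hub_mode = TRUE, seed = 8))
  pp <- cohort$truth$planted_pairs
  expect_equal(length(unique(pp$gene_a)), 1L)
  fit <- discoverMarkerPanel(cohort$matrix, cohort$annotation)
  got <- paste(fit$reversal_pairs$gene_a, fit$reversal_pairs$gene_b)
  expect_true(all(paste(pp$gene_a, pp$gene_b) %in% got))
})

test_that("cohort truth round-trips through TSV", {
  cohort <- smallCohort(3)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCohortTruth(cohort$truth$planted_pairs, f)
  expect_identical(readCohortTruth(f), cohort$truth$planted_pairs)
})
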