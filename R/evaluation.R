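#' Confusion counts of classifications against annotated truth
#'
#' Cancer and cancer-adjacent samples count as positives; normal, adenoma and
#' IBD samples as negatives (`binary_label` of the annotation). A prediction
#' without a truth label is a hard error naming the sample.
#'
#' @param predictions `data.frame` from [classifyMatrix()] (columns
#'   `sample_id`, `call`).
#' @param truth annotation `data.frame` (see [makeSampleAnnotation()]).
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(predictions, truth) {
  if (!nrow(predictions))
    stop("no predictions to evaluate")
  idx <- match(predictions$sample_id, truth$sample_id)
  if (anyNA(idx))
    stop("missing truth label for sample: ",
         predictions$sample_id[which(is.na(idx))[1L]])
  pos <- truth$binary_label[idx] == "positive"
  called <- predictions$call == "cancer"
  new("ConfusionCounts",
      TP = sum(called & pos), FP = sum(called & !pos),
      TN = sum(!called & !pos), FN = sum(!called & pos))
}

#' Sensitivity, specificity, geometric mean and accuracy
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `gmean = sqrt(sensitivity * specificity)`,
#' `accuracy = (TP + TN) / total`. A ratio whose denominator is zero (no
#' positives, or no negatives, among the evaluated samples) is undefined and
#' reported as `NA`, never silently as zero; `gmean` is `NA` whenever either
#' input rate is.
#'
#' @param counts a [ConfusionCounts-class].
#' @return named list with `sensitivity`, `specificity`, `gmean`,
#'   `accuracy`.
#' @export
sensitivitySpecificity <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  npos <- counts@TP + counts@FN
  nneg <- counts@TN + counts@FP
  sens <- if (npos > 0L) counts@TP / npos else NA_real_
  spec <- if (nneg > 0L) counts@TN / nneg else NA_real_
  gmean <- if (is.na(sens) || is.na(spec)) NA_real_ else sqrt(sens * spec)
  total <- npos + nneg
  acc <- if (total > 0L) (counts@TP + counts@TN) / total else NA_real_
  list(sensitivity = sens, specificity = spec, gmean = gmean, accuracy = acc)
}

#' Accuracy stratified by a clinical annotation field
#'
#' Per-stratum sample count and fraction of correct calls, "correct" meaning
#' the call agrees with the sample's `binary_label` (cancer call for a
#' positive sample, non-cancer call for a negative one). Samples with no
#' value for the stratum field are gathered in an `"unknown"` row; empty
#' strata do not appear.
#'
#' @param predictions `data.frame` from [classifyMatrix()].
#' @param truth annotation `data.frame` (see [makeSampleAnnotation()]).
#' @param stratumField one of `"stage"`, `"msi_status"`, `"primary_site"`,
#'   `"class_label"`.
#' @return `data.frame` with columns `stratum`, `n`, `accuracy`.
#' @export
stratifiedAccuracy <- function(predictions, truth,
                               stratumField = c("stage", "msi_status",
                                                "primary_site",
                                                "class_label")) {
  stratumField <- match.arg(stratumField)
  idx <- match(predictions$sample_id, truth$sample_id)
  if (anyNA(idx))
    stop("missing truth label for sample: ",
         predictions$sample_id[which(is.na(idx))[1L]])
  stratum <- as.character(truth[[stratumField]][idx])
  stratum[is.na(stratum)] <- "unknown"
  correct <- (predictions$call == "cancer") ==
    (truth$binary_label[idx] == "positive")
  agg <- tapply(correct, stratum, function(z) c(n = length(z),
                                                accuracy = mean(z)))
  out <- data.frame(stratum = names(agg),
                    n = vapply(agg, `[[`, numeric(1L), "n"),
                    accuracy = vapply(agg, `[[`, numeric(1L), "accuracy"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$stratum), , drop = FALSE]
}

#' Fisher's exact test for a reversal pair
#'
#' Builds the 2x2 table of class (positive / negative, rows) against REO
#' direction (`a < b` / `a > b`, columns), excluding tied samples from the
#' table but reporting their count, and returns the two-sided Fisher exact
#' p-value (the sum of hypergeometric probabilities not exceeding the
#' observed table's). When every sample is tied the table is empty, its
#' margins are zero and the p-value is undefined (`NA`).
#'
#' @param x a [ReoMatrix-class].
#' @param annotation annotation `data.frame` covering the samples of `x`.
#' @param geneA,geneB the gene pair to test.
#' @return list with `p_value`, `table` (the 2x2 contingency table) and
#'   `n_ties_excluded`.
#' @export
reversalFisherTest <- function(x, annotation, geneA, geneB) {
  stopifnot(is(x, "ReoMatrix"))
  for (g in c(geneA, geneB))
    if (!g %in% geneIds(x)) stop("unknown gene: ", g)
  idx <- match(sampleIds(x), annotation$sample_id)
  if (anyNA(idx))
    stop("missing annotation for sample: ",
         sampleIds(x)[which(is.na(idx))[1L]])
  pos <- annotation$binary_label[idx] == "positive"
  v <- exprsValues(x)
  a <- v[geneA, ]
  b <- v[geneB, ]
  tie <- a == b
  tab <- matrix(c(sum(pos & !tie & a < b), sum(pos & !tie & a > b),
                  sum(!pos & !tie & a < b), sum(!pos & !tie & a > b)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(class = c("positive", "negative"),
                                reo = c("a_lt_b", "a_gt_b")))
  p <- if (sum(tab) == 0L) NA_real_ else stats::fisher.test(tab)$p.value
  list(p_value = p, table = tab, n_ties_excluded = sum(tie))
}
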