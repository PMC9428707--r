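#' Count cancer-direction votes for one sample
#'
#' A panel pair votes cancer only when the sample shows the strict cancer
#' ordering `expression(gene_low) < expression(gene_high)`; ties and reversed
#' orderings cast no vote. Votes depend only on the ordering of values, so
#' any strictly increasing transform of the sample leaves them unchanged.
#'
#' @param sampleValues named numeric vector of one sample's expression
#'   values, covering every panel gene.
#' @param panel a [MarkerPanel-class].
#' @return integer vote count in `[0, k]`.
#' @export
countCancerVotes <- function(sampleValues, panel) {
  stopifnot(is(panel, "MarkerPanel"))
  p <- panelPairs(panel)
  missing <- setdiff(unique(c(p$gene_low, p$gene_high)), names(sampleValues))
  if (length(missing))
    stop("panel gene missing from sample: ", missing[1L])
  sum(sampleValues[p$gene_low] < sampleValues[p$gene_high])
}

#' Classify one sample with the half-voting rule
#'
#' The sample is called cancer when at least half of the panel pairs —
#' `ceiling(k/2)` votes — show the cancer-direction ordering (3 of 6 for the
#' published six-pair colorectal panel, 2 of 3, 1 of 1); otherwise it is
#' called non-cancer.
#'
#' @inheritParams countCancerVotes
#' @param sample_id identifier recorded in the result.
#' @return one-row `data.frame` with columns `sample_id`, `votes`, `k`,
#'   `call` (`"cancer"` or `"non_cancer"`).
#' @export
classifySample <- function(sampleValues, panel, sample_id = "sample") {
  votes <- countCancerVotes(sampleValues, panel)
  k <- panelSize(panel)
  data.frame(sample_id = sample_id,
             votes = as.integer(votes),
             k = as.integer(k),
             call = if (votes >= voteThreshold(panel)) "cancer"
                    else "non_cancer",
             stringsAsFactors = FALSE)
}

#' Classify every sample of an expression matrix
#'
#' Column-wise [classifySample()]; sample order is preserved. All panel
#' genes must be present in the matrix.
#'
#' @param x a [ReoMatrix-class].
#' @param panel a [MarkerPanel-class].
#' @return `data.frame` with one row per sample and columns `sample_id`,
#'   `votes`, `k`, `call`.
#' @examples
#' panel <- markerPanel("gA", "gB")
#' m <- matrix(c(1, 2, 5, 3), nrow = 2,
#'             dimnames = list(c("gA", "gB"), c("s1", "s2")))
#' classifyMatrix(ReoMatrix(m), panel)
#' @export
classifyMatrix <- function(x, panel) {
  stopifnot(is(x, "ReoMatrix"), is(panel, "MarkerPanel"))
  p <- panelPairs(panel)
  v <- exprsValues(x)
  missing <- setdiff(unique(c(p$gene_low, p$gene_high)), rownames(v))
  if (length(missing))
    stop("panel gene missing from matrix: ", missing[1L])
  votes <- colSums(v[p$gene_low, , drop = FALSE] <
                   v[p$gene_high, , drop = FALSE])
  k <- panelSize(panel)
  data.frame(sample_id = sampleIds(x),
             votes = as.integer(votes),
             k = as.integer(k),
             call = unname(ifelse(votes >= voteThreshold(panel),
                                  "cancer", "non_cancer")),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Convert qPCR cycle-threshold values to a relative expression scale
#'
#' Ct-like values decrease with abundance, so they must not be classified
#' directly. This helper maps them onto an expression-like scale with
#' `2^-(ct - reference)` (the usual delta-Ct transform); with the default
#' reference of 0 it is plain `2^-ct`. The transform is strictly decreasing
#' in Ct, hence strictly increasing in abundance, which is all the
#' rank-based classifier needs. Callers must state the assay scale of their
#' data themselves; nothing in the package guesses it.
#'
#' @param ct numeric vector or matrix of cycle-threshold values.
#' @param reference reference Ct (e.g. of a housekeeping control), recycled.
#' @return values on a relative expression scale.
#' @export
ctToRelativeExpression <- function(ct, reference = 0) {
  2^(-(ct - reference))
}
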