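#' Full marker-discovery pipeline
#'
#' Convenience wrapper chaining the discovery stages on one or several
#' training datasets (e.g. platform views with partially overlapping gene
#' universes):
#' \enumerate{
#'   \item restrict all matrices to their common gene universe
#'     ([intersectGeneUniverse()]);
#'   \item detect consistent pairs per dataset and class
#'     ([detectConsistentPairs()]);
#'   \item intersect them across datasets within each class
#'     ([intersectConsistentSets()]);
#'   \item detect reversal pairs between the cancer and non-cancer sets
#'     ([detectReversalPairs()]);
#'   \item score them with the reversal degree over the pooled training
#'     samples of each class ([scoreReversalPairs()]) and rank
#'     ([rankByReversalDegree()]);
#'   \item fix the panel size by forward selection with the half-voting
#'     rule ([forwardSelectPanel()]).
#' }
#'
#' Pooling versus intersecting is the caller's choice: pass pooled samples as
#' one matrix, or several matrices to intersect their pair sets.
#'
#' @param matrices a [ReoMatrix-class] or a list of them (each with its own
#'   disjoint samples).
#' @param annotation annotation `data.frame` covering all samples (see
#'   [makeSampleAnnotation()]).
#' @param threshold consistency threshold, default 0.70.
#' @return list with `panel` ([MarkerPanel-class]), `per_k` (forward
#'   selection diagnostics), `reversal_pairs` (scored, ranked
#'   `data.frame`), `consistent_cancer` and `consistent_noncancer`
#'   (intersected [ConsistentPairSet-class]s) and `train` (the pooled
#'   training [ReoMatrix-class] over the common gene universe).
#' @examples
#' cohort <- simulateCohort(simulationConfig(n_genes = 60, n_planted = 4,
#'                                           fidelity_pos = 1,
#'                                           fidelity_neg = 1, seed = 3))
#' fit <- discoverMarkerPanel(cohort$matrix, cohort$annotation)
#' fit$panel
#' @export
discoverMarkerPanel <- function(matrices, annotation, threshold = 0.70) {
  if (is(matrices, "ReoMatrix")) matrices <- list(matrices)
  stopifnot(all(vapply(matrices, is, logical(1L), "ReoMatrix")))
  if (length(matrices) > 1L)
    matrices <- intersectGeneUniverse(matrices)
  classSamples <- function(m, label) {
    ids <- sampleIds(m)
    idx <- match(ids, annotation$sample_id)
    if (anyNA(idx))
      stop("missing annotation for sample: ", ids[which(is.na(idx))[1L]])
    ids[annotation$binary_label[idx] == label]
  }
  setsFor <- function(label) {
    sets <- lapply(matrices, function(m)
      detectConsistentPairs(m, threshold = threshold,
                            samples = classSamples(m, label)))
    if (length(sets) == 1L) sets[[1L]] else intersectConsistentSets(sets)
  }
  cons_cancer <- setsFor("positive")
  cons_noncancer <- setsFor("negative")
  rev <- detectReversalPairs(cons_cancer, cons_noncancer)
  train <- if (length(matrices) == 1L) matrices[[1L]] else {
    vals <- do.call(cbind, lapply(matrices, exprsValues))
    ReoMatrix(vals, platform = "pooled")
  }
  ranks_cancer <- withinSampleRanks(train,
                                    samples = classSamples(train, "positive"))
  ranks_noncancer <- withinSampleRanks(train,
                                       samples = classSamples(train,
                                                              "negative"))
  rev <- rankByReversalDegree(
    scoreReversalPairs(rev, ranks_cancer, ranks_noncancer))
  sel <- forwardSelectPanel(rev, train, annotation)
  list(panel = sel$panel, per_k = sel$per_k, reversal_pairs = rev,
       consistent_cancer = cons_cancer,
       consistent_noncancer = cons_noncancer,
       train = train)
}
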