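#' Gene identifiers of an expression container
#' @param x a [ReoMatrix-class].
#' @return character vector of gene ids (row names).
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname geneIds
#' @export
setMethod("geneIds", "ReoMatrix", function(x) rownames(x))

#' Sample identifiers of an expression container
#' @param x a [ReoMatrix-class].
#' @return character vector of sample ids (column names).
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "ReoMatrix", function(x) colnames(x))

#' Platform tag of an expression container
#' @param x a [ReoMatrix-class].
#' @return single character platform tag.
#' @export
setGeneric("platformTag", function(x) standardGeneric("platformTag"))

#' @rdname platformTag
#' @export
setMethod("platformTag", "ReoMatrix",
          function(x) S4Vectors::metadata(x)$platform)

#' Expression values of a ReoMatrix
#'
#' Convenience accessor for `assay(x, "exprs")`.
#' @param x a [ReoMatrix-class].
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
setGeneric("exprsValues", function(x) standardGeneric("exprsValues"))

#' @rdname exprsValues
#' @export
setMethod("exprsValues", "ReoMatrix",
          function(x) SummarizedExperiment::assay(x, "exprs"))

#' Pair table of a consistent-pair set
#' @param x a [ConsistentPairSet-class].
#' @return `data.frame` with columns `gene_a`, `gene_b`, `direction`,
#'   `frequency`.
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname pairTable
#' @export
setMethod("pairTable", "ConsistentPairSet", function(x) x@pairs)

#' Number of pairs in a pair set or panel
#' @param x a [ConsistentPairSet-class] or [MarkerPanel-class].
#' @return integer count.
#' @export
setGeneric("pairCount", function(x) standardGeneric("pairCount"))

#' @rdname pairCount
#' @export
setMethod("pairCount", "ConsistentPairSet", function(x) nrow(x@pairs))

#' @rdname pairCount
#' @export
setMethod("pairCount", "MarkerPanel", function(x) nrow(x@pairs))

#' Consistency threshold of a pair set
#' @param x a [ConsistentPairSet-class].
#' @return numeric threshold in `[0.5, 1)`.
#' @export
setGeneric("consistencyThreshold",
           function(x) standardGeneric("consistencyThreshold"))

#' @rdname consistencyThreshold
#' @export
setMethod("consistencyThreshold", "ConsistentPairSet",
          function(x) x@threshold)

#' Pairs of a marker panel
#' @param x a [MarkerPanel-class].
#' @return `data.frame` with columns `gene_low`, `gene_high`, in selection
#'   order.
#' @export
setGeneric("panelPairs", function(x) standardGeneric("panelPairs"))

#' @rdname panelPairs
#' @export
setMethod("panelPairs", "MarkerPanel", function(x) x@pairs)

#' Panel size k
#' @param x a [MarkerPanel-class].
#' @return integer number of pairs.
#' @export
setGeneric("panelSize", function(x) standardGeneric("panelSize"))

#' @rdname panelSize
#' @export
setMethod("panelSize", "MarkerPanel", function(x) nrow(x@pairs))

#' Half-voting threshold of a panel
#'
#' Minimal number of cancer-direction votes that yields a cancer call:
#' `ceiling(k/2)` for a panel of `k` pairs (3 of 6, 2 of 3, 1 of 1).
#' @param x a [MarkerPanel-class].
#' @return integer vote threshold.
#' @export
setGeneric("voteThreshold", function(x) standardGeneric("voteThreshold"))

#' @rdname voteThreshold
#' @export
setMethod("voteThreshold", "MarkerPanel",
          function(x) as.integer(ceiling(nrow(x@pairs) / 2)))

setMethod("show", "ReoMatrix", function(object) {
  cat("ReoMatrix:", nrow(object), "genes x", ncol(object), "samples,",
      "platform:", platformTag(object), "\n")
  callNextMethod()
})

setMethod("show", "ConsistentPairSet", function(object) {
  cat("ConsistentPairSet:", nrow(object@pairs),
      "pairs consistent at frequency >", object@threshold, "\n")
  if (nrow(object@pairs))
    print(utils::head(object@pairs, 5L))
  if (nrow(object@pairs) > 5L)
    cat("...", nrow(object@pairs) - 5L, "more pairs\n")
})

setMethod("show", "MarkerPanel", function(object) {
  k <- nrow(object@pairs)
  cat("MarkerPanel: k =", k, "pairs, cancer call at >=",
      voteThreshold(object), "votes\n")
  cat("provenance:", object@provenance, "\n")
  print(object@pairs)
})

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts: TP =", object@TP, "FP =", object@FP,
      "TN =", object@TN, "FN =", object@FN, "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@n_genes, "genes,", object@n_planted,
      "planted pairs", if (object@hub_mode) "(hub mode)" else "", "\n")
  cat("  samples:", object@n_pos, "positive /", object@n_neg, "negative;",
      "fidelity:", object@fidelity_pos, "/", object@fidelity_neg, "\n")
  cat("  log-normal baseline N(", object@base_log_mean, ",",
      object@base_log_sd, "), noise sd", object@noise_sd,
      ", planted noise sd", object@planted_noise_sd, "\n")
  cat("  tie fraction", object@tie_fraction, ", seed", object@seed, "\n")
})
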