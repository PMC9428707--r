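#' @import methods
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Expression matrix container for rank-based (REO) analysis
#'
#' `ReoMatrix` extends [SummarizedExperiment::SummarizedExperiment] with the
#' constraints the relative-expression-ordering machinery relies on: a single
#' assay named `"exprs"` holding finite, non-negative expression values
#' (FPKM-like quantities, processed microarray intensities, or qPCR-derived
#' relative abundances), unique gene (row) and sample (column) identifiers,
#' and a free-text platform tag in `metadata(x)$platform`.
#'
#' All downstream pair statistics depend only on within-sample orderings of
#' the values, so any strictly increasing per-sample transform of the assay
#' (log, scaling, power) leaves every result of this package unchanged.
#'
#' @slot .Data inherited `SummarizedExperiment` internals.
#'
#' @seealso [ReoMatrix()] for construction, [readExpressionMatrix()] for the
#'   TSV reader.
#' @export
setClass("ReoMatrix", contains = "SummarizedExperiment")

.validReoMatrix <- function(object) {
  msg <- character()
  if (!("exprs" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    v <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(v))
      msg <- c(msg, "expression values must be numeric")
    else if (any(!is.finite(v)))
      msg <- c(msg, "expression values must all be finite")
    else if (any(v < 0))
      msg <- c(msg, "expression values must all be >= 0")
  }
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "gene (row) and sample (column) names are required")
  else {
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, paste0("duplicate gene id: ",
                           rownames(object)[duplicated(rownames(object))][1L]))
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, paste0("duplicate sample id: ",
                           colnames(object)[duplicated(colnames(object))][1L]))
  }
  p <- S4Vectors::metadata(object)$platform
  if (!is.character(p) || length(p) != 1L)
    msg <- c(msg, "metadata(x)$platform must be a single character string")
  if (length(msg)) msg else TRUE
}

setValidity("ReoMatrix", .validReoMatrix)

#' Construct a ReoMatrix
#'
#' @param values numeric matrix of non-negative, finite expression values,
#'   genes in rows, samples in columns; `dimnames` are required and must be
#'   unique.
#' @param platform single character tag recording the measurement platform
#'   (e.g. `"microarray"`, `"rnaseq"`, `"qpcr"`, `"simulated"`).
#' @param colData optional `data.frame` (or `DataFrame`) of per-sample
#'   annotation, one row per column of `values`.
#'
#' @return a validated [ReoMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 5, 3, 2, 6, 4), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' x <- ReoMatrix(m, platform = "rnaseq")
#' geneIds(x)
#' @export
ReoMatrix <- function(values, platform = "unspecified", colData = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene row names and sample column names")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate gene id: ", dup[1L])
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicate sample id: ", dup[1L])
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid expression value at gene '%s', sample '%s'",
                 rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]]))
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = colData,
    metadata = list(platform = platform)
  )
  new("ReoMatrix", se)
}

#' Group-consistent gene-pair set
#'
#' A set of unordered gene pairs whose within-sample relative ordering holds
#' in strictly more than `threshold` of the samples of one group. Pairs are
#' stored canonically: `gene_a` lexicographically before `gene_b`, with
#' `direction` one of `"a_lt_b"` (expression of `gene_a` below `gene_b`) or
#' `"a_gt_b"`, and `frequency` the fraction of group samples showing that
#' ordering.
#'
#' @slot pairs `data.frame` with columns `gene_a`, `gene_b`, `direction`,
#'   `frequency`.
#' @slot threshold numeric consistency threshold in `[0.5, 1)` used at
#'   construction; every stored frequency is strictly greater than it.
#'
#' @seealso [detectConsistentPairs()], [intersectConsistentSets()].
#' @export
setClass("ConsistentPairSet",
         representation(pairs = "data.frame", threshold = "numeric"))

.validConsistentPairSet <- function(object) {
  msg <- character()
  p <- object@pairs
  need <- c("gene_a", "gene_b", "direction", "frequency")
  if (!all(need %in% names(p)))
    return(paste("pairs must have columns", paste(need, collapse = ", ")))
  if (length(object@threshold) != 1L || object@threshold < 0.5 ||
      object@threshold >= 1)
    msg <- c(msg, "threshold must be a single value in [0.5, 1)")
  if (nrow(p)) {
    if (any(p$gene_a >= p$gene_b))
      msg <- c(msg, "gene_a must be lexicographically before gene_b")
    if (!all(p$direction %in% c("a_lt_b", "a_gt_b")))
      msg <- c(msg, "direction must be 'a_lt_b' or 'a_gt_b'")
    if (anyDuplicated(paste(p$gene_a, p$gene_b)))
      msg <- c(msg, "duplicate unordered pair")
    if (length(object@threshold) == 1L &&
        any(p$frequency <= object@threshold | p$frequency > 1))
      msg <- c(msg, "frequencies must lie in (threshold, 1]")
  }
  if (length(msg)) msg else TRUE
}

setValidity("ConsistentPairSet", .validConsistentPairSet)

#' Construct a ConsistentPairSet
#'
#' Usually produced by [detectConsistentPairs()]; the constructor is exported
#' for reading pair sets back from disk and for tests.
#'
#' @param pairs `data.frame` with columns `gene_a`, `gene_b`, `direction`,
#'   `frequency` (canonical orientation, see [ConsistentPairSet-class]).
#' @param threshold consistency threshold the set was built at.
#' @return a validated `ConsistentPairSet`.
#' @export
ConsistentPairSet <- function(pairs, threshold = 0.70) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  new("ConsistentPairSet", pairs = pairs, threshold = threshold)
}

#' Diagnostic gene-pair marker panel
#'
#' An ordered list of gene pairs oriented so that, in a disease (positive)
#' sample, `gene_low` is expected to have strictly lower expression than
#' `gene_high`. A sample is called positive when at least half of the pairs —
#' `ceiling(k/2)` votes for a panel of `k` pairs — show that ordering.
#'
#' @slot pairs `data.frame` with columns `gene_low`, `gene_high`, in
#'   selection order.
#' @slot provenance free-text description of how the panel was derived.
#'
#' @seealso [markerPanel()], [forwardSelectPanel()], [classifyMatrix()],
#'   [readMarkerPanel()].
#' @export
setClass("MarkerPanel",
         representation(pairs = "data.frame", provenance = "character"))

.validMarkerPanel <- function(object) {
  p <- object@pairs
  msg <- character()
  if (!all(c("gene_low", "gene_high") %in% names(p)))
    return("pairs must have columns gene_low, gene_high")
  if (nrow(p) < 1L)
    msg <- c(msg, "a panel must contain at least one pair")
  if (any(p$gene_low == p$gene_high))
    msg <- c(msg, "gene_low and gene_high must differ")
  key <- paste(pmin(p$gene_low, p$gene_high), pmax(p$gene_low, p$gene_high))
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate unordered pair in panel")
  if (length(msg)) msg else TRUE
}

setValidity("MarkerPanel", .validMarkerPanel)

#' Construct a MarkerPanel
#'
#' @param gene_low,gene_high character vectors of equal length: the genes
#'   expected low and high, respectively, in positive (disease) samples.
#' @param provenance free-text origin of the panel.
#' @return a validated [MarkerPanel-class].
#' @examples
#' p <- markerPanel(c("gA1", "gA2", "gA3"), c("gB1", "gB2", "gB3"))
#' panelSize(p)
#' voteThreshold(p)
#' @export
markerPanel <- function(gene_low, gene_high, provenance = "manual") {
  new("MarkerPanel",
      pairs = data.frame(gene_low = as.character(gene_low),
                         gene_high = as.character(gene_high),
                         stringsAsFactors = FALSE),
      provenance = provenance)
}

#' Confusion counts for a binary cancer / non-cancer evaluation
#'
#' @slot TP,FP,TN,FN non-negative integer counts of true-positive,
#'   false-positive, true-negative and false-negative samples.
#'
#' @seealso [confusionCounts()], [sensitivitySpecificity()].
#' @export
setClass("ConfusionCounts",
         representation(TP = "integer", FP = "integer",
                        TN = "integer", FN = "integer"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@TP, object@FP, object@TN, object@FN)
  if (length(v) != 4L || any(is.na(v)) || any(v < 0L))
    "TP, FP, TN, FN must be single non-negative integers"
  else TRUE
})

#' Simulation configuration for synthetic REO cohorts
#'
#' Parameters of the two-class synthetic cohort generator. Expression values
#' are log-normal: background gene `g` draws
#' `exp(mu_g + N(0, noise_sd))` with `mu_g ~ N(base_log_mean, base_log_sd)`.
#' Each planted reversal pair shares one baseline mean for both of its genes
#' (pair baselines evenly spaced `planted_spacing` apart on the log scale)
#' and a tighter dispersion `planted_noise_sd`; its class-specific ordering
#' (`gene_a < gene_b` in positive samples, the reverse in negative samples)
#' is imposed by conditionally swapping the two sampled values, so the pair's
#' value set — and hence each gene's marginal distribution — is preserved
#' while the ordering holds with probability exactly `fidelity_pos`
#' (`fidelity_neg`) per sample.
#'
#' @slot n_genes total number of genes.
#' @slot n_planted number of planted reversal pairs (disjoint genes unless
#'   `hub_mode`).
#' @slot n_pos,n_neg samples per class.
#' @slot fidelity_pos,fidelity_neg per-sample probability, in `(0.5, 1]`,
#'   that a planted pair shows its class-specific ordering.
#' @slot base_log_mean,base_log_sd baseline per-gene mean distribution on the
#'   natural-log scale.
#' @slot noise_sd per-observation log-scale noise for background genes.
#' @slot planted_noise_sd per-observation log-scale noise for planted genes.
#' @slot planted_spacing log-scale gap between consecutive planted-pair
#'   baseline means.
#' @slot tie_fraction probability any value is zeroed, to exercise tie
#'   handling (real FPKM matrices are zero-inflated).
#' @slot hub_mode if `TRUE`, all planted pairs share one low gene.
#' @slot seed integer RNG seed; all output is reproducible from the config.
#'
#' @seealso [simulationConfig()], [simulateCohort()].
#' @export
setClass("SimulationConfig",
         representation(n_genes = "integer", n_planted = "integer",
                        n_pos = "integer", n_neg = "integer",
                        fidelity_pos = "numeric", fidelity_neg = "numeric",
                        base_log_mean = "numeric", base_log_sd = "numeric",
                        noise_sd = "numeric", planted_noise_sd = "numeric",
                        planted_spacing = "numeric", tie_fraction = "numeric",
                        hub_mode = "logical", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  n_planted_genes <- if (object@hub_mode) object@n_planted + 1L
                     else 2L * object@n_planted
  if (n_planted_genes > object@n_genes)
    msg <- c(msg, "planted pairs require more genes than n_genes provides")
  if (object@n_planted < 0L) msg <- c(msg, "n_planted must be >= 0")
  if (object@n_pos < 1L || object@n_neg < 1L)
    msg <- c(msg, "need at least one sample per class")
  for (f in c(object@fidelity_pos, object@fidelity_neg))
    if (f <= 0.5 || f > 1)
      msg <- c(msg, "fidelities must lie in (0.5, 1]")
  if (object@base_log_sd < 0 || object@noise_sd < 0 ||
      object@planted_noise_sd < 0 || object@planted_spacing < 0)
    msg <- c(msg, "scale parameters must be >= 0")
  if (object@tie_fraction < 0 || object@tie_fraction >= 1)
    msg <- c(msg, "tie_fraction must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults describe the reference desk-scale cohort used throughout the
#' package's validation: 200 genes of which 10 pairs carry a planted
#' reversal, 30 samples per class, per-sample ordering fidelity 0.9 in both
#' classes, log-normal background (`exp(N(2, 1))` baselines, noise sd 0.5),
#' tight planted-pair dispersion (0.1) with pair baselines 1.5 log-units
#' apart, and 2% zero-inflation.
#'
#' @param n_genes,n_planted,n_pos,n_neg,fidelity_pos,fidelity_neg see
#'   [SimulationConfig-class].
#' @param base_log_mean,base_log_sd,noise_sd,planted_noise_sd see
#'   [SimulationConfig-class].
#' @param planted_spacing,tie_fraction,hub_mode,seed see
#'   [SimulationConfig-class].
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(n_genes = 60, n_planted = 4, seed = 7)
#' cohort <- simulateCohort(cfg)
#' cohort$truth$planted_pairs
#' @export
simulationConfig <- function(n_genes = 200L, n_planted = 10L,
                             n_pos = 30L, n_neg = 30L,
                             fidelity_pos = 0.9, fidelity_neg = 0.9,
                             base_log_mean = 2, base_log_sd = 1,
                             noise_sd = 0.5, planted_noise_sd = 0.1,
                             planted_spacing = 1.5, tie_fraction = 0.02,
                             hub_mode = FALSE, seed = 1L) {
  new("SimulationConfig",
      n_genes = as.integer(n_genes), n_planted = as.integer(n_planted),
      n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
      fidelity_pos = fidelity_pos, fidelity_neg = fidelity_neg,
      base_log_mean = base_log_mean, base_log_sd = base_log_sd,
      noise_sd = noise_sd, planted_noise_sd = planted_noise_sd,
      planted_spacing = planted_spacing, tie_fraction = tie_fraction,
      hub_mode = hub_mode, seed = as.integer(seed))
}
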