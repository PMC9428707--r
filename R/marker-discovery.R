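#' Detect reversal pairs between two consistent-pair sets
#'
#' A reversal pair is an unordered gene pair that is consistent in both the
#' cancer and the non-cancer set but with opposite directions — the raw
#' material of the diagnostic panel. Both sets should be built over the same
#' gene universe (see [intersectGeneUniverse()]).
#'
#' @param consistentCancer,consistentNoncancer [ConsistentPairSet-class]
#'   objects for the positive and negative group.
#' @return `data.frame` with columns `gene_a`, `gene_b` (canonical order),
#'   `cancer_direction`, `noncancer_direction`, `freq_cancer`,
#'   `freq_noncancer`. Zero rows when no pair reverses.
#' @seealso [scoreReversalPairs()] to add the reversal degree.
#' @export
detectReversalPairs <- function(consistentCancer, consistentNoncancer) {
  stopifnot(is(consistentCancer, "ConsistentPairSet"),
            is(consistentNoncancer, "ConsistentPairSet"))
  ca <- pairTable(consistentCancer)
  nc <- pairTable(consistentNoncancer)
  m <- merge(ca, nc, by = c("gene_a", "gene_b"),
             suffixes = c("_cancer", "_noncancer"))
  m <- m[m$direction_cancer != m$direction_noncancer, , drop = FALSE]
  out <- data.frame(gene_a = m$gene_a, gene_b = m$gene_b,
                    cancer_direction = m$direction_cancer,
                    noncancer_direction = m$direction_noncancer,
                    freq_cancer = m$frequency_cancer,
                    freq_noncancer = m$frequency_noncancer,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reversal degree of one gene pair
#'
#' For each sample the absolute within-sample rank difference
#' `R_ij = |R_i - R_j|` of the two genes is taken; the reversal degree is the
#' geometric mean of its two group means,
#' `avgR = sqrt(mean(R_ij | cancer) * mean(R_ij | non-cancer))`. Large values
#' mean the two genes sit far apart in the ranking on both sides of the
#' reversal. Being rank-based, it is symmetric in the two genes and invariant
#' to strictly increasing per-sample transforms.
#'
#' @param geneA,geneB gene identifiers.
#' @param ranksCancer,ranksNoncancer rank matrices from
#'   [withinSampleRanks()], computed over a common gene universe, one per
#'   group, each with at least one sample.
#' @return named numeric vector `c(mean_rankdiff_cancer,
#'   mean_rankdiff_noncancer, avg_r)`.
#' @export
reversalDegree <- function(geneA, geneB, ranksCancer, ranksNoncancer) {
  for (g in c(geneA, geneB)) {
    if (!g %in% rownames(ranksCancer)) stop("unknown gene: ", g)
    if (!g %in% rownames(ranksNoncancer)) stop("unknown gene: ", g)
  }
  mc <- mean(abs(ranksCancer[geneA, ] - ranksCancer[geneB, ]))
  mn <- mean(abs(ranksNoncancer[geneA, ] - ranksNoncancer[geneB, ]))
  c(mean_rankdiff_cancer = mc, mean_rankdiff_noncancer = mn,
    avg_r = sqrt(mc * mn))
}

#' Score reversal pairs with the reversal degree
#'
#' Vectorised [reversalDegree()] over a reversal-pair table. The rank
#' matrices are expected over the full common gene universe of the training
#' data, with each class's training samples pooled into one matrix.
#'
#' @param reversalPairs `data.frame` from [detectReversalPairs()].
#' @param ranksCancer,ranksNoncancer rank matrices from
#'   [withinSampleRanks()].
#' @return the input with columns `mean_rankdiff_cancer`,
#'   `mean_rankdiff_noncancer` and `avg_r` appended.
#' @export
scoreReversalPairs <- function(reversalPairs, ranksCancer, ranksNoncancer) {
  if (!nrow(reversalPairs)) {
    reversalPairs$mean_rankdiff_cancer <- numeric()
    reversalPairs$mean_rankdiff_noncancer <- numeric()
    reversalPairs$avg_r <- numeric()
    return(reversalPairs)
  }
  sc <- t(mapply(reversalDegree, reversalPairs$gene_a, reversalPairs$gene_b,
                 MoreArgs = list(ranksCancer = ranksCancer,
                                 ranksNoncancer = ranksNoncancer)))
  reversalPairs$mean_rankdiff_cancer <- sc[, "mean_rankdiff_cancer"]
  reversalPairs$mean_rankdiff_noncancer <- sc[, "mean_rankdiff_noncancer"]
  reversalPairs$avg_r <- sc[, "avg_r"]
  reversalPairs
}

#' Rank reversal pairs by descending reversal degree
#'
#' Ties are broken lexicographically on (`gene_a`, `gene_b`) so the ordering
#' is deterministic.
#'
#' @param reversalPairs scored `data.frame` from [scoreReversalPairs()].
#' @return the same `data.frame`, rows reordered.
#' @export
rankByReversalDegree <- function(reversalPairs) {
  if (!"avg_r" %in% names(reversalPairs))
    stop("pairs must be scored first; see scoreReversalPairs()")
  o <- order(-reversalPairs$avg_r, reversalPairs$gene_a, reversalPairs$gene_b)
  out <- reversalPairs[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Panel orientation of reversal pairs
#'
#' Re-orients each reversal pair into the panel convention: the gene expected
#' LOW in cancer first. A pair whose cancer direction is `a_lt_b` keeps
#' (`gene_a`, `gene_b`); `a_gt_b` swaps them.
#'
#' @param reversalPairs `data.frame` with `gene_a`, `gene_b`,
#'   `cancer_direction`.
#' @return `data.frame` with columns `gene_low`, `gene_high`.
#' @keywords internal
.panelOrientation <- function(reversalPairs) {
  lt <- reversalPairs$cancer_direction == "a_lt_b"
  data.frame(
    gene_low = ifelse(lt, reversalPairs$gene_a, reversalPairs$gene_b),
    gene_high = ifelse(lt, reversalPairs$gene_b, reversalPairs$gene_a),
    stringsAsFactors = FALSE)
}

#' Forward selection of the marker panel size
#'
#' Scans panel sizes `k = 1..m` over the reversal pairs (already ranked by
#' descending reversal degree), classifies every training sample with the
#' top-`k` panel under the half-voting rule, and returns the panel whose
#' geometric mean of sensitivity and specificity on the training data is
#' maximal. When several `k` achieve the maximum, the smallest is chosen
#' (the cheaper assay).
#'
#' @param rankedPairs scored, ranked reversal pairs
#'   ([rankByReversalDegree()]).
#' @param train a [ReoMatrix-class] of training samples containing every
#'   pair gene.
#' @param annotation annotation `data.frame` (see [makeSampleAnnotation()])
#'   covering the training samples, with at least one positive and one
#'   negative sample.
#' @return list with elements `panel` (a [MarkerPanel-class] of the selected
#'   top-`k` pairs) and `per_k` (`data.frame` with columns `k`,
#'   `sensitivity`, `specificity`, `gmean` for every candidate size).
#' @export
forwardSelectPanel <- function(rankedPairs, train, annotation) {
  stopifnot(is(train, "ReoMatrix"))
  m <- nrow(rankedPairs)
  if (m < 1L)
    stop("no reversal pairs to select from")
  ann <- annotation[match(sampleIds(train), annotation$sample_id), ,
                    drop = FALSE]
  if (any(is.na(ann$sample_id)))
    stop("missing annotation for sample: ",
         sampleIds(train)[which(is.na(ann$sample_id))[1L]])
  pos <- ann$binary_label == "positive"
  if (!any(pos) || all(pos))
    stop("training data must contain positive and negative samples")
  ori <- .panelOrientation(rankedPairs)
  v <- exprsValues(train)
  missing <- setdiff(unique(c(ori$gene_low, ori$gene_high)), rownames(v))
  if (length(missing))
    stop("pair gene absent from training matrix: ", missing[1L])
  # votes[p, s]: pair p shows the strict cancer ordering in sample s
  votes <- v[ori$gene_low, , drop = FALSE] < v[ori$gene_high, , drop = FALSE]
  cum <- apply(votes, 2L, cumsum)
  if (m == 1L) cum <- matrix(cum, nrow = 1L)
  per_k <- data.frame(k = seq_len(m), sensitivity = NA_real_,
                      specificity = NA_real_, gmean = NA_real_)
  for (k in seq_len(m)) {
    call_cancer <- cum[k, ] >= ceiling(k / 2)
    sens <- mean(call_cancer[pos])
    spec <- mean(!call_cancer[!pos])
    per_k$sensitivity[k] <- sens
    per_k$specificity[k] <- spec
    per_k$gmean[k] <- sqrt(sens * spec)
  }
  best <- which.max(per_k$gmean)  # first maximum = smallest k
  panel <- markerPanel(ori$gene_low[seq_len(best)],
                       ori$gene_high[seq_len(best)],
                       provenance = sprintf(
                         "forward selection, k = %d of m = %d, training gmean = %.4f",
                         best, m, per_k$gmean[best]))
  list(panel = panel, per_k = per_k)
}

#' Read / write a marker panel as TSV
#'
#' Two-column TSV with header (`gene_low_in_cancer`, `gene_high_in_cancer`),
#' one row per pair, rows in selection order.
#'
#' @param path file path.
#' @param provenance provenance string to attach when reading; defaults to
#'   the path.
#' @return `readMarkerPanel`: a [MarkerPanel-class].
#' @export
readMarkerPanel <- function(path, provenance = path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("gene_low_in_cancer", "gene_high_in_cancer") %in% names(df)))
    stop("panel file needs columns gene_low_in_cancer, gene_high_in_cancer")
  markerPanel(df$gene_low_in_cancer, df$gene_high_in_cancer,
              provenance = provenance)
}

#' @rdname readMarkerPanel
#' @param panel a [MarkerPanel-class] to write.
#' @return `writeMarkerPanel`: `path`, invisibly.
#' @export
writeMarkerPanel <- function(panel, path) {
  stopifnot(is(panel, "MarkerPanel"))
  p <- panelPairs(panel)
  utils::write.table(
    data.frame(gene_low_in_cancer = p$gene_low,
               gene_high_in_cancer = p$gene_high),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a scored reversal-pair table as TSV
#'
#' Columns `gene_a`, `gene_b`, `cancer_direction`, `mean_rankdiff_cancer`,
#' `mean_rankdiff_noncancer`, `avg_r`, rows in the order given (normally the
#' reversal-degree ranking).
#'
#' @param reversalPairs scored `data.frame` ([scoreReversalPairs()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeReversalPairs <- function(reversalPairs, path) {
  cols <- c("gene_a", "gene_b", "cancer_direction", "mean_rankdiff_cancer",
            "mean_rankdiff_noncancer", "avg_r")
  utils::write.table(reversalPairs[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
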