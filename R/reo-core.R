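#' Within-sample ranks of an expression matrix
#'
#' Ranks each sample's values in ascending order (smallest value gets rank
#' 1); ties receive the average of the tied rank positions, which keeps every
#' column sum equal to `n(n+1)/2`. These ranks drive the reversal-degree
#' statistic; the pairwise ordering machinery compares raw values directly.
#'
#' @param x a [ReoMatrix-class] with at least two genes.
#' @param samples optional character vector of sample ids to restrict to.
#' @return numeric matrix of ranks, same dimnames as the (restricted) input.
#' @export
withinSampleRanks <- function(x, samples = NULL) {
  stopifnot(is(x, "ReoMatrix"))
  v <- exprsValues(x)
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  if (nrow(v) < 2L)
    stop("ranking needs at least two genes")
  r <- apply(v, 2L, rank, ties.method = "average")
  dimnames(r) <- dimnames(v)
  r
}

.resolveSamples <- function(x, samples) {
  if (is.null(samples)) return(sampleIds(x))
  missing <- setdiff(samples, sampleIds(x))
  if (length(missing))
    stop("unknown sample: ", missing[1L])
  if (!length(samples))
    stop("empty sample subset")
  samples
}

#' Direction frequencies of one gene pair
#'
#' Fractions of samples in which `geneA`'s expression is strictly below,
#' strictly above, or exactly equal to `geneB`'s. The three fractions sum to
#' one; ties count toward neither direction but stay in the denominator.
#' Because only orderings are inspected, the result is invariant to any
#' strictly increasing per-sample transform of the values.
#'
#' @param x a [ReoMatrix-class].
#' @param geneA,geneB gene identifiers present in `x`.
#' @param samples optional sample subset.
#' @return named numeric vector `c(freq_a_lt_b, freq_a_gt_b, freq_tie)`,
#'   relative to the argument order of the two genes.
#' @export
pairDirectionFrequencies <- function(x, geneA, geneB, samples = NULL) {
  stopifnot(is(x, "ReoMatrix"))
  for (g in c(geneA, geneB))
    if (!g %in% geneIds(x)) stop("unknown gene: ", g)
  samples <- .resolveSamples(x, samples)
  v <- exprsValues(x)
  a <- v[geneA, samples]
  b <- v[geneB, samples]
  c(freq_a_lt_b = mean(a < b),
    freq_a_gt_b = mean(a > b),
    freq_tie = mean(a == b))
}

#' Detect group-consistent gene pairs
#'
#' Enumerates all `n(n-1)/2` unordered gene pairs and keeps those whose
#' within-sample ordering is the same in strictly more than `threshold` of
#' the samples ("more than 70%" at the default). A frequency exactly equal
#' to the threshold does not qualify. Ties within a sample count toward
#' neither direction but remain in the denominator, which is conservative
#' when zero-inflated values produce tied zeros.
#'
#' Pairs are processed one gene row against all later rows at a time, so
#' memory stays linear in `n * s` even though the pair space is quadratic;
#' a 5,000-gene universe (about 12.5 million pairs) fits in ordinary
#' desktop memory.
#'
#' @param x a [ReoMatrix-class].
#' @param threshold consistency threshold, in `[0.5, 1)`; default 0.70.
#'   Below 0.5 both directions could qualify at once.
#' @param samples optional sample subset (e.g. one class of a cohort).
#' @return a [ConsistentPairSet-class], canonically oriented
#'   (`gene_a` lexicographically before `gene_b`).
#' @examples
#' m <- matrix(c(1, 5, 3, 2, 6, 4, 7, 2, 3), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
#' pairTable(detectConsistentPairs(ReoMatrix(m), threshold = 0.6))
#' @export
detectConsistentPairs <- function(x, threshold = 0.70, samples = NULL) {
  stopifnot(is(x, "ReoMatrix"))
  if (length(threshold) != 1L || threshold < 0.5 || threshold >= 1)
    stop("threshold must lie in [0.5, 1)")
  samples <- .resolveSamples(x, samples)
  v <- exprsValues(x)[, samples, drop = FALSE]
  n <- nrow(v)
  s <- ncol(v)
  if (n < 2L)
    stop("pair detection needs at least two genes")
  genes <- rownames(v)
  acc <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    jj <- (i + 1L):n
    blk <- v[jj, , drop = FALSE]
    xi <- matrix(v[i, ], length(jj), s, byrow = TRUE)
    f_lt <- rowSums(blk > xi) / s   # fraction with gene i below gene j
    f_gt <- rowSums(blk < xi) / s
    keep <- f_lt > threshold | f_gt > threshold
    if (!any(keep)) next
    j_keep <- jj[keep]
    lt <- f_lt[keep] > threshold
    acc[[i]] <- data.frame(
      gi = genes[i], gj = genes[j_keep],
      i_lt_j = lt,
      frequency = ifelse(lt, f_lt[keep], f_gt[keep]),
      stringsAsFactors = FALSE)
  }
  acc <- acc[!vapply(acc, is.null, logical(1L))]
  if (!length(acc)) {
    pairs <- data.frame(gene_a = character(), gene_b = character(),
                        direction = character(), frequency = numeric(),
                        stringsAsFactors = FALSE)
    return(ConsistentPairSet(pairs, threshold = threshold))
  }
  raw <- do.call(rbind, acc)
  flip <- raw$gi > raw$gj
  pairs <- data.frame(
    gene_a = ifelse(flip, raw$gj, raw$gi),
    gene_b = ifelse(flip, raw$gi, raw$gj),
    direction = ifelse(xor(raw$i_lt_j, flip), "a_lt_b", "a_gt_b"),
    frequency = raw$frequency,
    stringsAsFactors = FALSE)
  ConsistentPairSet(pairs, threshold = threshold)
}

#' Intersect consistent-pair sets across datasets or platforms
#'
#' A pair survives the intersection only if it is present in every input set
#' with the same direction; its frequency becomes the minimum of the input
#' frequencies (the weakest evidence across datasets). This is how
#' platform-specific pair sets are combined into cross-platform consistent
#' pairs, and how imbalanced datasets are reconciled without pooling.
#'
#' @param sets list of two or more [ConsistentPairSet-class] objects.
#' @return a [ConsistentPairSet-class]; its threshold is the minimum of the
#'   input thresholds. May be empty.
#' @export
intersectConsistentSets <- function(sets) {
  if (length(sets) < 2L)
    stop("need at least two consistent-pair sets")
  stopifnot(all(vapply(sets, is, logical(1L), "ConsistentPairSet")))
  thr <- min(vapply(sets, consistencyThreshold, numeric(1L)))
  cur <- pairTable(sets[[1L]])
  for (k in 2L:length(sets)) {
    nxt <- pairTable(sets[[k]])
    cur <- merge(cur, nxt, by = c("gene_a", "gene_b", "direction"))
    if (!nrow(cur)) break
    cur$frequency <- pmin(cur$frequency.x, cur$frequency.y)
    cur <- cur[, c("gene_a", "gene_b", "direction", "frequency")]
  }
  if (!nrow(cur))
    cur <- data.frame(gene_a = character(), gene_b = character(),
                      direction = character(), frequency = numeric(),
                      stringsAsFactors = FALSE)
  ConsistentPairSet(cur[, c("gene_a", "gene_b", "direction", "frequency")],
                    threshold = thr)
}

#' Read / write consistent-pair sets as TSV
#'
#' Four-column TSV with header (`gene_a`, `gene_b`, `direction`,
#' `frequency`), `gene_a` lexicographically before `gene_b`.
#'
#' @param path file path.
#' @param threshold threshold to attach when reading (the file format does
#'   not carry it); default 0.70.
#' @return `readConsistentPairs`: a [ConsistentPairSet-class].
#' @export
readConsistentPairs <- function(path, threshold = 0.70) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ConsistentPairSet(df, threshold = threshold)
}

#' @rdname readConsistentPairs
#' @param x a [ConsistentPairSet-class] to write.
#' @return `writeConsistentPairs`: `path`, invisibly.
#' @export
writeConsistentPairs <- function(x, path) {
  stopifnot(is(x, "ConsistentPairSet"))
  utils::write.table(pairTable(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
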