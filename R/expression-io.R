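#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects the GEO series-matrix convention: tab-separated text, first column
#' gene (or probe) identifiers, first row sample identifiers, genes in rows.
#' Row and column order are preserved. Duplicated identifiers and negative or
#' non-numeric cells are hard errors that name the offender.
#'
#' @param path path to a tab-separated text file.
#' @param platform platform tag stored on the returned object.
#' @return a [ReoMatrix-class].
#' @seealso [writeExpressionMatrix()]
#' @export
readExpressionMatrix <- function(path, platform = "unspecified") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L)
    stop("expression file needs a gene id column plus at least one sample")
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate gene id: ", dup[1L])
  samples <- colnames(df)[-1L]
  dup <- samples[duplicated(samples)]
  if (length(dup))
    stop("duplicate sample id: ", dup[1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  bad <- which(!is.finite(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "negative or non-numeric value at gene '%s', sample '%s'",
      ids[bad[1L, 1L]], samples[bad[1L, 2L]]))
  dimnames(vals) <- list(ids, samples)
  ReoMatrix(vals, platform = platform)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpressionMatrix()]: first column `gene_id`, one column
#' per sample, tab separators, no quoting. Writing then re-reading is the
#' identity, and re-writing a freshly read matrix reproduces the file
#' byte-for-byte.
#'
#' @param x a [ReoMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
  stopifnot(is(x, "ReoMatrix"))
  df <- data.frame(gene_id = geneIds(x), exprsValues(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a per-sample annotation table
#'
#' TSV with header; required columns `sample_id` and `class_label`
#' (`cancer`, `cancer_adjacent`, `adenoma`, `normal`, `ibd`); optional
#' columns `stage` (I--IV), `msi_status` (MSI/MSS) and `primary_site`
#' (left/right) may be present with empty cells. A derived `binary_label`
#' column is added: `positive` for cancer and cancer-adjacent samples
#' (mis-sampled biopsies near a tumour should still be flagged), `negative`
#' for normal, adenoma and IBD.
#'
#' @param path path to a tab-separated annotation file.
#' @return `data.frame` with `sample_id`, `class_label`, `binary_label` and
#'   any optional stratum columns.
#' @export
readSampleAnnotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  makeSampleAnnotation(df)
}

#' Validate a sample annotation data.frame
#'
#' Checks the invariants of the annotation table (unique sample ids, known
#' class labels) and derives the `binary_label` column; see
#' [readSampleAnnotation()] for the column contract.
#'
#' @param df `data.frame` with at least `sample_id` and `class_label`.
#' @return the validated `data.frame` with `binary_label` added.
#' @export
makeSampleAnnotation <- function(df) {
  if (!all(c("sample_id", "class_label") %in% names(df)))
    stop("annotation needs columns 'sample_id' and 'class_label'")
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicate annotation for sample: ", dup[1L])
  known <- c("cancer", "cancer_adjacent", "adenoma", "normal", "ibd")
  bad <- setdiff(unique(df$class_label), known)
  if (length(bad))
    stop("unknown class_label: ", bad[1L])
  df$binary_label <- ifelse(df$class_label %in% c("cancer", "cancer_adjacent"),
                            "positive", "negative")
  for (col in c("stage", "msi_status", "primary_site"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  df
}

#' Write a sample annotation table as TSV
#' @param annotation `data.frame` as returned by [makeSampleAnnotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSampleAnnotation <- function(annotation, path) {
  cols <- intersect(c("sample_id", "class_label", "binary_label", "stage",
                      "msi_status", "primary_site"), names(annotation))
  utils::write.table(annotation[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Read a probe-to-gene mapping table
#'
#' Two-column TSV with header (`probe_id`, `gene_id`). A probe may map to
#' several genes and a gene may receive several probes; duplicated
#' (probe, gene) rows are collapsed.
#'
#' @param path path to the mapping file.
#' @return `data.frame` with columns `probe_id`, `gene_id`.
#' @export
readProbeGeneMap <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("probe_id", "gene_id") %in% names(df)))
    stop("probe map needs columns 'probe_id' and 'gene_id'")
  unique(df[, c("probe_id", "gene_id")])
}

#' Read a gene-length table
#'
#' Two-column TSV with header (`gene_id`, `length`), lengths in base pairs.
#'
#' @param path path to the length file.
#' @return named numeric vector of lengths, names = gene ids.
#' @export
readGeneLengths <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length") %in% names(df)))
    stop("gene length table needs columns 'gene_id' and 'length'")
  stats::setNames(as.numeric(df$length), df$gene_id)
}

#' Collapse a probe-level matrix to gene level
#'
#' Probes mapping to more than one gene are discarded before any averaging;
#' when several surviving probes map to the same gene, the gene's expression
#' is their arithmetic mean, per sample. Probes absent from the map are
#' dropped with a warning giving their count (the mapping table defines the
#' annotated universe).
#'
#' @param probeMatrix a [ReoMatrix-class] keyed by probe ids.
#' @param map `data.frame` with columns `probe_id`, `gene_id` (see
#'   [readProbeGeneMap()]).
#' @return a [ReoMatrix-class] keyed by gene ids (sorted), same samples.
#' @export
collapseProbes <- function(probeMatrix, map) {
  stopifnot(is(probeMatrix, "ReoMatrix"))
  map <- unique(map[, c("probe_id", "gene_id")])
  probes <- geneIds(probeMatrix)
  unmapped <- setdiff(probes, map$probe_id)
  if (length(unmapped))
    warning(length(unmapped), " probe(s) absent from the map were dropped")
  multi <- names(which(table(map$probe_id) > 1L))
  keep_map <- map[!(map$probe_id %in% multi) & map$probe_id %in% probes, ,
                  drop = FALSE]
  if (!nrow(keep_map))
    stop("no probe survives multi-gene filtering and map restriction")
  vals <- exprsValues(probeMatrix)[keep_map$probe_id, , drop = FALSE]
  sums <- rowsum(vals, group = keep_map$gene_id)
  counts <- as.vector(table(keep_map$gene_id)[rownames(sums)])
  out <- sums / counts
  ReoMatrix(out[order(rownames(out)), , drop = FALSE],
            platform = platformTag(probeMatrix),
            colData = colData(probeMatrix))
}

#' Convert raw counts to FPKM
#'
#' `FPKM(g, s) = count(g, s) * 1e9 / (length(g) * totalCount(s))`, the
#' library size being the total count over the genes present in the matrix.
#' FPKM preserves the within-sample ordering of equal-length genes, so
#' rank-based downstream results do not depend on this normalisation beyond
#' the length correction.
#'
#' @param counts a [ReoMatrix-class] of non-negative counts.
#' @param geneLengths named numeric vector of transcript lengths in base
#'   pairs covering every gene of `counts` (see [readGeneLengths()]).
#' @return a [ReoMatrix-class] of FPKM values.
#' @export
countsToFPKM <- function(counts, geneLengths) {
  stopifnot(is(counts, "ReoMatrix"))
  genes <- geneIds(counts)
  missing <- setdiff(genes, names(geneLengths))
  if (length(missing))
    stop("missing gene length for gene: ", missing[1L])
  len <- geneLengths[genes]
  if (any(len <= 0))
    stop("non-positive length for gene: ", genes[which(len <= 0)[1L]])
  v <- exprsValues(counts)
  tot <- colSums(v)
  if (any(tot == 0))
    stop("zero total count for sample: ", sampleIds(counts)[which(tot == 0)[1L]])
  fpkm <- sweep(v / len, 2L, tot, "/") * 1e9
  ReoMatrix(fpkm, platform = platformTag(counts), colData = colData(counts))
}

#' Restrict matrices to their common gene universe
#'
#' Cross-platform pair sets must refer to a single gene universe; this
#' restricts every matrix to the sorted intersection of their gene ids,
#' leaving sample columns untouched.
#'
#' @param matrices list of two or more [ReoMatrix-class] objects.
#' @return list of [ReoMatrix-class] objects over the common, sorted gene
#'   universe, in input order.
#' @export
intersectGeneUniverse <- function(matrices) {
  if (length(matrices) < 2L)
    stop("need at least two matrices")
  common <- Reduce(intersect, lapply(matrices, geneIds))
  if (!length(common))
    stop("the gene universes have an empty intersection")
  common <- sort(common)
  lapply(matrices, function(m) m[common, ])
}
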