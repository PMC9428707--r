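# run code under a temporary RNG state so simulation never perturbs the
# caller's random stream
.withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a two-class cohort with planted reversal pairs
#'
#' Generates a gene-by-sample expression matrix whose background genes carry
#' no class-linked ordering (independent log-normal values), while each
#' planted pair shows `gene_a < gene_b` with probability `fidelity_pos` in
#' positive samples and `gene_a > gene_b` with probability `fidelity_neg` in
#' negative samples. Orderings are imposed by conditionally swapping the
#' pair's two sampled values, which preserves each gene's marginal
#' distribution (the two genes of a pair share one baseline). A
#' `tie_fraction` of values is zeroed afterwards to exercise tie handling.
#' Strata labels (stage, MSI status, primary site) are assigned at random to
#' cancer samples purely so stratified evaluation is exercisable; they carry
#' no biology.
#'
#' In `hub_mode` all pairs share one low gene; sequential swapping against
#' the shared gene guarantees the desired ordering with probability at least
#' the fidelity (not exactly equal to it).
#'
#' Output is fully reproducible from the config (including its `seed`) and
#' the caller's RNG state is left untouched.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `matrix` (a [ReoMatrix-class], positives
#'   first), `annotation` (`data.frame`, see [makeSampleAnnotation()]) and
#'   `truth` (list with `planted_pairs`: `data.frame` of `gene_a`, `gene_b`,
#'   `cancer_direction = "a_lt_b"`, and `config`).
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  .withSeed(config@seed, {
    n <- config@n_genes
    np <- config@n_planted
    s <- config@n_pos + config@n_neg
    genes <- sprintf("g%04d", seq_len(n))
    sample_ids <- c(sprintf("pos_%03d", seq_len(config@n_pos)),
                    sprintf("neg_%03d", seq_len(config@n_neg)))
    is_pos <- c(rep(TRUE, config@n_pos), rep(FALSE, config@n_neg))

    if (config@hub_mode && np > 0L) {
      low_idx <- rep(1L, np)
      high_idx <- 1L + seq_len(np)
    } else {
      low_idx <- 2L * seq_len(np) - 1L
      high_idx <- 2L * seq_len(np)
    }
    planted_idx <- unique(c(low_idx, high_idx))

    mu <- stats::rnorm(n, config@base_log_mean, config@base_log_sd)
    sds <- rep(config@noise_sd, n)
    if (np > 0L) {
      # each pair shares one baseline; pair baselines evenly spaced so the
      # class-conditional shift induced by forcing cannot overlap between
      # pairs or spill onto nearby background genes
      pair_mu <- config@base_log_mean +
        (seq_len(np) - (np + 1) / 2) * config@planted_spacing
      mu[low_idx] <- pair_mu
      mu[high_idx] <- pair_mu
      if (config@hub_mode) mu[1L] <- config@base_log_mean
      sds[planted_idx] <- config@planted_noise_sd
    }
    vals <- exp(mu + matrix(stats::rnorm(n * s), n, s) * sds)
    dimnames(vals) <- list(genes, sample_ids)

    for (t in seq_len(np)) {
      a <- low_idx[t]; b <- high_idx[t]
      want_lt <- ifelse(is_pos,
                        stats::runif(s) < config@fidelity_pos,
                        stats::runif(s) >= config@fidelity_neg)
      swap <- (vals[a, ] < vals[b, ]) != want_lt
      tmp <- vals[a, swap]
      vals[a, swap] <- vals[b, swap]
      vals[b, swap] <- tmp
    }
    if (config@tie_fraction > 0)
      vals[matrix(stats::runif(n * s), n, s) < config@tie_fraction] <- 0

    class_label <- character(s)
    class_label[is_pos] <- sample(c("cancer", "cancer_adjacent"),
                                  config@n_pos, replace = TRUE,
                                  prob = c(0.8, 0.2))
    class_label[!is_pos] <- sample(c("normal", "adenoma", "ibd"),
                                   config@n_neg, replace = TRUE,
                                   prob = c(0.7, 0.2, 0.1))
    annotation <- data.frame(sample_id = sample_ids,
                             class_label = class_label,
                             stringsAsFactors = FALSE)
    cancer <- annotation$class_label == "cancer"
    annotation$stage <- ifelse(cancer,
                               sample(c("I", "II", "III", "IV"), s,
                                      replace = TRUE),
                               NA_character_)
    annotation$msi_status <- ifelse(cancer,
                                    sample(c("MSI", "MSS"), s, replace = TRUE,
                                           prob = c(0.3, 0.7)),
                                    NA_character_)
    annotation$primary_site <- ifelse(cancer,
                                      sample(c("left", "right"), s,
                                             replace = TRUE),
                                      NA_character_)
    annotation <- makeSampleAnnotation(annotation)

    planted_pairs <- data.frame(
      gene_a = genes[low_idx], gene_b = genes[high_idx],
      cancer_direction = rep("a_lt_b", np),
      stringsAsFactors = FALSE)

    list(matrix = ReoMatrix(vals, platform = "simulated",
                            colData = annotation),
         annotation = annotation,
         truth = list(planted_pairs = planted_pairs, config = config))
  })
}

#' Apply a strictly monotone per-sample distortion
#'
#' Simulates platform and batch effects that preserve within-sample
#' orderings: every sample's values pass through their own strictly
#' increasing transform, so all rank-based results downstream are unchanged.
#' Families: `affine_positive` (`scale * x + shift`, `scale > 0`,
#' `shift >= 0`), `power` (`x^exponent`, `exponent > 0`), `log1p_scale`
#' (`scale * log1p(x)`, `scale > 0`) and `identity`. Parameters may be given
#' per sample or drawn reproducibly from `seed`.
#'
#' @param x a [ReoMatrix-class].
#' @param family distortion family.
#' @param params optional `data.frame` with one row per sample: columns
#'   `scale` and `shift` (affine), `exponent` (power), or `scale`
#'   (log1p_scale). When `NULL`, parameters are drawn from `seed`.
#' @param seed RNG seed used when `params` is `NULL`.
#' @return a distorted [ReoMatrix-class] with the same gene and sample ids;
#'   the platform tag records the family.
#' @export
applyMonotoneDistortion <- function(x,
                                    family = c("affine_positive", "power",
                                               "log1p_scale", "identity"),
                                    params = NULL, seed = 1L) {
  stopifnot(is(x, "ReoMatrix"))
  family <- match.arg(family)
  v <- exprsValues(x)
  s <- ncol(v)
  if (family == "identity") {
    out <- v
  } else {
    if (is.null(params)) {
      params <- .withSeed(seed, switch(family,
        affine_positive = data.frame(scale = stats::runif(s, 0.5, 3),
                                     shift = stats::runif(s, 0, 5)),
        power = data.frame(exponent = stats::runif(s, 0.5, 2)),
        log1p_scale = data.frame(scale = stats::runif(s, 0.5, 3))))
    }
    if (nrow(params) != s)
      stop("params must have one row per sample")
    out <- switch(family,
      affine_positive = {
        if (any(params$scale <= 0) || any(params$shift < 0))
          stop("affine distortion needs scale > 0 and shift >= 0")
        sweep(sweep(v, 2L, params$scale, "*"), 2L, params$shift, "+")
      },
      power = {
        if (any(params$exponent <= 0))
          stop("power distortion needs exponent > 0")
        sweep(v, 2L, params$exponent, "^")
      },
      log1p_scale = {
        if (any(params$scale <= 0))
          stop("log1p_scale distortion needs scale > 0")
        sweep(log1p(v), 2L, params$scale, "*")
      })
  }
  ReoMatrix(out, platform = paste0(platformTag(x), "+", family),
            colData = colData(x))
}

#' Split a cohort into distorted multi-platform views
#'
#' Emulates a microarray / RNA-seq style split: samples are partitioned into
#' `nViews` disjoint random groups covering the whole cohort, each view keeps
#' a random gene subset of `geneKeepFraction` of the universe (always
#' including `plantedGenes`, so planted pairs stay discoverable in every
#' view) and receives its own monotone distortion.
#'
#' @param x a [ReoMatrix-class].
#' @param nViews number of views (platforms).
#' @param geneKeepFraction fraction of genes each view retains, in `(0, 1]`.
#' @param family distortion family per view (see
#'   [applyMonotoneDistortion()]).
#' @param seed RNG seed controlling the partition, gene subsets and
#'   distortion parameters.
#' @param plantedGenes character vector of genes that every view must keep;
#'   an error is raised when `geneKeepFraction` is too small to honour it.
#' @return list of `nViews` [ReoMatrix-class] objects with disjoint sample
#'   sets.
#' @export
makePlatformViews <- function(x, nViews = 2L, geneKeepFraction = 1.0,
                              family = "affine_positive", seed = 1L,
                              plantedGenes = character()) {
  stopifnot(is(x, "ReoMatrix"))
  if (geneKeepFraction <= 0 || geneKeepFraction > 1)
    stop("geneKeepFraction must lie in (0, 1]")
  if (nViews < 1L || nViews > ncol(x))
    stop("nViews must lie between 1 and the number of samples")
  genes <- geneIds(x)
  plantedGenes <- intersect(plantedGenes, genes)
  keep_n <- round(geneKeepFraction * length(genes))
  if (keep_n < length(plantedGenes))
    stop("geneKeepFraction too small to retain all planted genes")
  .withSeed(seed, {
    shuffled <- sample(sampleIds(x))
    grp <- rep_len(seq_len(nViews), length(shuffled))
    lapply(seq_len(nViews), function(k) {
      cols <- sort(shuffled[grp == k])
      extra <- sample(setdiff(genes, plantedGenes),
                      keep_n - length(plantedGenes))
      rows <- genes[genes %in% c(plantedGenes, extra)]
      view <- x[rows, cols]
      view <- ReoMatrix(exprsValues(view),
                        platform = sprintf("view%d", k),
                        colData = colData(view))
      applyMonotoneDistortion(view, family = family,
                              seed = seed + 1000L * k)
    })
  })
}

#' Read / write the planted ground truth of a simulated cohort
#'
#' Three-column TSV with header (`gene_a`, `gene_b`, `cancer_direction`);
#' round-trips losslessly.
#'
#' @param path file path.
#' @return `readCohortTruth`: `data.frame` of planted pairs.
#' @export
readCohortTruth <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' @rdname readCohortTruth
#' @param plantedPairs `data.frame` of planted pairs
#'   (`truth$planted_pairs` from [simulateCohort()]).
#' @return `writeCohortTruth`: `path`, invisibly.
#' @export
writeCohortTruth <- function(plantedPairs, path) {
  utils::write.table(plantedPairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
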