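#' Heatmap matrix of differential genes, centred on the group midpoint
#'
#' Builds the display matrix for a two-group expression heatmap: rows are the
#' genes whose regularized t-statistic exceeds the threshold (two-sided,
#' `|d| > t_threshold`, so both over- and under-expressed genes appear;
#' `two_sided = FALSE` keeps only `d > t_threshold`), each row is the probe
#' representing the gene, and every cell is the log2 value minus the gene's
#' midpoint reference — the mean of the two group means on the log2 scale —
#' so cell signs correspond to fold-change direction and the two groups sit
#' symmetrically around 0. Rows are ordered by average-linkage clustering on
#' correlation distance; columns by time of death, ascending within each
#' group (control group first).
#'
#' @param norm normalized log2 matrix (probes x samples).
#' @param de per-gene differential expression table ([collapse_probes()]
#'   output): columns `probe_id`, `gene_id`, `d`.
#' @param meta data.frame with `sample`, `group`, `tod` covering the matrix
#'   columns.
#' @param groups factor of two levels over the samples (control level first),
#'   as used in the DE step.
#' @param t_threshold inclusion threshold on the regularized t (default 1).
#' @param two_sided include both signs of d (default TRUE).
#' @return object of class `"heatmap_spec"`: list with `values` (genes x
#'   samples, reordered), `genes`, `samples`, `midpoint` (per-gene log2
#'   reference).
#' @export
heatmap_matrix <- function(norm, de, meta, groups, t_threshold = 1,
                           two_sided = TRUE) {
  g <- .check_groups(norm, groups, min_per_group = 1)
  keep <- if (two_sided) abs(de$d) > t_threshold else de$d > t_threshold
  if (!any(keep)) stop("no gene passes the t-statistic threshold ",
                       t_threshold)
  de <- de[keep, , drop = FALSE]
  probes <- de$probe_id
  if (!all(probes %in% rownames(norm)))
    stop("DE probes missing from the normalized matrix")
  vals <- norm[probes, , drop = FALSE]
  rownames(vals) <- de$gene_id

  m1 <- rowMeans(vals[, g$ctrl, drop = FALSE])
  m2 <- rowMeans(vals[, g$test, drop = FALSE])
  midpoint <- (m1 + m2) / 2
  vals <- vals - midpoint

  row_ord <- seq_len(nrow(vals))
  if (nrow(vals) >= 3) {
    cd <- 1 - stats::cor(t(vals))
    cd[!is.finite(cd)] <- 2      # zero-variance guard
    row_ord <- stats::hclust(stats::as.dist(cd), method = "average")$order
  }
  idx <- match(colnames(norm), meta$sample)
  if (anyNA(idx)) stop("metadata must cover every sample column")
  grp <- as.factor(groups)
  col_ord <- order(as.integer(grp), meta$tod[idx])

  vals <- vals[row_ord, col_ord, drop = FALSE]
  structure(list(values = vals, genes = rownames(vals),
                 samples = colnames(vals), midpoint = midpoint[row_ord]),
            class = "heatmap_spec")
}

#' Run a full two-cohort comparison
#'
#' Executes the whole pipeline on one comparison: detection filter,
#' multi-loess normalization, regularized-t differential expression with
#' permutation q-values and signed fold changes, probe-to-gene collapse,
#' q-ranked gene list, rank-order gene-set enrichment with Bonferroni
#' adjustment, VI clustering of the significant sets, and the heatmap matrix.
#' A manifest records the seed, the parameters and the counts at each stage.
#'
#' @param matrix raw log2 expression matrix (probes x samples).
#' @param meta sample metadata (`sample`, `group`, `tod`).
#' @param mapping probe-to-gene mapping (`probe_id`, `gene_id`).
#' @param collection named list of gene sets.
#' @param test,control values of `meta$group` naming the two cohorts.
#' @param threshold_method,manual_threshold detection threshold settings
#'   (see [estimate_detection_threshold()]).
#' @param span,tol multi-loess settings.
#' @param s0_percentile,n_perm,seed differential expression settings.
#' @param alpha significance cutoff on Bonferroni-adjusted set p-values.
#' @param t_threshold heatmap inclusion threshold on the regularized t.
#' @return list with `threshold`, `normalized`, `de`, `de_genes`, `ranked`,
#'   `enrichment`, `clustering` (NULL if fewer than 2 significant sets),
#'   `heatmap` (NULL if no gene passes), `manifest`.
#' @export
run_comparison <- function(matrix, meta, mapping, collection,
                           test = "pos", control = "neg",
                           threshold_method = "valley",
                           manual_threshold = NULL,
                           span = 0.4, tol = 1e-3,
                           s0_percentile = 75, n_perm = 200, seed = 1L,
                           alpha = 0.01, t_threshold = 1) {
  sel <- meta$group %in% c(test, control)
  if (sum(meta$group == test) < 2 || sum(meta$group == control) < 2)
    stop("each cohort must match at least 2 samples")
  meta <- meta[sel, , drop = FALSE]
  matrix <- matrix[, meta$sample, drop = FALSE]
  groups <- factor(meta$group, levels = c(control, test))

  thr <- estimate_detection_threshold(matrix, method = threshold_method,
                                      manual_value = manual_threshold)
  detected <- filter_detected(matrix, thr)
  norm <- multiloess_normalize(detected, span = span, tol = tol)
  de <- diff_expression(norm, groups, n_perm = n_perm, seed = seed,
                        s0_percentile = s0_percentile)
  de_genes <- collapse_probes(de, mapping)
  ranked <- ranked_gene_list(de_genes)
  enrichment <- enrich_collection(ranked, collection, alpha = alpha)

  sig <- enrichment$set[enrichment$significant]
  clustering <- if (length(sig) >= 2)
    cluster_sets(collection[sig], universe = ranked) else NULL
  heatmap <- tryCatch(
    heatmap_matrix(norm, de_genes, meta, groups, t_threshold = t_threshold),
    error = function(e) NULL)

  manifest <- list(
    seed = seed,
    parameters = list(test = test, control = control,
                      threshold_method = threshold_method, span = span,
                      tol = tol, s0_percentile = s0_percentile,
                      n_perm = n_perm, alpha = alpha,
                      t_threshold = t_threshold),
    threshold = thr$value,
    normalization = list(iterations = attr(norm, "iterations"),
                         residual = attr(norm, "residual")),
    counts = list(samples = ncol(matrix),
                  probes_in = nrow(matrix),
                  probes_detected = nrow(detected),
                  genes = nrow(de_genes),
                  de_q05 = sum(de_genes$q < 0.05),
                  sets_testable = attr(enrichment, "n_testable"),
                  sets_significant = length(sig),
                  heatmap_genes = if (is.null(heatmap)) 0L
                                  else length(heatmap$genes)))
  list(threshold = thr, normalized = norm, de = de, de_genes = de_genes,
       ranked = ranked, enrichment = enrichment, clustering = clustering,
       heatmap = heatmap, manifest = manifest)
}

#' Write a comparison manifest as JSON
#'
#' @param bundle a [run_comparison()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(bundle, path) {
  jsonlite::write_json(bundle$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
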