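#' Regularized t-statistic with an exchangeability factor
#'
#' For each probe, `s = sqrt((1/n1 + 1/n2) * (SS1 + SS2)/(n1 + n2 - 2))` is
#' the pooled standard error and `d = (mean(test) - mean(control)) / (s + s0)`
#' the regularized t-statistic, with the exchangeability factor `s0` a shared
#' scalar set to a percentile of the per-probe `s` values. The additive `s0`
#' keeps probes with accidentally tiny variance from dominating the ranking.
#'
#' @param matrix log2 expression matrix (probes x samples).
#' @param groups factor (or coercible) of two levels over the samples; the
#'   first level is the control group, the second the test group, so `d > 0`
#'   means higher expression in the test group.
#' @param s0_percentile percentile (0--100) of the `s` distribution used for
#'   `s0`; linear interpolation between order statistics. Default 75.
#' @param s0 optional fixed `s0`, overriding the percentile rule.
#' @return data.frame with columns `probe_id`, `d`, `s`; the scalar `s0` is
#'   attached as an attribute.
#' @examples
#' m <- rbind(A = c(1, 1, 1, 0, 0, 0))
#' colnames(m) <- paste0("s", 1:6)
#' g <- factor(rep(c("ctrl", "test"), each = 3))
#' regularized_t(m, g, s0 = 0.5)  # d = 1 / 0.5 = 2
#' @export
regularized_t <- function(matrix, groups, s0_percentile = 75, s0 = NULL) {
  g <- .check_groups(matrix, groups)
  st <- .dstat_parts(matrix, g$test, g$ctrl)
  if (is.null(s0)) {
    if (s0_percentile < 0 || s0_percentile > 100)
      stop("s0_percentile must be in [0, 100]")
    s0 <- unname(stats::quantile(st$s, s0_percentile / 100, type = 7))
    if (s0 == 0) warning("s0 is 0 (constant matrix?)")
  }
  if (s0 < 0) stop("s0 must be non-negative")
  out <- data.frame(probe_id = .probe_ids(matrix),
                    d = st$num / (st$s + s0), s = st$s,
                    stringsAsFactors = FALSE)
  attr(out, "s0") <- s0
  out
}

#' Permutation-based q-values for the regularized t-statistic
#'
#' SAM-style false discovery rates: for every candidate threshold on `|d|`
#' (the observed `|d|` values), the expected number of false calls is the
#' median over label permutations of the count of permuted `|d*|` at or above
#' the threshold, scaled by an estimate of the null proportion `pi0`; the FDR
#' at a threshold is that expectation over the observed call count, and a
#' probe's q-value is the smallest FDR over all thresholds at which it is
#' called. `s0` is computed once from the observed labels and reused for the
#' permuted statistics. When the number of distinct label assignments is at
#' most `n_perm` they are enumerated exhaustively; otherwise `n_perm` random
#' permutations are drawn.
#'
#' `pi0` defaults to the quantile heuristic: the fraction of observed `d`
#' falling between the 25th and 75th percentiles of the permuted `d*`,
#' divided by 0.5 and capped at 1. Pass `pi0 = 1` to disable the correction.
#'
#' @inheritParams regularized_t
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the random permutations.
#' @param pi0 optional fixed null proportion in (0, 1].
#' @param assignments optional list of test-group column-index vectors to use
#'   as the permutations, overriding enumeration/sampling (mainly for
#'   diagnostics).
#' @return data.frame with columns `probe_id`, `d`, `s`, `q`; attributes
#'   `s0`, `pi0` and `n_perm_used`.
#' @export
permutation_qvalues <- function(matrix, groups, n_perm = 200, seed = 1L,
                                s0_percentile = 75, s0 = NULL, pi0 = NULL,
                                assignments = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  g <- .check_groups(matrix, groups)
  obs <- regularized_t(matrix, groups, s0_percentile, s0)
  s0 <- attr(obs, "s0")
  n <- ncol(matrix)
  n_test <- length(g$test)

  if (!is.null(assignments)) {
    assign_idx <- assignments
  } else if (choose(n, n_test) <= n_perm) {
    assign_idx <- utils::combn(n, n_test, simplify = FALSE)
  } else {
    set.seed(seed)
    assign_idx <- replicate(n_perm, sort(sample(n, n_test)), simplify = FALSE)
  }
  B <- length(assign_idx)
  if (B < 20) warning("few permutations (", B, "); q-value resolution is ",
                      signif(1 / B, 2))

  all_idx <- seq_len(n)
  dstar <- vapply(assign_idx, function(te) {
    st <- .dstat_parts(matrix, te, setdiff(all_idx, te))
    st$num / (st$s + s0)
  }, numeric(nrow(matrix)))              # probes x B

  if (is.null(pi0)) {
    qs <- stats::quantile(dstar, c(0.25, 0.75))
    pi0 <- min(1, mean(obs$d > qs[1] & obs$d < qs[2]) / 0.5)
    if (pi0 <= 0) pi0 <- 1
  }
  if (pi0 <= 0 || pi0 > 1) stop("pi0 must be in (0, 1]")

  absd <- abs(obs$d)
  ord <- order(absd, decreasing = TRUE)
  thr <- absd[ord]                       # thresholds, largest first
  m <- length(thr)
  ## per permutation, count of |d*| >= each threshold
  counts <- vapply(seq_len(B), function(b) {
    sd_ <- sort(abs(dstar[, b]))
    m - findInterval(thr, sd_, left.open = TRUE)
  }, numeric(m))
  V <- apply(counts, 1, stats::median)
  R <- seq_len(m)                        # observed calls at each threshold
  fdr <- pmin(1, pi0 * V / R)
  q_sorted <- rev(cummin(rev(fdr)))      # min FDR over thresholds <= |d_i|
  q <- numeric(m)
  q[ord] <- q_sorted
  out <- data.frame(probe_id = obs$probe_id, d = obs$d, s = obs$s, q = q,
                    stringsAsFactors = FALSE)
  attr(out, "s0") <- s0
  attr(out, "pi0") <- pi0
  attr(out, "n_perm_used") <- B
  out
}

#' Signed fold change of linear-scale group means
#'
#' The ratio of linear-scale (2^log2) group means, test over control. Ratios
#' below one are reported as the negated reciprocal, so `|f| >= 1` always and
#' the sign encodes direction: `f = 4` is 4-fold up in the test group,
#' `f = -2` is 2-fold down.
#'
#' @inheritParams regularized_t
#' @return named numeric vector of signed fold changes, one per probe.
#' @export
fold_change <- function(matrix, groups) {
  g <- .check_groups(matrix, groups, min_per_group = 1)
  lin <- 2^matrix
  m_test <- rowMeans(lin[, g$test, drop = FALSE])
  m_ctrl <- rowMeans(lin[, g$ctrl, drop = FALSE])
  stopifnot(all(m_test > 0), all(m_ctrl > 0))
  ratio <- m_test / m_ctrl
  f <- ifelse(ratio >= 1, ratio, -1 / ratio)
  names(f) <- .probe_ids(matrix)
  f
}

#' Differential expression table (d, q, f) for a two-group comparison
#'
#' Convenience wrapper running [regularized_t()], [permutation_qvalues()] and
#' [fold_change()] on the same matrix and labels.
#'
#' @inheritParams permutation_qvalues
#' @return data.frame with columns `probe_id`, `d`, `s`, `q`, `f` and
#'   attributes `s0`, `pi0`, `n_perm_used`.
#' @export
diff_expression <- function(matrix, groups, n_perm = 200, seed = 1L,
                            s0_percentile = 75, s0 = NULL, pi0 = NULL) {
  de <- permutation_qvalues(matrix, groups, n_perm = n_perm, seed = seed,
                            s0_percentile = s0_percentile, s0 = s0, pi0 = pi0)
  de$f <- unname(fold_change(matrix, groups))
  de
}

#' Collapse per-probe results to one probe per gene
#'
#' Whenever several probes interrogate the same gene, only the highest-ranking
#' probe represents it: smallest q, ties broken by larger `|d|`, then by
#' lexicographic probe id. Probes without a mapping entry are dropped with a
#' warning.
#'
#' @param results per-probe data.frame with at least `probe_id`, `d`, `q`.
#' @param mapping data.frame with columns `probe_id`, `gene_id`.
#' @return per-gene data.frame (one row per gene) with a `gene_id` column.
#' @export
collapse_probes <- function(results, mapping) {
  if (nrow(mapping) == 0) stop("empty probe-to-gene mapping")
  idx <- match(results$probe_id, mapping$probe_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " probes without gene mapping dropped")
    results <- results[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  results$gene_id <- mapping$gene_id[idx]
  ord <- order(results$q, -abs(results$d), results$probe_id)
  results <- results[ord, , drop = FALSE]
  out <- results[!duplicated(results$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ranked gene list from a per-gene differential expression table
#'
#' Sorts genes best-first by ascending q, ties by descending `|d|`, then by
#' gene id, yielding the strict order the rank-based enrichment statistic
#' requires (position 1 = most significant).
#'
#' @param gene_results per-gene data.frame with `gene_id`, `q`, `d`.
#' @return character vector of gene ids, best first.
#' @export
ranked_gene_list <- function(gene_results) {
  if (anyDuplicated(gene_results$gene_id))
    stop("gene ids must be unique; run collapse_probes() first")
  gene_results$gene_id[order(gene_results$q, -abs(gene_results$d),
                             gene_results$gene_id)]
}

.probe_ids <- function(matrix) {
  if (is.null(rownames(matrix))) sprintf("P%05d", seq_len(nrow(matrix)))
  else rownames(matrix)
}

.check_groups <- function(matrix, groups, min_per_group = 2) {
  g <- as.factor(groups)
  if (nlevels(g) != 2) stop("groups must have exactly 2 levels")
  if (length(g) != ncol(matrix)) stop("one group label per sample required")
  ctrl <- which(g == levels(g)[1])
  test <- which(g == levels(g)[2])
  if (length(ctrl) < min_per_group || length(test) < min_per_group)
    stop("each group needs at least ", min_per_group, " samples")
  list(ctrl = ctrl, test = test)
}

# Pooled-SE t pieces for test/control column indices.
.dstat_parts <- function(matrix, test, ctrl) {
  n1 <- length(test); n2 <- length(ctrl)
  m1 <- rowMeans(matrix[, test, drop = FALSE])
  m2 <- rowMeans(matrix[, ctrl, drop = FALSE])
  ss1 <- rowSums((matrix[, test, drop = FALSE] - m1)^2)
  ss2 <- rowSums((matrix[, ctrl, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(num = m1 - m2, s = s)
}
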