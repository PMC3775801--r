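#' Positions of gene-set members in a ranked list
#'
#' Returns the sorted 1-based positions of the set members that appear in the
#' ranked list (position 1 = most significant). Members absent from the list
#' — genes not detected in the experiment — are dropped, and the effective
#' set size `n` counts only present members.
#'
#' @param ranked character vector of unique gene ids, best first.
#' @param members character vector of set member gene ids.
#' @return sorted integer vector of ranks (possibly empty).
#' @export
ranks_of_set <- function(ranked, members) {
  if (anyDuplicated(ranked)) stop("ranked list must contain unique ids")
  sort(which(ranked %in% members))
}

#' Tail probability of a rank order statistic
#'
#' For `n` ranks drawn uniformly without replacement from `{1..N}`, the
#' probability that at least `k` of them fall within the top `r` positions —
#' equivalently, that the k-th best of the `n` random ranks is at least as
#' good as position `r`:
#' \deqn{p_k = \sum_{j=k}^{\min(n,r)} \binom{r}{j}\binom{N-r}{n-j} /
#'   \binom{N}{n}.}
#' Terms are accumulated in log space (via `lchoose`) so the computation is
#' stable at list lengths in the tens of thousands. Vectorized over paired
#' `k` and `r`.
#'
#' @param k depth (1-based), `1 <= k <= n`.
#' @param r rank position, `1 <= r <= N`.
#' @param n number of ranks drawn (set size in the list).
#' @param N list length.
#' @param log return log tail probabilities (useful when enrichment is so
#'   deep that the probability underflows a double).
#' @return numeric vector of tail probabilities in (0, 1] (or their logs).
#' @examples
#' order_statistic_tail(1, 1, 1, 10)  # 0.1
#' order_statistic_tail(2, 3, 2, 6)   # 0.2
#' @export
order_statistic_tail <- function(k, r, n, N, log = FALSE) {
  len <- max(length(k), length(r))
  k <- rep_len(as.integer(k), len)
  r <- rep_len(as.integer(r), len)
  if (n < 1 || n > N) stop("need 1 <= n <= N")
  if (any(k < 1 | k > n)) stop("need 1 <= k <= n")
  if (any(r < 1 | r > N)) stop("need 1 <= r <= N")
  lden <- lchoose(N, n)
  lt <- matrix(-Inf, len, n)
  for (j in seq_len(n)) {
    active <- k <= j & j <= r
    if (any(active))
      lt[active, j] <- lchoose(r[active], j) +
        lchoose(N - r[active], n - j) - lden
  }
  ## log-sum-exp across terms, factoring out the largest
  mx <- do.call(pmax, c(as.data.frame(lt), list(na.rm = TRUE)))
  lp <- ifelse(is.finite(mx),
               mx + log(rowSums(exp(lt - ifelse(is.finite(mx), mx, 0)))),
               -Inf)
  lp <- pmin(lp, 0)
  if (log) lp else exp(lp)
}

#' Rank-order enrichment p-value of one gene set
#'
#' The set's members occupy positions `r_1 < ... < r_n` in the ranked list.
#' For each depth `k` the tail probability `p_k` that `k` random ranks would
#' reach position `r_k` is computed, and the set p-value is `min_k p_k`: the
#' statistic looks for the depth at which the set is most concentrated at the
#' top of the list. No within-set multiplicity adjustment is applied — the
#' `n` tail tests on one set are strongly dependent — so the statistic is
#' anti-conservative as a p-value and is meant to be adjusted across sets
#' (see [enrich_collection()]). By design it only detects overrepresentation
#' at the top, never depletion.
#'
#' @inheritParams ranks_of_set
#' @return list with `n`, `N`, `ranks`, `p_k` (length n), `p` (= min p_k),
#'   `log_p` (natural log of `p`, exact even when `p` underflows to 0),
#'   `argmin_k`, and `testable` (FALSE when no member is present, in which
#'   case `p` is NA).
#' @examples
#' set_pvalue(c("g1", "g2", "g3", "g4", "g5", "g6"), c("g1", "g2"))$p # 1/15
#' @export
set_pvalue <- function(ranked, members) {
  ranks <- ranks_of_set(ranked, members)
  n <- length(ranks)
  N <- length(ranked)
  if (n == 0)
    return(list(n = 0L, N = N, ranks = integer(0), p_k = numeric(0),
                p = NA_real_, log_p = NA_real_, argmin_k = NA_integer_,
                testable = FALSE))
  ## depth selection in log space: deep enrichments underflow exp scale
  log_pk <- order_statistic_tail(seq_len(n), ranks, n, N, log = TRUE)
  argmin <- which.min(log_pk)
  list(n = n, N = N, ranks = ranks, p_k = exp(log_pk),
       p = exp(log_pk[argmin]), log_p = log_pk[argmin],
       argmin_k = argmin, testable = TRUE)
}

#' Null distribution of the minimum rank-order tail statistic
#'
#' Draws random sets of `n` ranks without replacement from `{1..N}` and
#' returns the min-over-depths tail statistic of each draw. Because the
#' per-depth tails are not adjusted for the minimum, this statistic is
#' anti-conservative relative to a uniform p-value; its empirical null CDF is
#' the calibration reference for interpreting raw set p-values.
#'
#' @param N list length.
#' @param n set size.
#' @param draws number of Monte Carlo draws.
#' @param seed integer seed.
#' @return numeric vector of `draws` null min-p statistics.
#' @export
null_min_p <- function(N, n, draws, seed = 1L) {
  set.seed(seed)
  ranks <- vapply(seq_len(draws),
                  function(i) sort(sample.int(N, n)), integer(n))
  ranks <- matrix(ranks, nrow = n)   # n x draws
  P <- matrix(NA_real_, draws, n)
  for (k in seq_len(n))
    P[, k] <- order_statistic_tail(k, ranks[k, ], n, N)
  do.call(pmin, as.data.frame(P))
}

#' Rank-order enrichment over a gene-set collection
#'
#' Applies [set_pvalue()] to every set, Bonferroni-adjusts the set p-values
#' for the number of testable sets (`p_adj = min(1, p * m)`), and flags sets
#' with `p_adj <= alpha` as significant. Sets with no member in the ranked
#' list are untestable and excluded (their count is recorded in the
#' `n_untestable` attribute).
#'
#' @inheritParams ranks_of_set
#' @param collection named list of character vectors (gene sets), e.g. from
#'   [read_gmt()] or [generate_geneset_collection()].
#' @param alpha significance cutoff on the adjusted p-value (default 0.01).
#' @return data.frame, sorted by `p_adj` then set name, with columns `set`,
#'   `n` (members in the list), `p`, `p_adj`, `argmin_k`, `r_argmin`,
#'   `significant`; attributes `n_testable`, `n_untestable`, `N`.
#' @export
enrich_collection <- function(ranked, collection, alpha = 0.01) {
  if (length(collection) == 0) stop("empty collection")
  if (is.null(names(collection)) || anyDuplicated(names(collection)))
    stop("collection must have unique set names")
  res <- lapply(collection, function(m) set_pvalue(ranked, m))
  testable <- vapply(res, `[[`, logical(1), "testable")
  if (!any(testable)) stop("no testable set (no member overlaps the list)")
  m <- sum(testable)
  res <- res[testable]
  out <- data.frame(
    set = names(res),
    n = vapply(res, `[[`, integer(1), "n"),
    p = vapply(res, `[[`, numeric(1), "p"),
    argmin_k = vapply(res, `[[`, integer(1), "argmin_k"),
    r_argmin = vapply(res, function(x) x$ranks[x$argmin_k], integer(1)),
    stringsAsFactors = FALSE)
  out$p_adj <- pmin(1, out$p * m)
  out$significant <- out$p_adj <= alpha
  out <- out[order(out$p_adj, out$set),
             c("set", "n", "p", "p_adj", "argmin_k", "r_argmin",
               "significant")]
  rownames(out) <- NULL
  attr(out, "n_testable") <- m
  attr(out, "n_untestable") <- sum(!testable)
  attr(out, "N") <- length(ranked)
  out
}
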