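#' Variation of information between two gene sets
#'
#' Each set induces a binary partition of the universe into members and
#' non-members; the variation of information between the two partitions is
#' `H(A) + H(B) - 2 I(A; B)` with entropies in bits and cell probabilities
#' equal to cell sizes over the universe size (`0 log 0 = 0`). VI is a true
#' metric on partitions: identical sets are at distance 0 and, at fixed set
#' sizes, VI decreases as the overlap grows. One degeneracy of the binary
#' reading is worth knowing: a set and its exact complement induce the same
#' partition and are at distance 0 — irrelevant in practice for small
#' ontology-like sets over a large universe.
#'
#' @param a,b character vectors, subsets of `universe`.
#' @param universe character vector of all gene ids under consideration
#'   (typically the detected genes).
#' @return distance in bits (non-negative scalar).
#' @examples
#' vi_distance(c("1", "2"), c("1", "3"), as.character(1:4))  # 2 bits
#' @export
vi_distance <- function(a, b, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(a %in% universe) || !all(b %in% universe))
    stop("sets must be subsets of the universe")
  Nu <- length(universe)
  n11 <- length(intersect(a, b))
  n10 <- length(a) - n11
  n01 <- length(b) - n11
  n00 <- Nu - n11 - n10 - n01
  h <- function(p) ifelse(p > 0, -p * log2(p), 0)
  pa <- length(a) / Nu
  pb <- length(b) / Nu
  ## sort() fixes the summation order so VI(a,b) and VI(b,a) are bit-identical
  Hmarg <- sum(h(sort(c(pa, 1 - pa, pb, 1 - pb))))
  Hab <- sum(h(sort(c(n11, n10, n01, n00) / Nu)))
  max(0, 2 * Hab - Hmarg)       # VI = 2 H(A,B) - H(A) - H(B)
}

#' Cluster gene sets by variation of information
#'
#' Builds the pairwise VI distance matrix over the given sets (binary
#' member/non-member partitions of the universe) and an average-linkage
#' hierarchical tree. Because overlapping sets are close in VI, clusters
#' group ontology terms that share member genes; the returned `shared` matrix
#' records pairwise shared-member counts for the report.
#'
#' @param sets named list of character vectors (typically the significant
#'   sets of an [enrich_collection()] run); at least 2.
#' @param universe character vector of all gene ids.
#' @return object of class `"vi_clustering"`: list with `dist` (symmetric
#'   matrix, bits), `hclust` (average linkage), `shared` (pairwise shared
#'   member counts), `sets`.
#' @export
cluster_sets <- function(sets, universe) {
  if (length(sets) < 2) stop("need at least 2 sets to cluster")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  k <- length(sets)
  D <- matrix(0, k, k, dimnames = list(names(sets), names(sets)))
  shared <- matrix(0L, k, k, dimnames = dimnames(D))
  diag(shared) <- lengths(sets)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    D[i, j] <- D[j, i] <- vi_distance(sets[[i]], sets[[j]], universe)
    shared[i, j] <- shared[j, i] <- length(intersect(sets[[i]], sets[[j]]))
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  structure(list(dist = D, hclust = hc, shared = shared, sets = sets),
            class = "vi_clustering")
}

#' Newick string of a set-clustering dendrogram
#'
#' @param clustering a [cluster_sets()] result.
#' @return single newick-format string (branch lengths from merge heights).
#' @export
vi_newick <- function(clustering) {
  stopifnot(inherits(clustering, "vi_clustering"))
  ape::write.tree(ape::as.phylo(clustering$hclust))
}

#' @export
print.vi_clustering <- function(x, ...) {
  cat("VI clustering of", length(x$sets), "gene sets; distances in bits",
      "(max", signif(max(x$dist), 3), ")\n")
  invisible(x)
}
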