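# Independent oracles and fixture builders used across test files.

# Exhaustive enumeration oracle for the rank-order set statistic: for ranks
# r (sorted ascending) of a set of size n in a list of length N, p_k is the
# fraction of all C(N, n) rank subsets whose k-th smallest element is <= r_k.
enum_pk <- function(r, n, N) {
  subsets <- utils::combn(N, n)           # columns sorted ascending
  rowMeans(subsets <= r)                  # r recycled down rows
}

enum_set_p <- function(r, n, N) min(enum_pk(r, n, N))

# Small deterministic expression matrix with named probes/samples.
toy_matrix <- function(values, n_samples, probe_ids = NULL) {
  m <- matrix(values, ncol = n_samples)
  rownames(m) <- if (is.null(probe_ids)) sprintf("P%03d", seq_len(nrow(m)))
                 else probe_ids
  colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
  m
}

two_groups <- function(n_ctrl, n_test) {
  factor(rep(c("ctrl", "test"), c(n_ctrl, n_test)),
         levels = c("ctrl", "test"))
}
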