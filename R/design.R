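#' Describe a two-cohort expression study design
#'
#' Captures the sample layout of a two-group retinal expression study:
#' HIV-negative controls, lesion-free HIV-positive samples, and two lesioned
#' HIV-positive cohorts (cotton wool spots, intraretinal hemorrhages), plus
#' the probe layout and per-donor time of death (TOD, hours since midnight).
#'
#' @param n_neg number of HIV-negative control samples.
#' @param n_pos number of lesion-free HIV-positive samples.
#' @param n_cws number of cotton-wool-spot samples.
#' @param n_irh number of intraretinal-hemorrhage samples.
#' @param n_probes number of expressed probes the generator emits (the
#'   detection filter returns exactly this many rows; undetected floor probes
#'   are appended on top of this count).
#' @param probes_per_gene number of probes interrogating each gene; exercises
#'   the probe-to-gene collapse rule.
#' @param tod optional numeric vector of times of death in `[0, 24)`, one per
#'   sample in the order negative, positive, CWS, IRH. When `NULL` the
#'   generator draws TODs itself (normal draws truncated to the day, centred
#'   at 12.5 h / sd 6.8 h for negatives and 11 h / sd 7.1 h for positives,
#'   matching the autopsy cohorts this design emulates).
#'
#' @return An object of class `"study_design"`.
#' @examples
#' d <- study_design(n_neg = 3, n_pos = 4, n_probes = 100)
#' d$n_samples
#' @export
study_design <- function(n_neg = 7, n_pos = 10, n_cws = 4, n_irh = 6,
                         n_probes = 18429, probes_per_gene = 1,
                         tod = NULL) {
  counts <- c(n_neg = n_neg, n_pos = n_pos, n_cws = n_cws, n_irh = n_irh)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("sample counts must be non-negative integers")
  if (n_probes <= 0) stop("n_probes must be positive")
  if (probes_per_gene < 1 || probes_per_gene != round(probes_per_gene))
    stop("probes_per_gene must be a positive integer")
  n_samples <- sum(counts)
  if (!is.null(tod)) {
    if (length(tod) != n_samples)
      stop("tod must have one entry per sample (", n_samples, ")")
    if (any(tod < 0 | tod >= 24)) stop("tod values must lie in [0, 24)")
  }
  structure(list(n_neg = as.integer(n_neg), n_pos = as.integer(n_pos),
                 n_cws = as.integer(n_cws), n_irh = as.integer(n_irh),
                 n_probes = as.integer(n_probes),
                 probes_per_gene = as.integer(probes_per_gene),
                 n_samples = as.integer(n_samples), tod = tod),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", x$n_neg, "neg /", x$n_pos, "pos /", x$n_cws,
      "CWS /", x$n_irh, "IRH samples;", x$n_probes, "expressed probes (",
      x$probes_per_gene, "probe(s) per gene )\n")
  invisible(x)
}

# Truncated-normal TOD draws on [0, 24) by rejection; means/sds chosen to
# mirror the autopsy cohorts (negatives 12:30PM +/- 6.8h, positives
# 11:00AM +/- 7.1h).
.draw_tod <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n + 10, mean, sd)
    out <- c(out, x[x >= 0 & x < 24])
  }
  out[seq_len(n)]
}
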