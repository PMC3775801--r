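#' Relative transcript abundance from Ct values
#'
#' Standard delta-Ct quantification against a reference gene:
#' `2^-(ct_target - ct_reference)`. One cycle of difference corresponds to a
#' factor of two in abundance.
#'
#' @param ct_target,ct_reference finite cycle-threshold values (vectorized).
#' @return linear relative abundance.
#' @examples
#' relative_abundance(21, 20)  # 0.5
#' @export
relative_abundance <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite")
  2^-(ct_target - ct_reference)
}

#' Cosinor test for a 24-hour rhythm in abundance
#'
#' Least-squares fit of log2 abundance on a single 24 h harmonic,
#' `cos(2*pi*t/24)` and `sin(2*pi*t/24)`. The amplitude is the norm of the
#' two harmonic coefficients, the acrophase (hour of peak) comes from their
#' angle, and the p-value is the joint F-test of the two harmonic terms
#' against the intercept-only model. This is a formal screen for diurnal
#' confounding when time of death is used as a proxy for circadian time.
#'
#' @param abundance positive linear relative abundances.
#' @param tod times in hours; at least 6 samples with at least 3 distinct
#'   times (the model has 3 parameters).
#' @return list with `amplitude` (log2 units), `phase` (hours in \[0, 24)),
#'   `p`, and `fit` (the lm object).
#' @examples
#' t <- seq(0, 23, 2)
#' diurnal_test(2^cos(2 * pi * (t - 6) / 24), t)$phase  # 6
#' @export
diurnal_test <- function(abundance, tod) {
  if (length(abundance) != length(tod)) stop("length mismatch")
  if (length(tod) < 6) stop("need at least 6 samples")
  if (length(unique(tod %% 24)) < 3)
    stop("need at least 3 distinct times of day")
  if (any(abundance <= 0)) stop("abundances must be positive")
  y <- log2(abundance)
  cs <- cos(2 * pi * tod / 24)
  sn <- sin(2 * pi * tod / 24)
  fit <- stats::lm(y ~ cs + sn)
  b <- stats::coef(fit)[c("cs", "sn")]
  b[is.na(b)] <- 0
  amplitude <- sqrt(sum(b^2))
  # y ~ A cos(w(t - phi)): b_cos = A cos(w phi), b_sin = A sin(w phi)
  phase <- (atan2(b[["sn"]], b[["cs"]]) * 24 / (2 * pi)) %% 24
  p <- stats::anova(stats::lm(y ~ 1), fit)[["Pr(>F)"]][2]
  if (is.na(p)) p <- 1  # perfectly constant response: no rhythm evidence
  list(amplitude = amplitude, phase = phase, p = p, fit = fit)
}

#' Per-gene diurnal screen of a qPCR table
#'
#' Computes delta-Ct relative abundances against the reference gene for every
#' target transcript and runs [diurnal_test()] on each, producing the
#' per-gene rhythm table and the per-sample plot data (abundance vs time of
#' death by group).
#'
#' @param qpcr data.frame with columns `sample`, `gene`, `ct`, `tod`,
#'   `group` (as from [generate_qpcr()] or [read_qpcr_tsv()]).
#' @param reference reference gene name (must be present for every sample).
#' @return list with `tests` (data.frame: gene, amplitude, phase, p) and
#'   `plot_data` (data.frame: sample, gene, tod, group, abundance).
#' @export
qpcr_diurnal_report <- function(qpcr, reference = "GAPDH") {
  ref <- qpcr[qpcr$gene == reference, ]
  if (nrow(ref) == 0) stop("reference gene ", reference, " not in table")
  targets <- setdiff(unique(qpcr$gene), reference)
  plot_rows <- list()
  tests <- list()
  for (g in targets) {
    tg <- qpcr[qpcr$gene == g, ]
    idx <- match(tg$sample, ref$sample)
    if (anyNA(idx)) stop("reference Ct missing for some samples of ", g)
    ab <- relative_abundance(tg$ct, ref$ct[idx])
    plot_rows[[g]] <- data.frame(sample = tg$sample, gene = g, tod = tg$tod,
                                 group = tg$group, abundance = ab,
                                 stringsAsFactors = FALSE)
    dt <- diurnal_test(ab, tg$tod)
    tests[[g]] <- data.frame(gene = g, amplitude = dt$amplitude,
                             phase = dt$phase, p = dt$p,
                             stringsAsFactors = FALSE)
  }
  out_tests <- do.call(rbind, tests)
  rownames(out_tests) <- NULL
  plot_data <- do.call(rbind, plot_rows)
  rownames(plot_data) <- NULL
  list(tests = out_tests, plot_data = plot_data)
}
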