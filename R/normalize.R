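#' Estimate the detection threshold from the pooled intensity distribution
#'
#' Array log-intensity distributions are typically bimodal: a narrow
#' background mode of probes that never hybridize and a broad mode of
#' expressed probes. The `valley` method locates the minimum of a kernel
#' density estimate of the pooled log2 values between the two largest modes —
#' an automated stand-in for reading the cutoff off a distribution plot.
#'
#' @param matrix numeric matrix of log2 expression (probes x samples).
#' @param method one of `"valley"`, `"quantile"`, `"manual"`.
#' @param manual_value threshold to use when `method = "manual"`.
#' @param q probability for `method = "quantile"`.
#' @return A `"detection_threshold"` object (list with `value`, `method`).
#' @examples
#' m <- matrix(c(rnorm(500, 4, 0.5), rnorm(500, 10, 0.5)), ncol = 4)
#' estimate_detection_threshold(m)$value
#' @seealso [filter_detected()]
#' @export
estimate_detection_threshold <- function(matrix,
                                         method = c("valley", "quantile",
                                                    "manual"),
                                         manual_value = NULL, q = 0.05) {
  method <- match.arg(method)
  if (length(matrix) == 0) stop("empty matrix")
  x <- as.numeric(matrix)
  value <- switch(method,
    manual = {
      if (is.null(manual_value)) stop("manual method requires manual_value")
      manual_value
    },
    quantile = unname(stats::quantile(x, q)),
    valley = {
      d <- stats::density(x, n = 1024)
      peaks <- which(diff(sign(diff(d$y))) == -2) + 1
      if (length(peaks) < 2)
        stop("pooled log2 distribution looks unimodal; ",
             "use method = 'quantile' or 'manual'")
      top2 <- sort(peaks[order(d$y[peaks], decreasing = TRUE)][1:2])
      i <- seq(top2[1], top2[2])
      d$x[i[which.min(d$y[i])]]
    })
  if (!is.finite(value)) stop("threshold is not finite")
  structure(list(value = value, method = method),
            class = "detection_threshold")
}

#' Keep probes detected in at least one sample
#'
#' A probe is detected when its expression exceeds the threshold in at least
#' one sample; all other probes are dropped. Probe order is preserved.
#'
#' @param matrix numeric matrix of log2 expression (probes x samples).
#' @param threshold a [estimate_detection_threshold()] result or a number.
#' @return The matrix restricted to detected probes.
#' @export
filter_detected <- function(matrix, threshold) {
  thr <- if (inherits(threshold, "detection_threshold")) threshold$value
         else threshold
  if (!is.finite(thr)) stop("threshold must be finite")
  keep <- apply(matrix, 1, max) > thr
  if (!any(keep)) warning("no probe exceeds the detection threshold")
  matrix[keep, , drop = FALSE]
}

#' Multi-loess (MA) normalization against a mean reference array
#'
#' Removes smooth intensity-dependent distortions by iterating over arrays:
#' for each array, `M = array - reference` and `A = (array + reference)/2`
#' with the reference the per-probe mean of all arrays; the loess fit of M on
#' A, centred on the consensus of all arrays' fits, is subtracted from the
#' array (the consensus component is common to every array, cancels in all
#' between-array contrasts, and keeping it out of the update keeps the mean
#' reference stable). The reference is recomputed each sweep and sweeps
#' repeat until the largest correction falls below `tol` or `max_iter`
#' sweeps have run. The loess fits use [stats::lowess()] (locally linear,
#' no robustness reweighting).
#'
#' @param matrix numeric matrix of log2 expression (probes x samples), at
#'   least two samples.
#' @param span lowess smoother span in `(0, 1]`.
#' @param max_iter maximum number of sweeps over all arrays.
#' @param tol convergence tolerance: largest absolute correction, log2 units.
#' @return The normalized matrix, with attributes `iterations` (sweeps
#'   applied to reach the returned state), `residual` (largest absolute
#'   fitted M against the final reference) and `converged`. When sweeps stop
#'   improving before reaching `tol` (typical for noisy data, where the
#'   corrections plateau at the intensity extremes), the best state reached
#'   is returned with a warning.
#' @examples
#' m <- matrix(rnorm(200, 8), ncol = 4)
#' norm <- multiloess_normalize(m)
#' attr(norm, "residual")
#' @export
multiloess_normalize <- function(matrix, span = 0.4, max_iter = 10,
                                 tol = 1e-3) {
  if (ncol(matrix) < 2) stop("need at least 2 arrays")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  x <- matrix
  iters <- 0L
  converged <- FALSE
  stall_sweeps <- 5L
  no_improve <- 0L
  best <- list(x = x, delta = Inf, residual = Inf, iters = 0L)
  ## Each sweep fits every array against one reference. The per-probe mean of
  ## the fits is a consensus component: subtracting it would warp all arrays
  ## identically (it cancels in every between-array contrast and in fold
  ## changes) while feeding back into the mean reference, so only each
  ## array's fit RELATIVE to that consensus is subtracted. Convergence is
  ## checked before subtracting, making a converged matrix an exact fixed
  ## point: re-normalizing it changes nothing. On noisy data the corrections
  ## eventually plateau instead of vanishing; the sweep with the smallest
  ## correction is kept, and iteration stops once sweeps stop improving.
  repeat {
    ref <- rowMeans(x)
    fits <- vapply(seq_len(ncol(x)),
                   function(j) .ma_loess_fit(x[, j], ref, span),
                   numeric(nrow(x)))
    changes <- fits - rowMeans(fits)
    delta <- max(abs(changes))
    if (delta < best$delta) {
      best <- list(x = x, delta = delta, residual = max(abs(fits)),
                   iters = iters)
      no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
    }
    if (delta < tol) { converged <- TRUE; break }
    if (iters >= max_iter || no_improve >= stall_sweeps) break
    x <- x - changes
    iters <- iters + 1L
  }
  if (converged) {
    best <- list(x = x, delta = delta, residual = max(abs(fits)),
                 iters = iters)
  } else {
    warning("multiloess did not converge (best correction ",
            signif(best$delta, 3), " after ", best$iters, " sweeps)")
  }
  out <- best$x
  attr(out, "iterations") <- best$iters
  attr(out, "residual") <- best$residual  # max |fitted M| vs final reference
  attr(out, "converged") <- converged
  out
}

# lowess fit of M = y - ref on A = (y + ref)/2, evaluated at every probe's A.
# Plain least-squares local fits (no robustness reweighting): with a minority
# of genuinely differential probes the robust reweighting interacts with the
# shared reference and can destabilize the sweep iteration on large arrays.
.ma_loess_fit <- function(y, ref, span) {
  A <- (y + ref) / 2
  M <- y - ref
  ## fine interpolation grid: lowess's default delta (1% of range) leaves
  ## piecewise-linear kinks ~1e-3 that block convergence below that scale
  lw <- stats::lowess(A, M, f = span, iter = 0, delta = diff(range(A)) / 1000)
  stats::approx(lw$x, lw$y, xout = A, rule = 2, ties = "ordered")$y
}
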