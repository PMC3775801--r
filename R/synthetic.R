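#' Generate a synthetic two-cohort expression study
#'
#' Emulates the statistical structure the downstream pipeline assumes: log2
#' expression equal to a per-probe baseline, plus a group effect on planted
#' genes (all HIV-positive cohorts, lesioned or not, carry the effect), plus a
#' per-array smooth monotone intensity distortion (a polynomial in the
#' baseline), plus Gaussian noise. A fraction of probes sits at a low
#' "undetected" floor in every sample, giving the detection threshold a valley
#' to find: baselines come from a two-mode mixture (narrow background mode,
#' broad expressed mode).
#'
#' Planted genes split into an upregulated fraction with linear fold changes
#' drawn from `up_range` (rod-like, defaults 2--5) and a downregulated rest
#' with magnitudes from `down_range` (cone-like, defaults 1.2--1.4, reported
#' with negative sign). Fold changes are linear-scale with the `|f| >= 1`
#' convention; the planted log2 group effect is `sign(f) * log2(|f|)`.
#'
#' @param design a [study_design()].
#' @param noise_sd Gaussian noise standard deviation on the log2 scale.
#'   Must be `>= 0`; 0 gives a noiseless study for exact-recovery checks.
#' @param distortion_degree degree of the per-array monotone polynomial
#'   distortion; 0 disables distortion, 3 (default) gives the cubic the
#'   normalizer is expected to remove.
#' @param distortion_sd scale of the random distortion coefficients.
#' @param floor_frac fraction (of `n_probes`) of additional undetected floor
#'   probes appended to the matrix.
#' @param de_frac fraction of genes planted as differentially expressed.
#' @param up_frac fraction of planted genes that are upregulated.
#' @param up_range,down_range linear fold-change magnitude ranges for
#'   up-/downregulated planted genes.
#' @param seed integer seed; all randomness flows from it.
#'
#' @return A list with components `matrix` (log2 expression, probes x
#'   samples), `meta` (data.frame: sample, group, lesion, tod, donor),
#'   `mapping` (data.frame: probe_id, gene_id), and `truth` (list: `de_genes`,
#'   `planted_f` named signed fold changes, `enriched_sets`).
#' @examples
#' st <- generate_study(study_design(n_neg = 4, n_pos = 4, n_cws = 0,
#'                                   n_irh = 0, n_probes = 200), seed = 1)
#' dim(st$matrix)
#' head(st$truth$planted_f)
#' @export
generate_study <- function(design, noise_sd = 0.5, distortion_degree = 3,
                           distortion_sd = 0.15, floor_frac = 0.25,
                           de_frac = 0.05, up_frac = 0.6,
                           up_range = c(2, 5), down_range = c(1.2, 1.4),
                           seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (distortion_degree < 0 || distortion_degree != round(distortion_degree))
    stop("distortion_degree must be a non-negative integer")
  if (any(up_range < 1) || any(down_range < 1))
    stop("fold magnitude ranges must be >= 1")
  set.seed(seed)

  n_expr <- design$n_probes
  n_floor <- round(floor_frac * n_expr)
  n_samp <- design$n_samples
  if (n_samp < 2) stop("design must have at least 2 samples")

  ## expressed baseline: broad right-skewed mode well above the floor, so the
  ## pooled log2 distribution is bimodal with a clean valley
  base_expr <- 7 + stats::rexp(n_expr, rate = 1 / 1.5)
  base_floor <- stats::rnorm(n_floor, mean = 2.5, sd = 0.3)
  baseline <- c(base_expr, base_floor)
  if (stats::sd(baseline) == 0) stop("degenerate constant baseline")

  ## probe/gene bookkeeping: probes_per_gene consecutive probes per gene
  n_genes <- ceiling(n_expr / design$probes_per_gene)
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  gene_of_probe <- rep(gene_ids, each = design$probes_per_gene)[seq_len(n_expr)]
  suffix <- stats::ave(seq_len(n_expr), gene_of_probe, FUN = seq_along)
  probe_ids <- c(paste0(gene_of_probe, "_p", suffix),
                 sprintf("FLOOR%05d", seq_len(n_floor)))

  ## planted truth
  n_de <- round(de_frac * n_genes)
  de_genes <- sort(sample(gene_ids, n_de))
  n_up <- round(up_frac * n_de)
  up_genes <- de_genes[seq_len(n_up)]
  f_up <- stats::runif(n_up, up_range[1], up_range[2])
  f_dn <- -stats::runif(n_de - n_up, down_range[1], down_range[2])
  planted_f <- c(f_up, f_dn)
  names(planted_f) <- de_genes

  ## per-probe log2 group effect (positive cohorts only)
  effect <- numeric(n_expr + n_floor)
  planted_probe <- gene_of_probe %in% de_genes
  effect[seq_len(n_expr)][planted_probe] <-
    sign(planted_f[gene_of_probe[planted_probe]]) *
    log2(abs(planted_f[gene_of_probe[planted_probe]]))

  group <- c(rep("neg", design$n_neg), rep("pos", design$n_pos),
             rep("cws", design$n_cws), rep("irh", design$n_irh))
  lesion <- c(rep("none", design$n_neg + design$n_pos),
              rep("CWS", design$n_cws), rep("IRH", design$n_irh))
  is_pos <- group != "neg"

  tod <- design$tod
  if (is.null(tod)) {
    tod <- numeric(n_samp)
    tod[!is_pos] <- .draw_tod(sum(!is_pos), 12.5, 6.8)
    tod[is_pos] <- .draw_tod(sum(is_pos), 11.0, 7.1)
  }

  values <- matrix(baseline, nrow = n_expr + n_floor, ncol = n_samp)
  values <- values + outer(effect, as.numeric(is_pos))

  ## per-array monotone polynomial distortion, evaluated at the baseline
  if (distortion_degree > 0) {
    z <- (baseline - mean(baseline)) / stats::sd(baseline)
    for (j in seq_len(n_samp)) {
      values[, j] <- values[, j] +
        .monotone_poly_distortion(z, distortion_degree, distortion_sd)
    }
  }
  if (noise_sd > 0)
    values <- values + matrix(stats::rnorm(length(values), 0, noise_sd),
                              nrow = nrow(values))

  sample_ids <- sprintf("S%02d", seq_len(n_samp))
  dimnames(values) <- list(probe_ids, sample_ids)
  meta <- data.frame(sample = sample_ids, group = group, lesion = lesion,
                     tod = tod, donor = sprintf("D%02d", seq_len(n_samp)),
                     stringsAsFactors = FALSE)
  mapping <- data.frame(probe_id = probe_ids,
                        gene_id = c(gene_of_probe,
                                    sprintf("FLOORG%05d", seq_len(n_floor))),
                        stringsAsFactors = FALSE)
  list(matrix = values, meta = meta, mapping = mapping,
       truth = list(de_genes = de_genes, planted_f = planted_f,
                    enriched_sets = character(0)))
}

# Random distortion curve d(u) = sum_d c_d u^d with u the baseline rescaled
# to [-1, 1], resampled until x + d(u(x)) is monotone increasing on the
# observed range. Bounding |u| keeps every term at the coef_sd scale, so the
# curve is a gentle intensity-dependent warp rather than a tail blow-up.
.monotone_poly_distortion <- function(z, degree, coef_sd) {
  u <- z / max(abs(z))
  grid <- seq(min(u), max(u), length.out = 200)
  span_x <- diff(range(z))
  repeat {
    co <- stats::rnorm(degree, 0, coef_sd)
    fit <- grid * span_x / diff(range(u)) +
      drop(outer(grid, seq_len(degree), `^`) %*% co)
    if (all(diff(fit) > 0))
      return(drop(outer(u, seq_len(degree), `^`) %*% co))
  }
}

#' Generate a gene-set collection with controllable overlap
#'
#' Draws `n_sets` gene sets over `universe`. With `overlap_rate = 0` sets are
#' independent uniform draws; as `overlap_rate` approaches 1 sets draw an
#' increasing fraction of their members from a fixed shared core (the first
#' members of which are taken deterministically), so that at `overlap_rate =
#' 1` equal-sized sets are identical. This mimics the heavy member sharing of
#' ontology-derived collections.
#'
#' @param universe character vector of gene identifiers.
#' @param n_sets number of sets to draw.
#' @param size_range integer pair `(min, max)` of set sizes.
#' @param overlap_rate number in `[0, 1]` controlling shared membership.
#' @param seed integer seed.
#' @return A named list of character vectors (class `"geneset_collection"`).
#' @examples
#' gs <- generate_geneset_collection(sprintf("G%03d", 1:100), n_sets = 3,
#'                                   size_range = c(5, 10), seed = 1)
#' lengths(gs)
#' @export
generate_geneset_collection <- function(universe, n_sets,
                                        size_range = c(10, 50),
                                        overlap_rate = 0, seed = 1L) {
  if (length(universe) == 0) stop("empty universe")
  if (anyDuplicated(universe)) stop("universe ids must be unique")
  if (size_range[1] > size_range[2]) stop("size_range inverted")
  if (size_range[2] > length(universe)) stop("max set size exceeds universe")
  if (overlap_rate < 0 || overlap_rate > 1) stop("overlap_rate not in [0,1]")
  if (n_sets < 1) stop("n_sets must be positive")
  set.seed(seed)
  core <- sample(universe, size_range[2])
  sets <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    size <- if (size_range[1] == size_range[2]) size_range[1] else
      sample(seq(size_range[1], size_range[2]), 1)
    k <- round(overlap_rate * size)
    shared <- core[seq_len(k)]
    rest <- sample(setdiff(universe, shared), size - k)
    sets[[i]] <- sort(c(shared, rest))
  }
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  structure(sets, class = "geneset_collection")
}

#' Generate a synthetic qPCR table with an optional diurnal harmonic
#'
#' Produces per-sample Ct values for target transcripts and a reference gene.
#' Log2 relative abundance of each target follows
#' `baseline + group effect + amplitude * cos(2*pi*(tod - phase)/24) + noise`;
#' the target Ct is the reference Ct minus that log2 abundance, so
#' [relative_abundance()] recovers it. The default amplitude is 0: the study
#' conditions this emulates showed no evident diurnal rhythm, and the harmonic
#' is there to power the confound check, not to assert a rhythm.
#'
#' @param design a [study_design()] (only sample counts and TOD are used).
#' @param amplitude diurnal amplitude in log2 units, `>= 0`.
#' @param phase hour of peak abundance.
#' @param noise_sd Gaussian noise sd on log2 abundance.
#' @param genes target transcript names.
#' @param group_fold named signed linear fold change of each target in the
#'   positive cohorts (defaults mirror rod upregulation and cone
#'   downregulation).
#' @param target_base named baseline log2 abundance of each target relative to
#'   the reference gene.
#' @param reference reference gene name.
#' @param seed integer seed.
#' @return data.frame with columns sample, gene, ct, tod, group.
#' @export
generate_qpcr <- function(design, amplitude = 0, phase = 6, noise_sd = 0.25,
                          genes = c("RHO", "OPN1SW", "CRYBB2"),
                          group_fold = c(RHO = 4.4, OPN1SW = -1.4,
                                         CRYBB2 = 1.8),
                          target_base = c(RHO = -2, OPN1SW = -6, CRYBB2 = -4),
                          reference = "GAPDH", seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  if (amplitude < 0) stop("amplitude must be non-negative")
  set.seed(seed)
  n <- design$n_samples
  group <- c(rep("neg", design$n_neg),
             rep("pos", design$n_pos + design$n_cws + design$n_irh))
  tod <- design$tod
  if (is.null(tod)) {
    tod <- numeric(n)
    tod[group == "neg"] <- .draw_tod(sum(group == "neg"), 12.5, 6.8)
    tod[group == "pos"] <- .draw_tod(sum(group == "pos"), 11.0, 7.1)
  }
  sample_ids <- sprintf("Q%02d", seq_len(n))
  ct_ref <- stats::rnorm(n, 20, 0.3)
  rows <- list(data.frame(sample = sample_ids, gene = reference, ct = ct_ref,
                          tod = tod, group = group, stringsAsFactors = FALSE))
  for (g in genes) {
    eff <- if (g %in% names(group_fold))
      ifelse(group == "pos",
             sign(group_fold[[g]]) * log2(abs(group_fold[[g]])), 0)
    else 0
    base <- if (g %in% names(target_base)) target_base[[g]] else -3
    l2 <- base + eff + amplitude * cos(2 * pi * (tod - phase) / 24) +
      stats::rnorm(n, 0, noise_sd)
    rows[[length(rows) + 1]] <-
      data.frame(sample = sample_ids, gene = g, ct = ct_ref - l2,
                 tod = tod, group = group, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
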