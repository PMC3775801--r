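test_that("noiseless distortion-free generation plants exact group effects", {
  des <- study_design(n_neg = 4, n_pos = 4, n_cws = 0, n_irh = 0,
                      n_probes = 300)
  st <- generate_study(des, noise_sd = 0, distortion_degree = 0, seed = 11)
  g <- st$meta$group
  diff <- rowMeans(st$matrix[, g == "pos"]) - rowMeans(st$matrix[, g == "neg"])
  for (gene in st$truth$de_genes) {
    probes <- st$mapping$probe_id[st$mapping$gene_id == gene]
    f <- st$truth$planted_f[[gene]]
    expect_equal(unname(diff[probes]), rep(sign(f) * log2(abs(f)),
                                           length(probes)),
                 tolerance = 1e-12)
  }
  # non-planted expressed probes carry no effect
  null_probes <- setdiff(st$mapping$probe_id[st$mapping$gene_id %in%
                                             setdiff(st$mapping$gene_id,
                                                     st$truth$de_genes)],
                         grep("^FLOOR", rownames(st$matrix), value = TRUE))
  expect_true(all(abs(diff[null_probes]) < 1e-12))
})

test_that("generation is bit-identical for a fixed seed", {
  des <- study_design(n_neg = 3, n_pos = 3, n_cws = 2, n_irh = 2,
                      n_probes = 150)
  a <- generate_study(des, seed = 5)
  b <- generate_study(des, seed = 5)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)
  c <- generate_study(des, seed = 6)
  expect_false(identical(a$matrix, c$matrix))
})

test_that("paper-shaped design yields 17 columns and all expressed probes detected", {
  # scaled-down probe count, full sample layout of the pos-vs-neg comparison
  des <- study_design(n_neg = 7, n_pos = 10, n_cws = 0, n_irh = 0,
                      n_probes = 3000)
  st <- generate_study(des, seed = 21)
  expect_equal(ncol(st$matrix), 17)
  expect_equal(nrow(st$matrix), 3000 + round(0.25 * 3000))
  thr <- estimate_detection_threshold(st$matrix)
  det <- filter_detected(st$matrix, thr)
  expect_equal(nrow(det), 3000)
  expect_false(any(grepl("^FLOOR", rownames(det))))
})

test_that("probes_per_gene expands probes with gene-derived ids", {
  des <- study_design(n_neg = 2, n_pos = 2, n_cws = 0, n_irh = 0,
                      n_probes = 60, probes_per_gene = 3)
  st <- generate_study(des, seed = 2)
  map <- st$mapping[!grepl("^FLOOR", st$mapping$probe_id), ]
  expect_equal(length(unique(map$gene_id)), 20)
  expect_true(all(table(map$gene_id) == 3))
  expect_true(all(startsWith(map$probe_id, map$gene_id)))
})

test_that("study_design validates its inputs", {
  expect_error(study_design(n_neg = -1), "non-negative")
  expect_error(study_design(n_probes = 0), "positive")
  expect_error(study_design(n_neg = 2, n_pos = 2, n_cws = 0, n_irh = 0,
                            tod = c(1, 2)), "one entry per sample")
  expect_error(generate_study(study_design(), noise_sd = -1), "non-negative")
})

test_that("gene-set collections honour size and overlap controls", {
  u <- sprintf("G%04d", 1:1000)
  one <- generate_geneset_collection(u, n_sets = 1, size_range = c(5, 5),
                                     seed = 1)
  expect_length(one[[1]], 5)
  expect_true(all(one[[1]] %in% u))

  # overlap 1: equal-size sets share identical membership
  full <- generate_geneset_collection(u, n_sets = 2, size_range = c(8, 8),
                                      overlap_rate = 1, seed = 2)
  expect_identical(full[[1]], full[[2]])

  # overlap 0: intersections at binomial chance level (<= 2 in >= 95% of seeds)
  small <- vapply(1:100, function(s) {
    gs <- generate_geneset_collection(u, n_sets = 2, size_range = c(5, 5),
                                      overlap_rate = 0, seed = s)
    length(intersect(gs[[1]], gs[[2]]))
  }, integer(1))
  expect_gte(mean(small <= 2), 0.95)

  expect_error(generate_geneset_collection(u, 2, size_range = c(9, 5)),
               "inverted")
  expect_error(generate_geneset_collection(character(0), 1, c(1, 1)),
               "empty universe")
})

test_that("qPCR generator places the cosine peak and respects amplitude 0", {
  tod <- seq(0, 23.5, length.out = 24) %% 24
  des <- study_design(n_neg = 12, n_pos = 12, n_cws = 0, n_irh = 0,
                      n_probes = 10, tod = tod)
  qp <- generate_qpcr(des, amplitude = 1, phase = 6, noise_sd = 0,
                      group_fold = c(), seed = 3)
  ref <- qp[qp$gene == "GAPDH", ]
  rho <- qp[qp$gene == "RHO", ]
  ab <- relative_abundance(rho$ct, ref$ct[match(rho$sample, ref$sample)])
  expect_equal(rho$tod[which.max(ab)], tod[which.min(abs(tod - 6))])

  qp0 <- generate_qpcr(des, amplitude = 0, noise_sd = 0, group_fold = c(),
                       seed = 3)
  rho0 <- qp0[qp0$gene == "RHO", ]
  ab0 <- relative_abundance(rho0$ct,
                            qp0$ct[qp0$gene == "GAPDH"][match(rho0$sample,
                              qp0$sample[qp0$gene == "GAPDH"])])
  expect_equal(diff(range(log2(ab0))), 0, tolerance = 1e-12)
  expect_error(generate_qpcr(des, amplitude = -1), "non-negative")
})

test_that("drawn times of death track the autopsy cohort targets", {
  des <- study_design(n_neg = 0, n_pos = 15, n_cws = 0, n_irh = 0,
                      n_probes = 10)
  set.seed(99)
  tods <- replicate(40, {
    qp <- generate_qpcr(des, seed = sample.int(1e6, 1))
    qp$tod[qp$gene == "GAPDH"]
  })
  expect_true(all(tods >= 0 & tods < 24))
  # target 11.0 +/- 7.1 before day-truncation; allow truncation shrinkage
  expect_equal(mean(tods), 11.0, tolerance = 0.15)
  expect_gt(sd(as.numeric(tods)), 4.5)
  expect_lt(sd(as.numeric(tods)), 7.5)
})
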