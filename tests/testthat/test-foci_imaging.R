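test_that("segmentation handles blanks, disk grids and touching nuclei", {
  blank <- micrograph(matrix(0, 60, 60), matrix(0, 60, 60))
  expect_warning(lab <- segment_nuclei(blank), "blank")
  expect_equal(max(lab), 0)

  # grid of non-overlapping disks -> one label each
  m <- matrix(0, 200, 200)
  centers <- expand.grid(r = c(30, 100, 170), c = c(30, 100, 170))
  for (i in seq_len(nrow(centers)))
    m <- draw_disk(m, centers$r[i], centers$c[i], 14)
  img <- micrograph(m, matrix(0, 200, 200))
  lab <- segment_nuclei(img)
  expect_equal(max(lab), 9)

  # two touching disks are split by the distance-transform watershed
  m2 <- matrix(0, 80, 120)
  m2 <- draw_disk(m2, 40, 45, 16)
  m2 <- draw_disk(m2, 40, 75, 16)   # centres 30 px apart, radii 16: touching
  img2 <- micrograph(m2, matrix(0, 80, 120))
  lab2 <- segment_nuclei(img2)
  expect_equal(max(lab2), 2)
})

test_that("focus detection: blanks give zero, counts track truth", {
  m <- draw_disk(matrix(0, 90, 90), 45, 45, 30)
  img <- micrograph(m, matrix(0, 90, 90))
  lab <- segment_nuclei(img)
  ft <- detect_foci(img, lab)
  expect_equal(ft$focus_count, 0)
  expect_error(detect_foci(img, matrix(0L, 10, 10)), "shape mismatch")
})

test_that("detection recall and precision exceed 0.9 on synthetic truth", {
  sim <- gen_micrographs(rng_seed = 5, n_nuclei = 30, foci_mean = 10,
                         foci_sd = 4, nucleus_radius_px = 30)
  tp <- 0; n_det <- 0
  pos_all <- sim$positions
  for (i in seq_along(sim$micrographs)) {
    img <- sim$micrographs[[i]]
    ft <- detect_foci(img, segment_nuclei(img))
    det <- attr(ft, "foci")
    n_det <- n_det + nrow(det)
    pos <- pos_all[pos_all$image == i, ]
    for (j in seq_len(nrow(det))) {
      d2 <- (pos$row0 - det$row0[j])^2 + (pos$col0 - det$col0[j])^2
      k <- which.min(d2)
      if (length(k) && d2[k] <= 9) { tp <- tp + 1; pos <- pos[-k, ] }
    }
  }
  recall <- tp / nrow(pos_all)
  precision <- tp / n_det
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("detected counts are invariant to global intensity scaling", {
  sim <- gen_micrographs(rng_seed = 11, n_nuclei = 8, foci_mean = 20,
                         foci_sd = 8, nucleus_radius_px = 25,
                         nuclei_per_image = 8)
  img <- sim$micrographs[[1]]
  lab <- segment_nuclei(img)
  f1 <- detect_foci(img, lab)
  img_scaled <- micrograph(img$nucleus, img$foci * 7.3)
  f2 <- detect_foci(img_scaled, lab)
  expect_identical(f1$focus_count, f2$focus_count)
})

test_that("uniformly bright nuclei are flagged pan-nuclear and excluded", {
  m <- matrix(0, 90, 180)
  m <- draw_disk(m, 45, 45, 25)
  m <- draw_disk(m, 45, 135, 25)
  set.seed(2)
  f <- matrix(rnorm(90 * 180, 100, 5), 90, 180)
  # nucleus 1: uniform pan staining; nucleus 2: three discrete foci
  f <- draw_disk(f, 45, 45, 25, value = 180)
  for (cc in c(120, 135, 150))
    f <- f + 80 * exp(-(outer((1:90 - 45)^2, rep(1, 180)) +
                          outer(rep(1, 90), (1:180 - cc)^2)) / 8)
  img <- micrograph(m, pmax(f, 0))
  lab <- segment_nuclei(img)
  ft <- detect_foci(img, lab)
  pan_id <- ft$nucleus_id[ft$pan_nuclear]
  norm_id <- ft$nucleus_id[!ft$pan_nuclear]
  expect_length(pan_id, 1)
  expect_true(is.na(ft$focus_count[ft$nucleus_id == pan_id]))
  expect_equal(ft$focus_count[ft$nucleus_id == norm_id], 3)
})

test_that("mean detected count tracks the generating mean across seeds", {
  rel_err <- vapply(1:5, function(s) {
    sim <- gen_micrographs(rng_seed = 100 + s, n_nuclei = 20,
                           foci_mean = 42, foci_sd = 14,
                           nucleus_radius_px = 30, nuclei_per_image = 20)
    img <- sim$micrographs[[1]]
    ft <- detect_foci(img, segment_nuclei(img))
    mean(ft$focus_count, na.rm = TRUE) / mean(sim$truth$true_count) - 1
  }, numeric(1))
  expect_lt(max(abs(rel_err)), 0.1)
})

test_that("group summaries run Welch/Dunnett-style comparisons", {
  mk_tab <- function(counts, cond) {
    data.frame(nucleus_id = seq_along(counts), area_px = 2500,
               focus_count = counts, pan_nuclear = FALSE,
               condition = cond, time_h = 72)
  }
  set.seed(6)
  a <- mk_tab(rnbinom(50, mu = 15, size = 15^2 / (9.7^2 - 15)), "control")
  # identical groups: no difference
  same <- summarize_foci(list(a, transform(a, condition = "copy")))
  expect_equal(same$comparisons$diff, 0)
  expect_gt(same$comparisons$p_value, 0.99)

  # treated vs control at the reported 72-h moments: clearly separated
  b <- mk_tab(rnbinom(50, mu = 42, size = 42^2 / (14^2 - 42)), "treated")
  cmp <- summarize_foci(list(a, b), control = "control")
  expect_lt(cmp$comparisons$p_value, 1e-4)

  # three groups, one shifted: only the shifted one flagged
  c0 <- mk_tab(rnbinom(60, mu = 15, size = 16), "groupB")
  d0 <- mk_tab(rnbinom(60, mu = 40, size = 16), "groupC")
  multi <- summarize_foci(list(a, c0, d0), control = "control")
  flags <- multi$comparisons$p_adj < 0.01
  expect_identical(multi$comparisons$group[flags], "groupC")
  expect_lt(multi$omnibus$p.value, 0.001)

  # small groups are excluded with a warning
  tiny <- mk_tab(c(5, 6), "tiny")
  expect_warning(summarize_foci(list(a, b, tiny)), "excluding group")
})
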