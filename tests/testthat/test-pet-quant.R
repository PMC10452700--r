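test_that("SUV conversion follows the body-weight formula", {
  expect_equal(compute_suv(1000, 1e5, 20), 0.2)
  expect_equal(compute_suv(array(0, c(2, 2, 2)), 1e5, 20),
               array(0, c(2, 2, 2)))
  # study-scale dose: 3.68 MBq, 20 g mouse, 184 kBq/mL concentration
  expect_equal(compute_suv(184000, 3.68e6, 20), 1.0)
  expect_error(compute_suv(1000, 0, 20), "injected_activity")
  expect_error(compute_suv(1000, 1e5, -1), "body_weight")
  expect_error(compute_suv(-5, 1e5, 20), ">= 0")
})

make_study <- function(suv_vals, tumor_idx, muscle_idx, dims = c(4L, 4L, 4L)) {
  suv <- array(suv_vals, dims)
  tm <- array(FALSE, dims); tm[tumor_idx] <- TRUE
  mm <- array(FALSE, dims); mm[muscle_idx] <- TRUE
  pet_study(suv, tm, mm)
}

test_that("pet_study validates masks and SUV sign", {
  expect_error(make_study(-1, 1:3, 10:12), "negative")
  expect_error(make_study(1, integer(0), 10:12), "tumor mask is empty")
  expect_error(make_study(1, 1:3, 3:5), "disjoint")
})

test_that("ROI summaries match hand values and a brute-force loop", {
  st <- make_study(seq(0.1, by = 0.1, length.out = 64), 4:6, 10:12)
  s <- roi_summary(st, "tumor")  # voxels 0.4, 0.5, 0.6
  expect_equal(s$mean, 0.5)
  expect_equal(s$max, 0.6)
  expect_equal(s$n_voxels, 3L)
  expect_equal(s$sd, sd(c(0.4, 0.5, 0.6)))

  set.seed(14)
  dims <- c(8L, 8L, 8L)
  suv <- array(runif(512, 0, 3), dims)
  mask_idx <- sample(512, 100)
  st2 <- make_study(suv, mask_idx, setdiff(seq_len(512), mask_idx)[1:20],
                    dims = dims)
  s2 <- roi_summary(st2, "tumor")
  oracle <- brute_roi_stats(st2$suv, st2$tumor_mask)
  expect_equal(s2$mean, oracle$mean)
  expect_equal(s2$sd, oracle$sd)
  expect_equal(s2$max, oracle$max)
  expect_equal(s2$n_voxels, oracle$n)
})

test_that("single-voxel ROI reports sd 0 with a degenerate warning", {
  st <- make_study(1:64 / 10, 5, 10:12)
  expect_warning(s <- roi_summary(st, "tumor"), "degenerate")
  expect_equal(s$sd, 0)
  expect_equal(s$n_voxels, 1L)
})

test_that("proliferative threshold is muscle mean plus k standard deviations", {
  m <- pethet:::suv_summary(mean = 0.5, sd = 0.1, max = 0.8, n_voxels = 50L)
  expect_equal(proliferative_threshold(m), 0.7)
  expect_equal(proliferative_threshold(m, sd_multiplier = 0), 0.5)
  m2 <- pethet:::suv_summary(0.45, 0.075, 0.8, 50L)
  expect_equal(proliferative_threshold(m2), 0.6)
  m3 <- pethet:::suv_summary(0.5, 0, 0.5, 10L)
  expect_equal(proliferative_threshold(m3), 0.5)
  m1 <- pethet:::suv_summary(0.5, 0, 0.5, 1L)
  expect_error(proliferative_threshold(m1), "fewer than 2")
})

test_that("voxel classification is inclusive at the threshold and partitions the tumor", {
  st <- make_study(c(0.4, 0.7, 1.2, rep(0, 61)), 1:3, 10:12)
  cls <- classify_voxels(st, 0.7)
  expect_equal(sum(cls$proliferative_mask), 2L)  # 0.7 itself counts
  expect_equal(cls$proliferative_fraction, 2 / 3)
  expect_identical(cls$proliferative_mask | cls$necrotic_mask, st$tumor_mask)
  expect_false(any(cls$proliferative_mask & cls$necrotic_mask))
  expect_true(all(st$suv[cls$proliferative_mask] >= 0.7))

  above <- classify_voxels(st, 2)
  expect_true(above$empty)
  expect_equal(above$proliferative_fraction, 0)
  expect_null(above$proliferative_summary)
})

test_that("classification labels equal a brute-force voxel loop on a phantom", {
  ph <- small_phantom(seed = 17)
  cls <- classify_voxels(ph$study, 0.6)
  expect_identical(cls$proliferative_mask,
                   brute_classify(ph$study$suv, ph$study$tumor_mask, 0.6))
})

test_that("thresholding can only raise the mean above the whole-tumor mean", {
  ph <- small_phantom(seed = 23)
  tumor_mean <- mean(ph$study$suv[ph$study$tumor_mask])
  for (thr in c(0.3, 0.6, 0.9)) {
    cls <- classify_voxels(ph$study, thr)
    if (!cls$empty && sum(cls$necrotic_mask) > 0) {
      expect_gte(cls$proliferative_summary$mean, tumor_mean)
    }
  }
})

test_that("quantify_study composes the chain with a per-scan threshold", {
  ph <- generate_phantom(phantom_spec(seed = 31))
  q <- quantify_study(ph$study)
  expect_equal(q$threshold, 0.6, tolerance = 0.02)  # 0.5 + 2 x 0.05, MC error
  expect_equal(q$threshold, q$muscle$mean + 2 * q$muscle$sd)
  expect_equal(q$classification$proliferative_fraction,
               sum(q$classification$proliferative_mask) / q$tumor$n_voxels)

  # uniform tumor entirely above threshold: thresholded mean = tumor mean
  st <- make_study(c(rep(2, 3), rep(0.5, 61)), 1:3, 10:12)
  q2 <- quantify_study(st)
  expect_equal(q2$classification$proliferative_summary$mean, q2$tumor$mean)
  expect_equal(q2$classification$proliferative_fraction, 1)
})

test_that("treatment suppression lowers the thresholded mean SUV", {
  qs <- lapply(c(1, 0.5), function(s) {
    ph <- generate_phantom(phantom_spec(seed = 19, suppression = s))
    quantify_study(ph$study)
  })
  expect_lt(qs[[2]]$classification$proliferative_summary$mean,
            qs[[1]]$classification$proliferative_summary$mean)
})
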