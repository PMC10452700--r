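test_that("phantom masks partition the tumor and stay clear of muscle", {
  for (frac in c(0.3, 0.45, 0.6)) {
    ph <- small_phantom(seed = 42, necrotic_fraction = frac)
    tumor <- ph$study$tumor_mask
    expect_false(any(ph$truth$necrotic_mask & ph$truth$viable_mask))
    expect_identical(ph$truth$necrotic_mask | ph$truth$viable_mask, tumor)
    expect_false(any(tumor & ph$study$muscle_mask))
  }
})

test_that("zero necrotic fraction degenerates to an all-viable tumor", {
  ph <- small_phantom(seed = 3, necrotic_fraction = 0)
  expect_identical(ph$truth$viable_mask, ph$study$tumor_mask)
  expect_false(any(ph$truth$necrotic_mask))
  expect_equal(ph$truth$true_proliferative_fraction, 1)
})

test_that("identical seed reproduces the phantom bit-for-bit", {
  a <- generate_phantom(phantom_spec(seed = 7))
  b <- generate_phantom(phantom_spec(seed = 7))
  expect_identical(a$study$suv, b$study$suv)
  expect_identical(a$study$tumor_mask, b$study$tumor_mask)
  expect_identical(a$truth, b$truth)
  c <- generate_phantom(phantom_spec(seed = 8))
  expect_false(identical(a$study$suv, c$study$suv))
})

test_that("realized necrotic fraction tracks the spec for large tumors", {
  ph <- generate_phantom(phantom_spec(seed = 5, necrotic_fraction = 0.37))
  n_tumor <- sum(ph$study$tumor_mask)
  expect_gt(n_tumor, 10000)
  realized <- sum(ph$truth$necrotic_mask) / n_tumor
  expect_lt(abs(realized - 0.37), 0.02)
})

test_that("each region's sample mean is within 3 SE of its specification", {
  spec <- phantom_spec(seed = 11, necrotic_suv_mean = 0.4,
                       necrotic_suv_sd = 0.05, viable_suv_mean = 1.2,
                       viable_suv_sd = 0.2, muscle_suv_mean = 0.5,
                       muscle_suv_sd = 0.05)
  ph <- generate_phantom(spec)
  check <- function(mask, mean, sd) {
    n <- sum(mask)
    expect_lt(abs(mean(ph$study$suv[mask]) - mean), 3 * sd / sqrt(n))
  }
  check(ph$truth$necrotic_mask, 0.4, 0.05)
  check(ph$truth$viable_mask, 1.2, 0.2)
  check(ph$study$muscle_mask, 0.5, 0.05)
})

test_that("suppression scales only the viable rim", {
  full <- small_phantom(seed = 9, suppression = 1)
  half <- small_phantom(seed = 9, suppression = 0.5)
  v <- full$truth$viable_mask
  n <- full$truth$necrotic_mask
  expect_lt(mean(half$study$suv[v]), mean(full$study$suv[v]))
  expect_equal(mean(half$study$suv[n]), mean(full$study$suv[n]), tolerance = 1e-12)
})

test_that("invalid phantom specs and undersized grids are rejected", {
  expect_error(phantom_spec(necrotic_fraction = 1.2), "necrotic_fraction")
  expect_error(phantom_spec(suppression = 0), "suppression")
  expect_error(phantom_spec(viable_suv_sd = -1), "viable_suv_sd")
  expect_error(generate_phantom(phantom_spec(grid_shape = c(4L, 4L, 4L))),
               "grid too small")
})

test_that("longitudinal series share geometry and vary only uptake", {
  spec <- phantom_spec(seed = 21, grid_shape = c(20L, 20L, 20L))
  series <- generate_longitudinal_study(
    spec, data.frame(day = c(0L, 10L), suppression = c(1, 0.6)))
  expect_length(series, 2L)
  expect_identical(series[[1]]$tumor_mask, series[[2]]$tumor_mask)
  expect_identical(series[[1]]$muscle_mask, series[[2]]$muscle_mask)
  expect_identical(vapply(series, function(s) s$day, 0L), c(0L, 10L))
  truth <- attr(series, "truth")
  v <- truth$viable_mask
  expect_lt(mean(series[[2]]$suv[v]), mean(series[[1]]$suv[v]))
})

test_that("longitudinal validation rejects bad designs", {
  spec <- phantom_spec(seed = 1, grid_shape = c(20L, 20L, 20L))
  expect_error(generate_longitudinal_study(spec, data.frame()), "at least one")
  expect_error(generate_longitudinal_study(
    spec, data.frame(day = c(0, 0), suppression = c(1, 1))),
    "strictly increasing")
  expect_error(generate_longitudinal_study(
    spec, data.frame(day = c(0, 10), suppression = c(1, 1.5))),
    "suppression")
})

test_that("no-treatment longitudinal series shows no distribution shift", {
  spec <- phantom_spec(seed = 33, grid_shape = c(20L, 20L, 20L))
  series <- generate_longitudinal_study(
    spec, data.frame(day = c(0L, 10L), suppression = c(1, 1)))
  a <- series[[1]]$suv[series[[1]]$tumor_mask]
  b <- series[[2]]$suv[series[[2]]$tumor_mask]
  ks <- ks_two_sample(a, b)
  n <- length(a)
  crit_01 <- sqrt(-log(0.01 / 2) / 2) * sqrt(2 / n)
  expect_lt(ks$distance, crit_01)
})

test_that("growth cohort generator honors enrollment window, arms, and noise", {
  tab <- generate_growth_cohort(seed = 4)
  base <- tab[tab$day == 0, ]
  expect_true(all(base$volume >= 125 & base$volume <= 300))
  expect_identical(attr(tab, "arms"),
                   c("vehicle", "trastuzumab", "niraparib", "combination"))
  expect_equal(tab$volume, caliper_volume(tab$L1, tab$L2), tolerance = 1e-9)
  expect_identical(tab, generate_growth_cohort(seed = 4))

  flat <- generate_growth_cohort(
    seed = 1, arms = data.frame(name = "a", mean_pct_change = 0,
                                sd_pct_change = 0), n_per_arm = 3)
  pct <- pethet:::percent_change_table(flat)
  expect_equal(pct$pct_change, rep(0, nrow(pct)), tolerance = 1e-9)
})

test_that("plate generator is seeded, replicated, and needs a control", {
  plate <- generate_plate(seed = 2)
  expect_identical(plate, generate_plate(seed = 2))
  expect_equal(sum(plate$condition == "control"), 5L)
  expect_true("combination" %in% plate$condition)
  expect_equal(default_plate_conditions()$mean_signal_fraction[4], 0.42)

  noiseless <- generate_plate(seed = 1, conditions = data.frame(
    label = c("control", "x"), mean_signal_fraction = c(1, 1), sd = c(0, 0)))
  ps <- percent_survival(noiseless$signal[noiseless$condition == "x"],
                         noiseless$signal[noiseless$condition == "control"])
  expect_equal(ps$percent, 100)

  expect_error(generate_plate(seed = 1, conditions = data.frame(
    label = "x", mean_signal_fraction = 1, sd = 0)), "control")
  expect_error(generate_plate(seed = 1, conditions = data.frame(
    label = "control", mean_signal_fraction = -1, sd = 0)),
    "mean_signal_fraction")
})
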