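# synthetic phantom / cohort generator

test_that("make_phantom geometry matches the brute-force voxel-center oracle", {
  spec <- small_spec()
  ph <- make_phantom(spec)
  expect_equal(sum(ph$rois$masks$lesion),
               sphere_count_oracle(spec$grid_shape, spec$lesion_center,
                                   spec$lesion_radius))
  # every lesion voxel lies in exactly one hemisphere
  in_ipsi <- ph$rois$masks$lesion & ph$rois$masks$ipsi_hemisphere
  in_contra <- ph$rois$masks$lesion & ph$rois$masks$contra_hemisphere
  expect_equal(sum(in_ipsi) + sum(in_contra), sum(ph$rois$masks$lesion))
  expect_false(any(in_ipsi & in_contra))
  # T2 values: lesion prolonged, elsewhere background
  expect_true(all(ph$t2_map$data[ph$rois$masks$lesion] == spec$t2_lesion))
  expect_true(all(ph$t2_map$data[!ph$rois$masks$lesion] == spec$t2_background))
})

test_that("degenerate lesion radius gives an empty mask and uniform T2", {
  ph <- make_phantom(small_spec(lesion_radius = 0))
  expect_equal(sum(ph$rois$masks$lesion), 0L)
  expect_equal(length(unique(as.vector(ph$t2_map$data))), 1L)
})

test_that("phantom geometry violations are rejected naming the structure", {
  expect_error(small_spec(lesion_center = c(30, 18, 4)), "lesion sphere")
  expect_error(small_spec(lesion_center = c(18, 18, 4)), "midline")
  expect_error(small_spec(cc_box = list(from = c(10, 10, 3),
                                        to = c(40, 12, 6))),
               "corpus callosum")
  expect_error(small_spec(t2_lesion = 40), "t2_lesion")
})

test_that("simulate_multiecho produces mono-exponential decay", {
  t2 <- vol3d(array(50, c(2, 2, 2)))
  s0 <- vol3d(array(1000, c(2, 2, 2)))
  se <- simulate_multiecho(t2, s0, echo_times = c(25, 50, 75), noise_sigma = 0)
  expect_equal(se$data[1, 1, 1, 2], 1000 * exp(-1), tolerance = 1e-12)
  # strictly decreasing across echoes wherever S0 > 0
  sig <- matrix(se$data, ncol = 3)
  expect_true(all(sig[, 1] > sig[, 2] & sig[, 2] > sig[, 3]))
  expect_error(simulate_multiecho(t2, s0, echo_times = c(50, 25)),
               "strictly increasing")
})

test_that("simulate_multiecho is reproducible under a fixed seed", {
  ph <- make_phantom(small_spec())
  a <- simulate_multiecho(ph$t2_map, ph$s0_map, noise_sigma = 15, seed = 11)
  b <- simulate_multiecho(ph$t2_map, ph$s0_map, noise_sigma = 15, seed = 11)
  c <- simulate_multiecho(ph$t2_map, ph$s0_map, noise_sigma = 15, seed = 12)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("add_rician_noise follows the magnitude-MRI model", {
  v <- vol3d(array(runif(64, 50, 150), c(4, 4, 4)))
  expect_identical(add_rician_noise(v, 0), v)          # sigma = 0 identity
  expect_error(add_rician_noise(v, -1), "sigma")
  expect_identical(add_rician_noise(v, 5, seed = 3)$data,
                   add_rician_noise(v, 5, seed = 3)$data)
  # v = 0: magnitude noise is Rayleigh with mean sigma * sqrt(pi / 2)
  z <- add_rician_noise(array(0, c(50, 50, 40)), sigma = 1, seed = 4)
  expect_equal(mean(z), sqrt(pi / 2), tolerance = 0.01)
  expect_true(all(z >= 0))
})

test_that("simulate_contrast_pair seeds CE voxels per ROI by the rounding rule", {
  ph <- make_phantom(small_spec())
  n_lesion <- sum(ph$rois$masks$lesion)
  cs <- contrast_spec(ce_fraction_per_roi = c(lesion = 0.10),
                      noise_sigma = 0, seed = 5)
  pair <- simulate_contrast_pair(ph$t2_map, ph$s0_map, ph$rois, cs)
  expect_equal(sum(pair$gt$true_ce_mask & ph$rois$masks$lesion),
               as.integer(floor(0.10 * n_lesion + 0.5)))
  # truth confined to the seeded ROI
  expect_false(any(pair$gt$true_ce_mask & !ph$rois$masks$lesion))
  # seeded voxels darkened by exactly ce_amplitude, others untouched
  ce <- pair$gt$true_ce_mask
  expect_equal(pair$post$data[ce], pair$pre$data[ce] * cs$ce_amplitude,
               tolerance = 1e-12)
  expect_identical(pair$post$data[!ce], pair$pre$data[!ce])
})

test_that("null contrast with zero noise leaves pre and post identical", {
  ph <- make_phantom(small_spec())
  cs <- contrast_spec(ce_fraction_per_roi = c(lesion = 0), noise_sigma = 0)
  pair <- simulate_contrast_pair(ph$t2_map, ph$s0_map, ph$rois, cs)
  expect_identical(pair$pre$data, pair$post$data)
  expect_equal(sum(pair$gt$true_ce_mask), 0L)
})

test_that("contrast spec invariants are enforced", {
  expect_error(contrast_spec(ce_fraction_per_roi = c(lesion = 1.2)), "\\[0, 1\\]")
  expect_error(contrast_spec(ce_amplitude = 1.5), "ce_amplitude")
  expect_error(contrast_spec(pre_hypointense_fraction = -0.1),
               "pre_hypointense_fraction")
  expect_error(contrast_spec(noise_sigma = -2), "noise_sigma")
})

test_that("confound voxels are darkened in both images and kept out of the CE truth", {
  ph <- make_phantom(small_spec())
  cs <- contrast_spec(ce_fraction_per_roi = c(lesion = 0.2),
                      pre_hypointense_fraction = 0.5, noise_sigma = 0,
                      seed = 9)
  pair <- simulate_contrast_pair(ph$t2_map, ph$s0_map, ph$rois, cs)
  cf <- pair$gt$confound_mask
  expect_gt(sum(cf), 0)
  expect_false(any(cf & pair$gt$true_ce_mask))
  base <- ph$s0_map$data * exp(-cs$gre_te / ph$t2_map$data)
  expect_equal(pair$pre$data[cf], base[cf] * cs$ce_amplitude)
  expect_identical(pair$pre$data[cf], pair$post$data[cf])
})

test_that("the pre-contrast hypointensity confound masks CE detection (day-21 effect)", {
  ph <- make_phantom(small_spec())
  eq3_at <- function(confound) {
    cs <- contrast_spec(ce_fraction_per_roi = c(lesion = 0.2),
                        pre_hypointense_fraction = confound,
                        noise_sigma = 0, seed = 13)
    pair <- simulate_contrast_pair(ph$t2_map, ph$s0_map, ph$rois, cs)
    eq3_ce_volume_fraction(pair$pre, pair$post, ph$rois$masks$lesion)$percent
  }
  expect_lt(eq3_at(0.5), eq3_at(0))
})

test_that("generate_cohort produces labeled, reproducible records", {
  groups <- list(list(agent = "targeted", day = 2),
                 list(agent = "control", day = 2))
  cs <- list(contrast_spec(ce_fraction_per_roi = c(lesion = 0.1),
                           noise_sigma = 10),
             contrast_spec(ce_fraction_per_roi = c(lesion = 0),
                           noise_sigma = 10))
  co <- generate_cohort(3, groups, spec = small_spec(),
                        cspec_per_group = cs, seed = 21)
  expect_length(co, 6L)
  expect_equal(vapply(co, `[[`, "", "agent"),
               rep(c("targeted", "control"), each = 3))
  expect_equal(vapply(co, `[[`, "", "subject"), sprintf("S%03d", 1:6))
  co2 <- generate_cohort(3, groups, spec = small_spec(),
                         cspec_per_group = cs, seed = 21)
  expect_identical(co[[4]]$pre$data, co2[[4]]$pre$data)
  expect_error(generate_cohort(3, list(), spec = small_spec()), "empty")
  expect_error(generate_cohort(0, groups, spec = small_spec()),
               "n_per_group")
})

test_that("a zero-CE control group yields near-zero recovered CE fractions", {
  groups <- list(list(agent = "control", day = 1))
  cs <- contrast_spec(ce_fraction_per_roi = c(lesion = 0), noise_sigma = 20)
  co <- generate_cohort(6, groups, spec = small_spec(),
                        cspec_per_group = cs, seed = 33)
  fr <- vapply(co, function(rec)
    eq3_ce_volume_fraction(rec$pre, rec$post, rec$gt$lesion_mask)$percent,
    numeric(1))
  expect_lt(abs(mean(fr)), 1.5)   # ~3 SE at this ROI size
})
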