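test_that("phantom generator emits the complete deterministic design", {
  cfg <- phantom_config(seed = 2L)
  x <- generate_phantom_dataset(cfg)
  expect_equal(nrow(x), 16 * 5 * 106 * 2 * 3)  # 50,880
  validate_feature_table(x, build_feature_catalog())
  expect_false("shape_LeastAxisLength" %in% x$feature_name)
  # complete design: 6 replicates per object/sequence/feature
  reps <- dplyr::count(x, .data$object_id, .data$sequence,
                       .data$feature_name)
  expect_true(all(reps$n == 6L))
  expect_identical(x, generate_phantom_dataset(cfg))
  expect_false(identical(x$value,
                         generate_phantom_dataset(
                           phantom_config(seed = 3L))$value))
})

test_that("feature substreams are stable under catalog subsetting", {
  cat <- build_feature_catalog()
  cfg <- phantom_config(n_types = 2L, n_objects_per_type = 2L,
                        sequences = "FLAIR", seed = 9L)
  full <- generate_phantom_dataset(cfg, cat[1:20, ])
  sub <- generate_phantom_dataset(cfg, cat[c(5, 17), ])
  keep <- full[full$feature_name %in% sub$feature_name, ]
  expect_equal(dplyr::arrange(keep, .data$feature_name, .data$object_id),
               dplyr::arrange(sub, .data$feature_name, .data$object_id))
})

test_that("noiseless configuration gives perfect downstream statistics", {
  cfg <- phantom_config(sigma_scan = 0, sigma_obs = 0, obs_shift = 0,
                        sequences = "T2 map", seed = 4L)
  x <- generate_phantom_dataset(cfg, build_feature_catalog()[1:20, ])
  st <- stability_table(x)
  expect_true(all(st$ccc == 1))
  expect_true(all(st$dr == 1))
  expect_true(all(st$icc_intra == 1 & st$icc_inter == 1))
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(sigma_scan = -1), "sigma_scan")
  expect_error(phantom_config(sequences = character(0)), "sequence")
  expect_error(phantom_config(n_types = 0), "at least one type")
})

test_that("closed-form oracles match their boundary arithmetic", {
  expect_equal(expected_ccc(1, 0), 1)
  expect_equal(expected_ccc(1, 1), 0.5)
  expect_equal(expected_ccc(3, 4), 9 / 25)
  expect_error(expected_ccc(0, 0), "undefined")
  expect_equal(expected_icc(1, 0), 1)
  expect_equal(expected_icc(2, 2), 4 / 6)
  expect_error(expected_icc(0, 0), "undefined")
})

test_that("generator recovers the closed-form CCC and ICCs", {
  # recovery design: between-object spread carries all signal (n - 1 df)
  # and enough objects that the convergence limit applies
  cfg <- phantom_config(
    n_types = 1L, n_objects_per_type = 512L, sequences = "T2 map",
    sigma_type = 0, sigma_obj = sqrt(10), sigma_scan = 1,
    sigma_obs = 0.5, obs_shift = 0.5, shape_scan_factor = 1, seed = 101L
  )
  st <- stability_table(generate_phantom_dataset(cfg))
  expect_equal(nrow(st), 106L)
  zscore <- function(v, target) {
    (mean(v) - target) / (sd(v) / sqrt(length(v)))
  }
  expect_lt(abs(zscore(st$ccc, expected_ccc(sqrt(10), 1))), 3)
  sb <- sqrt(10 + 1)  # scan noise is shared within object-scan subjects
  expect_lt(abs(zscore(st$icc_intra, expected_icc(sb, 0.5 * 0.1))), 3)
  expect_lt(abs(zscore(st$icc_inter, expected_icc(sb, 0.5, 0.5))), 3)
})

test_that("raising rescan noise never raises mean CCC (coupled seeds)", {
  cat20 <- build_feature_catalog()[10:29, ]
  for (seed in 1:20) {
    lo <- phantom_config(sequences = "T2 map", sigma_scan = 0.5,
                         shape_scan_factor = 1, seed = seed)
    hi <- phantom_config(sequences = "T2 map", sigma_scan = 1.5,
                         shape_scan_factor = 1, seed = seed)
    ccc_lo <- robustness_table(generate_phantom_dataset(lo, cat20))$ccc
    ccc_hi <- robustness_table(generate_phantom_dataset(hi, cat20))$ccc
    expect_lte(mean(ccc_hi), mean(ccc_lo))
  }
})

test_that("strong type separation makes every cross-type pair separable", {
  cfg <- phantom_config(sigma_type = 50, sigma_obj = 5, sigma_scan = 0.1,
                        sigma_obs = 0.05, obs_shift = 0,
                        sequences = "T2 map", seed = 6L)
  x <- generate_phantom_dataset(cfg, build_feature_catalog()[40:69, ])
  g <- pairwise_gini_grid(x)
  type_of <- function(o) sub("[0-9]+$", "", o)
  cross <- g[type_of(g$object_a) != type_of(g$object_b), ]
  per_pair <- tapply(cross$perfect, paste(cross$object_a, cross$object_b),
                     any)
  expect_true(all(per_pair))
})
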