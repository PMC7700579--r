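test_that("same seed gives byte-identical datasets", {
  s1 <- generate_synthetic(synthetic_spec(seed = 60, years = 2016:2018))
  s2 <- generate_synthetic(synthetic_spec(seed = 60, years = 2016:2018))
  expect_identical(s1$regions, s2$regions)
  expect_identical(s1$panels, s2$panels)
  expect_identical(s1$distances, s2$distances)
  expect_identical(s1$covariates, s2$covariates)
  s3 <- generate_synthetic(synthetic_spec(seed = 61, years = 2016:2018))
  expect_false(identical(s1$panels, s3$panels))
})

test_that("generated data satisfy the input invariants", {
  sdat <- generate_synthetic(synthetic_spec(seed = 62, years = 2017:2018))
  expect_silent(validate_region_table(as.data.frame(sdat$regions)))
  expect_silent(validate_distance_matrix(sdat$distances))
  for (p in sdat$panels) {
    expect_true(all(p$values > 0))
    expect_false(anyDuplicated(p$region_ids) > 0)
  }
  expect_true(all(sdat$covariates[-1] > 0))
  expect_equal(unname(table(sdat$block_assignment)),
               array(c(8, 7, 7, 9)), ignore_attr = TRUE)
})

test_that("eastward gradient raises capacity in the east", {
  wins <- sapply(1:7, function(s) {
    sdat <- generate_synthetic(synthetic_spec(seed = 200 + s,
                                              gradient_strength = 1,
                                              years = 2018,
                                              block_boost = 1))
    sc <- sdat$capacity$scores
    x <- sdat$regions$x_coord
    third <- floor(length(sc) / 3)
    mean(sc[order(x, decreasing = TRUE)[1:third]]) >
      mean(sc[order(x)[1:third]])
  })
  expect_gte(mean(wins), 0.75)   # repeated-seed majority
})

test_that("degenerate spec yields identical regions and uniform capacity", {
  sdat <- generate_synthetic(synthetic_spec(seed = 63, gradient_strength = 0,
                                            noise_sd = 0, years = 2018,
                                            block_boost = 1))
  vals <- sdat$panels[["2018"]]$values
  expect_equal(max(apply(vals, 2, function(v) diff(range(v)))), 0)
  expect_equal(diff(range(sdat$capacity$scores)), 0)
})

test_that("inconsistent block plant is rejected", {
  expect_error(synthetic_spec(n_regions = 30, block_plant = c(8, 7, 7, 9)),
               "sum")
  expect_error(synthetic_spec(n_regions = 3), "n_regions")
  expect_error(synthetic_spec(covariate_effects = c(Bogus = 1)), "unknown")
})

test_that("planted covariates are calibrated at zero and powered when strong", {
  sdat <- generate_synthetic(synthetic_spec(seed = 64))
  net <- sdat$network
  set.seed(65)
  ps_null <- replicate(60, {
    v <- plant_covariate(net, 0)
    qap_correlation(net, difference_matrix(v), n_perm = 99)$p_one_tailed
  })
  expect_gt(mean(ps_null), 0.35)           # roughly uniform, not skewed low
  expect_lte(mean(ps_null <= 0.05), 0.15)
  ps_strong <- replicate(20, {
    v <- plant_covariate(net, 0.95)
    qap_correlation(net, difference_matrix(v), n_perm = 199)$p_one_tailed
  })
  expect_gte(mean(ps_strong <= 0.05), 0.9) # power > 0.9
  expect_error(plant_covariate(net, 2), "strength")
  expect_error(plant_network_effect(sdat$covariates, net, "Bogus", 0.5),
               "unknown factor")
})

test_that("full pipeline smoke property on the default world", {
  sdat <- generate_synthetic(synthetic_spec(seed = 66, years = 2018))
  cap <- capacity_index(sdat$panels[["2018"]])
  grav <- modified_gravity(sdat$regions, pmax(cap$scores, 1e-6),
                           sdat$distances)
  net <- binarize_gravity(grav)
  s <- network_summary(net)
  expect_true(s$density >= 0 && s$density <= 1)
  expect_true(s$level >= 0 && s$level <= 1)
  expect_true(s$efficiency >= 0 && s$efficiency <= 1)
  part <- concor(net, 2, 0.2)
  expect_equal(part$n_blocks, 4)
  expect_true(all(table(part$assignment) >= 1))
  tab <- qap_table(net, sdat$covariates, n_perm = 49, seed = 67)
  expect_equal(nrow(tab), 6)
})
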