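test_that("independent-wiring category probabilities follow the closed form", {
  q <- pair_category_probs(0.42, 0.20)
  expect_equal(unname(q),
               c(0.3712, 0.2688, 0.1856, 0.1344, 0.0232, 0.0168),
               tolerance = 1e-12)
  expect_equal(sum(q), 1, tolerance = 1e-12)
  expect_equal(unname(pair_category_probs(0, 0)), c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(pair_category_probs(1, 1)), c(0, 0, 0, 0, 0, 1))
  expect_error(pair_category_probs(1.2, 0), "\\[0, 1\\]")
  # sums to 1 for arbitrary inputs
  set.seed(2)
  for (i in 1:20)
    expect_equal(sum(pair_category_probs(stats::runif(1), stats::runif(1))), 1,
                 tolerance = 1e-12)
})

test_that("pair probabilities reconstruct from a category distribution", {
  printed <- c(0.340, 0.295, 0.214, 0.121, 0.024, 0.005)
  rec <- category_to_pair_probs(printed)
  expect_equal(rec$p_e, 0.421, tolerance = 1e-12)
  expect_equal(rec$p_c, 0.1965, tolerance = 1e-12)
  expect_equal(rec$p_chem_any, 0.364, tolerance = 1e-12)
  expect_equal(rec$p_dual_exclusive, 0.121)
  expect_equal(rec$p_dual_any, 0.126)
})

test_that("pair statistics count edges and categories correctly", {
  dat <- make_set(c("a", "b", "c", "d"),
                  e_edges = rbind(c("a", "b"), c("a", "c")),
                  c_edges = rbind(c("a", "b"), c("c", "d"), c("d", "c")))
  st <- pair_probabilities(dat)
  expect_equal(st$n_pairs, 6)
  expect_equal(st$p_e, 2 / 6)
  expect_equal(st$p_c, 3 / 12)
  expect_equal(st$p_chem_any, 2 / 6)
  expect_equal(as.integer(st$counts),
               c(3, 1, 0, 1, 1, 0))  # none, e_only, c_only, dual, bidir, bidir_e
  # round trip through the category arithmetic
  rec <- category_to_pair_probs(st$categories)
  expect_equal(rec$p_e, st$p_e)
  expect_equal(rec$p_c, st$p_c)
})

test_that("Monte Carlo p-values use the add-one rule and are calibrated", {
  nulls <- 1:9999
  expect_equal(mc_pvalue(10000, nulls, "greater"), 1e-4)
  expect_equal(mc_pvalue(10000, nulls, "two.sided"), 2e-4)
  expect_equal(mc_pvalue(0, nulls, "less"), 1e-4)
  expect_gte(mc_pvalue(5000, nulls, "two.sided"), 0.99)
  expect_error(mc_pvalue(1, 1:10), "999")

  # statistic generated under the null -> p uniform on its grid
  set.seed(17)
  ps <- replicate(200, mc_pvalue(stats::rnorm(1), stats::rnorm(999), "greater"))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("Bonferroni correction caps and dominates the raw p-values", {
  expect_equal(bonferroni(0.01, m = 4), 0.04)
  expect_equal(bonferroni(0.5, m = 4), 1)
  p <- c(0.001, 0.02, 0.7)
  expect_true(all(bonferroni(p) >= p))
  expect_equal(bonferroni(p), stats::p.adjust(p, "bonferroni"))
  expect_error(bonferroni(p, m = 2), "at least")
})

test_that("distance profiles estimate binned probabilities with bootstrap SDs", {
  set.seed(41)
  dat <- spread_geometry(400)
  dat <- wire(dat, "uniform", p_e = 1, p_c = 0)
  prof <- estimate_profiles(dat, "z", n_boot = 100)
  occ <- prof$n > 0
  expect_true(all(prof$p_e[occ] == 1))
  expect_true(all(prof$p_e_sd[occ] == 0))
  expect_error(estimate_profiles(dat, "z", n_boot = 10), "at least 100")
})

test_that("a transverse cutoff in the generator is recovered by the profiles", {
  set.seed(43)
  dat <- spread_geometry(4000)
  cutoff <- list(p0 = 0.9, d0_xy = 1e6, s_xy = 10, d0_z = 30, s_z = 2,
                 z_max = 30)
  dat <- wire(dat, "distance", e_profile = cutoff)
  expect_equal(sum(dat$pairs$electrical & dat$pairs$delta_z_um > 30), 0)
  prof <- estimate_profiles(dat, "z", breaks = seq(0, 50, 10), n_boot = 100)
  expect_true(all(prof$p_e[prof$lower >= 30 & prof$n > 0] == 0))
  # nonuniform model fitted to these data predicts ~0 at delta-z = 40 um
  nm <- fit_null_model(dat, "nonuniform_distance")
  far <- which(dat$pairs$delta_z_um > 35)
  pred <- predict(nm)
  expect_lt(max(pred$p_e[far]), 0.02)
})

test_that("uniform model predictions are constant and simulations deterministic", {
  set.seed(47)
  dat <- wire(fast_geometry(30, 3), "uniform")
  nm <- fit_null_model(dat, "uniform")
  pred <- predict(nm)
  expect_equal(length(unique(pred$p_e)), 1)
  expect_equal(unique(pred$p_e), nm$p_e)
  expect_equal(unique(pred$p_c_ab), nm$p_c)
  s1 <- sample_networks(dat, nm, 20, seed = 9)
  s2 <- sample_networks(dat, nm, 20, seed = 9)
  expect_identical(s1, s2)
})

test_that("nonuniform predictions are equal for equal distances and reproduce totals", {
  set.seed(53)
  dat <- wire(spread_geometry(3000), "distance")
  nm <- fit_null_model(dat, "nonuniform_distance")
  pred <- predict(nm)
  # normalisation: expected edge count over the fitted geometry matches data
  expect_equal(mean(pred$p_e), pair_probabilities(dat)$p_e, tolerance = 0.02)
  expect_equal(mean(pred$p_c_ab), pair_probabilities(dat)$p_c, tolerance = 0.02)
  # determinism on equal geometry
  i <- which.min(abs(dat$pairs$delta_xy_um - 50))
  expect_equal(predict(nm)$p_e[i], pred$p_e[i])
})

test_that("sampled networks reproduce their generating probabilities", {
  set.seed(59)
  dat <- wire(fast_geometry(200, 2), "uniform")
  nm <- fit_null_model(dat, "uniform")
  sims <- sample_networks(dat, nm, 2000, seed = 4)
  freq <- mean(sims$electrical)
  se <- sqrt(nm$p_e * (1 - nm$p_e) / (2000 * 200))
  expect_lt(abs(freq - nm$p_e), 3 * se)
  # a saturated model wires everything
  full <- make_set(c("a", "b", "c"),
                   e_edges = rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  nm_full <- fit_null_model(full, "uniform")
  s <- sample_networks(full, nm_full, 10, seed = 1)
  expect_true(all(s$electrical))
})

test_that("the ml-position model biases chemical edge direction downward", {
  set.seed(61)
  geo <- generate_geometry(150, cells_per_set = 3, seed = 8)
  dat <- wire(geo, "structured", ml_direction_bias = 1, seed = 9)
  nm <- fit_null_model(dat, "nonuniform_distance_ml")
  expect_equal(nm$p_down, 1)
  pred <- predict(nm)
  ml <- stats::setNames(dat$cells$ml_pos, dat$cells$cell_id)
  down_ab <- ml[dat$pairs$cell_a] > ml[dat$pairs$cell_b]
  expect_true(all(pred$p_c_ab[!down_ab] == 0))
  expect_true(all(pred$p_c_ba[down_ab] == 0))
})

test_that("motif ratios are near 1 when the data come from the fitted null", {
  set.seed(67)
  dat <- wire(fast_geometry(150, 3), "uniform")
  nm <- fit_null_model(dat, "uniform")
  mt <- motif_ratio_test(dat, nm, "chemical", n_samples = 999, seed = 3)
  expect_equal(sum(mt$census$observed), mt$n_triplets)
  # no class significant after Bonferroni for self-generated data
  expect_true(all(mt$census$p_adj >= 0.05))
  big <- mt$census$predicted > 0.05
  expect_true(all(abs(mt$census$ratio[big] - 1) < 0.5))
})
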