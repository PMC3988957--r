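test_that("worked triplet coefficient cases hold exactly", {
  # two-edge path: one open 2-path -> C = 0
  path2 <- make_set(c("a", "b", "c"),
                    e_edges = rbind(c("a", "b"), c("b", "c")))
  expect_identical(subnetwork_clustering(path2, "s1", "electrical"), 0)
  # triangle -> C = 1, AC undefined (complement has no 2-path)
  tri <- make_set(c("a", "b", "c"),
                  e_edges = rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_identical(subnetwork_clustering(tri, "s1", "electrical"), 1)
  expect_true(is.na(subnetwork_anticlustering(tri, "s1", "electrical")))
  # empty triad: complement is the triangle -> AC = 1
  empty <- make_set(c("a", "b", "c"))
  expect_identical(subnetwork_anticlustering(empty, "s1", "electrical"), 1)
  expect_true(is.na(subnetwork_clustering(empty, "s1", "electrical")))
  # single edge: no 2-path either way -> C undefined
  single <- make_set(c("a", "b", "c"), e_edges = rbind(c("a", "b")))
  expect_true(is.na(subnetwork_clustering(single, "s1", "electrical")))
})

test_that("a 4-cycle quadruplet has C = 0", {
  cyc <- make_set(c("a", "b", "c", "d"),
                  e_edges = rbind(c("a", "b"), c("b", "c"),
                                  c("c", "d"), c("d", "a")))
  expect_identical(subnetwork_clustering(cyc, "s1", "electrical"), 0)
})

test_that("anticlustering is clustering of the complement graph", {
  all_edges <- utils::combn(c("a", "b", "c", "d"), 2)
  set.seed(13)
  for (rep in 1:10) {
    on <- stats::runif(ncol(all_edges)) < 0.5
    g <- make_set(c("a", "b", "c", "d"),
                  e_edges = t(all_edges[, on, drop = FALSE]))
    comp <- make_set(c("a", "b", "c", "d"),
                     e_edges = t(all_edges[, !on, drop = FALSE]))
    expect_equal(subnetwork_anticlustering(g, "s1", "electrical"),
                 subnetwork_clustering(comp, "s1", "electrical"))
    # double complement is the identity
    expect_equal(subnetwork_anticlustering(comp, "s1", "electrical"),
                 subnetwork_clustering(g, "s1", "electrical"))
  }
})

test_that("chemical coefficients collapse uni- and bidirectional edges identically", {
  uni <- make_set(c("a", "b", "c"),
                  c_edges = rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  bi <- make_set(c("a", "b", "c"),
                 c_edges = rbind(c("a", "b"), c("b", "a"),
                                 c("b", "c"), c("a", "c")))
  expect_identical(subnetwork_clustering(uni, "s1", "chemical"), 1)
  expect_identical(subnetwork_clustering(bi, "s1", "chemical"), 1)
})

test_that("subnetwork coefficients agree with igraph transitivity", {
  set.seed(23)
  for (rep in 1:10) {
    dat <- wire(fast_geometry(1, 4), "uniform")
    adj_edges <- dat$pairs[dat$pairs$electrical, c("cell_a", "cell_b")]
    g <- igraph::graph_from_data_frame(adj_edges, directed = FALSE,
                                       vertices = dat$cells$cell_id)
    ours <- subnetwork_clustering(dat, dat$cells$set_id[1], "electrical")
    theirs <- igraph::transitivity(g, type = "global")
    if (is.na(ours)) expect_true(is.nan(theirs) || is.na(theirs))
    else expect_equal(ours, theirs)
  }
})

test_that("mean coefficients average only measurable subnetworks", {
  full <- make_set(c("a", "b", "c"),
                   e_edges = rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  mc <- mean_coefficients(full, "electrical")
  expect_equal(mc$mean_c, 1)
  expect_true(is.na(mc$mean_ac))
  expect_equal(mc$n_ac, 0)
})

test_that("per-triplet coefficients match subnetwork computation", {
  set.seed(31)
  dat <- wire(fast_geometry(25, 3), "uniform")
  tr <- decompose_triplets(dat)
  tc <- triplet_coefficients(tr, "electrical")
  mc <- mean_coefficients(dat, "electrical")
  expect_equal(mean(tc$c, na.rm = TRUE), mc$mean_c)
  expect_equal(mean(tc$ac, na.rm = TRUE), mc$mean_ac)
})

test_that("dispersion fit recovers a planar electrical confinement", {
  # electrical probability decaying steeply in delta-z: C_E falls and AC_E
  # rises with triplet dispersion; slope signs are stable across seeds
  prof <- list(p0 = 0.9, d0_xy = 500, s_xy = 50, d0_z = 8, s_z = 3)
  signs_c <- signs_ac <- logical(0)
  for (s in 1:5) {
    geo <- generate_geometry(80, cells_per_set = 3, z_spread_um = 15, seed = s)
    dat <- wire(geo, "distance", e_profile = prof, seed = 1000 + s)
    tr <- decompose_triplets(dat)
    fc <- coefficient_vs_dispersion(tr, "electrical", "clustering",
                                    n_boot = 100)
    fac <- coefficient_vs_dispersion(tr, "electrical", "anticlustering",
                                     n_boot = 100)
    signs_c <- c(signs_c, fc$slope < 0)
    signs_ac <- c(signs_ac, fac$slope > 0)
  }
  expect_gte(sum(signs_c), 4)
  expect_gte(sum(signs_ac), 4)
})

test_that("degenerate dispersion designs are rejected", {
  dat <- make_set(c("a", "b", "c"),
                  e_edges = rbind(c("a", "b"), c("b", "c")))
  tr <- decompose_triplets(dat)
  expect_error(coefficient_vs_dispersion(tr, "electrical", "clustering"),
               "at least 3")
})

test_that("fit comparison uses add-one Monte Carlo ranks", {
  fits <- data.frame(intercept = seq(0, 1, length.out = 9999),
                     slope = seq(-1, 1, length.out = 9999))
  p <- compare_fits(list(intercept = 2, slope = 0), fits)
  expect_equal(p$p_intercept, 2 * 1e-4)  # beyond all samples, two-sided
  expect_gt(p$p_slope, 0.9)              # at the null median
  expect_error(compare_fits(list(intercept = 0, slope = 0), fits[1:10, ]),
               "999")
})
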