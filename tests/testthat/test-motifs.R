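test_that("triad enumeration matches an igraph isomorphism oracle", {
  u <- motif_classes("electrical")
  d <- motif_classes("chemical")
  expect_equal(nrow(u), 4)
  expect_equal(nrow(d), 16)
  expect_equal(sum(u$orbit_size), 8)
  expect_equal(sum(d$orbit_size), 64)
  expect_true(all(6 %% d$orbit_size == 0))  # orbit sizes divide |S_3|

  # independent oracle: group all 64 labeled digraphs by igraph isomorphism
  graphs <- lapply(0:63, function(code)
    igraph::graph_from_adjacency_matrix(decode_dcode(code), mode = "directed"))
  rep_of <- integer(64)
  for (i in 1:64) {
    rep_of[i] <- i
    for (j in seq_len(i - 1)) {
      if (rep_of[j] == j && igraph::isomorphic(graphs[[i]], graphs[[j]])) {
        rep_of[i] <- j
        break
      }
    }
  }
  expect_equal(length(unique(rep_of)), 16)
  # orbit sizes agree with the oracle partition
  oracle_sizes <- sort(as.integer(table(rep_of)))
  expect_equal(sort(d$orbit_size), oracle_sizes)
  # and every oracle orbit maps to a single package class
  pkg_class <- vapply(0:63, function(code)
    classify_triad(code, directed = TRUE)$class_id, numeric(1))
  expect_true(all(tapply(pkg_class, rep_of, function(v) length(unique(v)) == 1)))
})

test_that("named directed motifs classify to their defining edge lists", {
  cls <- function(edges) classify_triad(edges, directed = TRUE)$name
  expect_equal(cls(rbind(c(1, 2))), "directed_edge")
  expect_equal(cls(rbind(c(1, 2), c(1, 3))), "v_out")
  expect_equal(cls(rbind(c(1, 2), c(2, 3))), "three_chain")
  expect_equal(cls(rbind(c(1, 2), c(2, 1), c(3, 1))), "mutual_in")
  expect_equal(cls(rbind(c(1, 2), c(2, 3), c(1, 3))), "feedforward")
  expect_equal(cls(rbind(c(1, 2), c(2, 3), c(3, 1))), "three_loop")
  expect_equal(cls(rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 2))),
               "regulating_mutual")
})

test_that("classification is invariant under node relabeling", {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  set.seed(11)
  for (rep in 1:20) {
    n_e <- sample(0:6, 1)
    edges <- matrix(nrow = 0, ncol = 2)
    all_pairs <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
    if (n_e > 0) edges <- all_pairs[sample(6, n_e), , drop = FALSE]
    base <- classify_triad(edges, directed = TRUE)$class_id
    for (p in seq_len(6)) {
      perm_edges <- edges
      perm_edges[] <- perms[p, ][edges]
      expect_equal(classify_triad(perm_edges, directed = TRUE)$class_id, base)
    }
    # same for the undirected support
    und <- unique(t(apply(edges, 1, sort)))
    if (nrow(edges) == 0) und <- matrix(nrow = 0, ncol = 2)
    base_u <- classify_triad(und, directed = FALSE)$class_id
    for (p in seq_len(6)) {
      pe <- und
      pe[] <- perms[p, ][und]
      expect_equal(classify_triad(pe, directed = FALSE)$class_id, base_u)
    }
  }
})

test_that("transitivity taxonomy matches a brute-force check of all 64 digraphs", {
  brute <- function(adj) {
    has_path <- FALSE
    for (i in 1:3) for (j in 1:3) for (k in 1:3)
      if (i != j && j != k && i != k && adj[i, j] && adj[j, k]) {
        has_path <- TRUE
        if (!adj[i, k]) return("intransitive")
      }
    if (has_path) "transitive" else "not_applicable"
  }
  labels <- vapply(0:63, function(code) brute(decode_dcode(code) > 0),
                   character(1))
  for (code in 0:63) {
    cls <- classify_triad(code, directed = TRUE)
    expect_equal(cls$transitivity, labels[code + 1],
                 label = paste("code", code))
  }
  d <- motif_classes("chemical")
  expect_equal(sum(d$transitivity == "transitive"), 4)
  expect_equal(sum(d$transitivity == "intransitive"), 7)
  expect_equal(sum(d$transitivity == "not_applicable"), 5)
  expect_equal(classify_transitivity("feedforward"), "transitive")
  expect_equal(classify_transitivity("three_loop"), "intransitive")
  expect_equal(classify_transitivity("v_out"), "not_applicable")
})

test_that("undirected triads classify by edge count", {
  expect_equal(classify_triad(matrix(nrow = 0, ncol = 2), FALSE)$name, "empty")
  expect_equal(classify_triad(rbind(c(1, 2), c(2, 3)), FALSE)$name, "two_path")
  expect_equal(classify_triad(rbind(c(1, 2), c(2, 3), c(3, 1)), FALSE)$name,
               "triangle")
  u <- motif_classes("electrical")
  expect_equal(u$n_edges, 0:3)
  expect_equal(u$orbit_size, c(1, 3, 3, 1))
})

test_that("quadruplets decompose into four triplets each and pairs into none", {
  set.seed(3)
  quads <- wire(fast_geometry(10, 4), "uniform")
  trips <- wire(fast_geometry(5, 3), "uniform")
  duos <- wire(fast_geometry(4, 2), "uniform")
  n <- function(d) nrow(decompose_triplets(d))
  expect_equal(n(quads), 40)
  expect_equal(n(trips), 5)
  expect_equal(n(duos), 0)

  dat <- make_set(c("a", "b", "c"), z = c(0, 0, 10))
  expect_equal(decompose_triplets(dat)$z_dispersion_um, 20 / 3)
})

test_that("decomposition agrees with per-triplet classification by hand", {
  set.seed(21)
  dat <- wire(fast_geometry(12, 4), "uniform")
  tr <- decompose_triplets(dat)
  pr <- dat$pairs
  for (i in sample(nrow(tr), 15)) {
    ids <- unlist(tr[i, c("cell_1", "cell_2", "cell_3")], use.names = FALSE)
    e_edges <- matrix(nrow = 0, ncol = 2)
    c_edges <- matrix(nrow = 0, ncol = 2)
    for (r in which(pr$cell_a %in% ids & pr$cell_b %in% ids)) {
      a <- match(pr$cell_a[r], ids)
      b <- match(pr$cell_b[r], ids)
      if (pr$electrical[r]) e_edges <- rbind(e_edges, c(a, b))
      if (pr$chem_ab[r]) c_edges <- rbind(c_edges, c(a, b))
      if (pr$chem_ba[r]) c_edges <- rbind(c_edges, c(b, a))
    }
    expect_equal(classify_triad(e_edges, FALSE)$class_id, tr$e_class[i])
    expect_equal(classify_triad(c_edges, TRUE)$class_id, tr$c_class[i])
  }
})

test_that("census counts partition the triplets", {
  set.seed(5)
  dat <- wire(fast_geometry(30, 3), "uniform")
  tr <- decompose_triplets(dat)
  cen <- motif_census(tr, "chemical")
  expect_equal(sum(cen$count), nrow(tr))
  expect_equal(sum(cen$frequency), 1)
  by_trans <- tapply(cen$count, cen$transitivity, sum)
  expect_equal(sum(by_trans), nrow(tr))

  empty <- motif_census(decompose_triplets(wire(fast_geometry(10, 3),
                                                "uniform", p_e = 0, p_c = 0)),
                        "electrical")
  expect_equal(empty$frequency[empty$name == "empty"], 1)
})
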