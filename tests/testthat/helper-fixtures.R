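# Fixture builders used across the suite. All data are generated in code.

# Large regular geometry: n_sets sets of k cells at fixed within-set offsets
# (all pairwise caps respected), spaced far apart between sets. Fast to
# build, used for large Monte Carlo oracle checks where the geometry itself
# is irrelevant.
fast_geometry <- function(n_sets, k) {
  total <- n_sets * k
  set_of <- rep(seq_len(n_sets), each = k)
  pos <- rep(seq_len(k), n_sets)
  off <- matrix(c(0, 0, 0, 30, 10, 5, 5, 40, 10, 50, 50, 15), 4, 3, byrow = TRUE)
  cells <- data.frame(cell_id = sprintf("c%07d", seq_len(total)),
                      set_id = sprintf("s%06d", set_of),
                      x_um = 1000 * set_of + off[pos, 1],
                      y_um = off[pos, 2], z_um = off[pos, 3],
                      ml_pos = stats::runif(total, 0.1, 0.9),
                      stringsAsFactors = FALSE)
  sl <- utils::combn(k, 2)
  ai <- as.vector(outer(sl[1, ], (seq_len(n_sets) - 1) * k, "+"))
  bi <- as.vector(outer(sl[2, ], (seq_len(n_sets) - 1) * k, "+"))
  pairs <- data.frame(cell_a = cells$cell_id[ai], cell_b = cells$cell_id[bi],
                      stringsAsFactors = FALSE)
  mli_data(cells, pairs)
}

# Geometry of n_pairs 2-cell sets with distances spread over the tested
# range (delta-xy up to 180 um, delta-z up to 50 um), for profile tests.
spread_geometry <- function(n_pairs) {
  dxy <- stats::runif(n_pairs, 0, 180)
  dz <- stats::runif(n_pairs, 0, 50)
  cells <- data.frame(
    cell_id = sprintf("c%07d", seq_len(2 * n_pairs)),
    set_id = rep(sprintf("s%06d", seq_len(n_pairs)), each = 2),
    x_um = as.vector(rbind(1000 * seq_len(n_pairs),
                           1000 * seq_len(n_pairs) + dxy)),
    y_um = 0, z_um = as.vector(rbind(rep(0, n_pairs), dz)),
    stringsAsFactors = FALSE)
  pairs <- data.frame(cell_a = cells$cell_id[c(TRUE, FALSE)],
                      cell_b = cells$cell_id[c(FALSE, TRUE)],
                      stringsAsFactors = FALSE)
  mli_data(cells, pairs)
}

# One recording set with explicit edges. cells: data.frame(cell_id, z, ml).
# e_edges / c_edges: 2-column matrices (or NULL) of cell ids; c_edges are
# directed source -> target.
make_set <- function(ids, z = NULL, ml = NULL, e_edges = NULL, c_edges = NULL,
                     x = NULL, y = NULL) {
  n <- length(ids)
  cells <- data.frame(cell_id = ids, set_id = "s1",
                      x_um = if (is.null(x)) seq(0, by = 20, length.out = n) else x,
                      y_um = if (is.null(y)) rep(0, n) else y,
                      z_um = if (is.null(z)) rep(0, n) else z,
                      stringsAsFactors = FALSE)
  if (!is.null(ml)) cells$ml_pos <- ml
  cmb <- utils::combn(ids, 2)
  has <- function(edges, a, b, directed) {
    if (is.null(edges)) return(FALSE)
    edges <- matrix(edges, ncol = 2)
    if (directed) any(edges[, 1] == a & edges[, 2] == b)
    else any((edges[, 1] == a & edges[, 2] == b) |
             (edges[, 1] == b & edges[, 2] == a))
  }
  pairs <- data.frame(cell_a = cmb[1, ], cell_b = cmb[2, ],
                      stringsAsFactors = FALSE)
  pairs$electrical <- mapply(function(a, b) has(e_edges, a, b, FALSE),
                             pairs$cell_a, pairs$cell_b)
  pairs$chem_ab <- mapply(function(a, b) has(c_edges, a, b, TRUE),
                          pairs$cell_a, pairs$cell_b)
  pairs$chem_ba <- mapply(function(a, b) has(c_edges, b, a, TRUE),
                          pairs$cell_a, pairs$cell_b)
  pairs$cc_percent <- ifelse(pairs$electrical, 5, NA)
  pairs$ipsc_ab_pa <- ifelse(pairs$chem_ab, 10, NA)
  pairs$ipsc_ba_pa <- ifelse(pairs$chem_ba, 10, NA)
  mli_data(cells, pairs)
}

# decode a directed triad bit code into an adjacency matrix; independent of
# the package internals (slot order (1,2),(1,3),(2,1),(2,3),(3,1),(3,2))
decode_dcode <- function(code) {
  slots <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  adj <- matrix(0L, 3, 3)
  for (k in 1:6)
    if (bitwAnd(code, 2^(k - 1)) > 0) adj[slots[k, 1], slots[k, 2]] <- 1L
  adj
}
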