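# Clustering (C) and anticlustering (AC) coefficients of recorded
# subnetworks of 3-4 cells. C is the global transitivity of the induced
# subgraph: closed 2-paths / 2-paths, undefined (NA) when the subgraph has no
# 2-path. AC is C of the complement graph on the same nodes. For the chemical
# network, directed edges are first collapsed to undirected, treating uni-
# and bidirectional connections identically.

# C from an undirected adjacency matrix (small n)
.clustering_adj <- function(adj) {
  deg <- rowSums(adj)
  paths2 <- sum(choose(deg, 2))
  if (paths2 == 0) return(NA_real_)
  closed <- sum(diag(adj %*% adj %*% adj)) / 2  # 3 * triangles * 2 / 2
  closed / paths2
}

# undirected adjacency of one recording set for one edge type
.set_adjacency <- function(data, set_id, edge_type) {
  cells <- data$cells$cell_id[data$cells$set_id == set_id]
  pr <- data$pairs[data$pairs$set_id == set_id, , drop = FALSE]
  n <- length(cells)
  adj <- matrix(0L, n, n, dimnames = list(cells, cells))
  on <- if (edge_type == "electrical") pr$electrical %in% TRUE
        else (pr$chem_ab %in% TRUE) | (pr$chem_ba %in% TRUE)
  a <- match(pr$cell_a, cells)
  b <- match(pr$cell_b, cells)
  adj[cbind(a[on], b[on])] <- 1L
  adj[cbind(b[on], a[on])] <- 1L
  adj
}

#' Clustering coefficient of a recorded subnetwork
#'
#' The number of closed 2-paths divided by the number of 2-paths in the
#' induced subgraph of one recording set (3 or 4 cells). Chemical edges are
#' collapsed to undirected before counting. For a triplet this is 1 on a
#' triangle, 0 on a 2-edge path and undefined (`NA`) otherwise.
#'
#' @param data an [mli_data] object.
#' @param set_id recording-set identifier.
#' @param edge_type `"electrical"` or `"chemical"`.
#' @return Value in `[0, 1]`, or `NA` when no 2-path exists.
#' @export
subnetwork_clustering <- function(data, set_id,
                                  edge_type = c("electrical", "chemical")) {
  edge_type <- match.arg(edge_type)
  adj <- .set_adjacency(data, set_id, edge_type)
  if (nrow(adj) < 3 || nrow(adj) > 4)
    stop("subnetwork must have 3 or 4 nodes, got ", nrow(adj))
  .clustering_adj(adj)
}

#' Anticlustering coefficient of a recorded subnetwork
#'
#' The clustering coefficient of the complement graph on the same nodes: the
#' likelihood that if A-B and B-C are both unconnected, A-C is unconnected
#' too. For a triplet it is 1 on the empty triad and undefined on the full
#' triangle.
#'
#' @inheritParams subnetwork_clustering
#' @return Value in `[0, 1]`, or `NA` when the complement has no 2-path.
#' @export
subnetwork_anticlustering <- function(data, set_id,
                                      edge_type = c("electrical", "chemical")) {
  edge_type <- match.arg(edge_type)
  adj <- .set_adjacency(data, set_id, edge_type)
  if (nrow(adj) < 3 || nrow(adj) > 4)
    stop("subnetwork must have 3 or 4 nodes, got ", nrow(adj))
  comp <- 1L - adj
  diag(comp) <- 0L
  .clustering_adj(comp)
}

# per-triplet C and AC from triad codes (triplet-level fast path)
# undirected code 0..7: C: 1 on 7 (triangle), 0 on {3,5,6}, NA otherwise
.c_of_ucode <- c(NA, NA, NA, 0, NA, 0, 0, 1)[1:8]
.triplet_C <- function(ucode) .c_of_ucode[ucode + 1]
.triplet_AC <- function(ucode) .c_of_ucode[bitwXor(ucode, 7L) + 1]

# collapse a directed triad code to the undirected code of its support
.collapse_dcode <- function(ccode) {
  f <- function(bit_f, bit_r) as.integer(bitwAnd(ccode, bit_f) > 0 |
                                         bitwAnd(ccode, bit_r) > 0)
  f(1L, 4L) + 2L * f(2L, 16L) + 4L * f(8L, 32L)
}

#' Mean clustering and anticlustering over recorded subnetworks
#'
#' Averages the coefficients over all recording sets of 3-4 cells where the
#' coefficient is defined, mirroring the subnetwork-level averaging used for
#' comparison against random connectivity models (the result does not
#' estimate the whole-network clustering coefficient).
#'
#' @param data an [mli_data] object.
#' @param edge_type `"electrical"` or `"chemical"`.
#' @return List of class `mli_clustering`: `mean_c`, `mean_ac`, counts of
#'   measurable subnetworks (`n_c`, `n_ac`), and `per_subnetwork` table.
#' @export
mean_coefficients <- function(data, edge_type = c("electrical", "chemical")) {
  edge_type <- match.arg(edge_type)
  sizes <- table(data$cells$set_id)
  ids <- names(sizes)[sizes >= 3 & sizes <= 4]
  if (length(ids) == 0) stop("no recording set with 3 or 4 cells")
  c_val <- vapply(ids, function(s) subnetwork_clustering(data, s, edge_type),
                  numeric(1))
  ac_val <- vapply(ids, function(s) subnetwork_anticlustering(data, s, edge_type),
                   numeric(1))
  structure(list(
    edge_type = edge_type,
    mean_c = if (all(is.na(c_val))) NA_real_ else mean(c_val, na.rm = TRUE),
    mean_ac = if (all(is.na(ac_val))) NA_real_ else mean(ac_val, na.rm = TRUE),
    n_c = sum(!is.na(c_val)), n_ac = sum(!is.na(ac_val)),
    per_subnetwork = data.frame(set_id = ids, c = c_val, ac = ac_val,
                                row.names = NULL, stringsAsFactors = FALSE)),
    class = "mli_clustering")
}

#' @export
print.mli_clustering <- function(x, ...) {
  cat(sprintf("Subnetwork clustering (%s): mean C = %.4f (n = %d), mean AC = %.4f (n = %d)\n",
              x$edge_type, x$mean_c, x$n_c, x$mean_ac, x$n_ac))
  invisible(x)
}

#' Per-triplet clustering and anticlustering coefficients
#'
#' Triplet-level fast path: C is 1 on a triangle, 0 on a 2-edge graph and
#' `NA` otherwise; AC is the same on the complement. Chemical triads are
#' collapsed to their undirected support first.
#'
#' @param triplets output of [decompose_triplets()].
#' @param edge_type `"electrical"` or `"chemical"`.
#' @return data.frame with columns `c` and `ac`, one row per triplet.
#' @export
triplet_coefficients <- function(triplets,
                                 edge_type = c("electrical", "chemical")) {
  edge_type <- match.arg(edge_type)
  ucode <- if (edge_type == "electrical") triplets$e_code
           else .collapse_dcode(triplets$c_code)
  data.frame(c = .triplet_C(ucode), ac = .triplet_AC(ucode))
}

#' Clustering coefficient versus transverse dispersion of triplets
#'
#' Ordinary least-squares fit of the per-triplet clustering (or
#' anticlustering) coefficient against the triplet's mean pairwise delta-z
#' (its transverse dispersion), with intercept and slope uncertainties from a
#' nonparametric bootstrap over triplets. Because electrical connections are
#' confined near a sagittal plane, C typically decreases and AC increases
#' with dispersion in structured data.
#'
#' @param triplets output of [decompose_triplets()].
#' @param edge_type `"electrical"` or `"chemical"`.
#' @param coefficient `"clustering"` or `"anticlustering"`.
#' @param n_boot bootstrap resamples for the parameter SEs (default 1000).
#' @return List of class `mli_dispersion_fit`: `intercept`, `slope`,
#'   `intercept_se`, `slope_se`, `n`, and the `points` used.
#' @export
coefficient_vs_dispersion <- function(triplets,
                                      edge_type = c("electrical", "chemical"),
                                      coefficient = c("clustering", "anticlustering"),
                                      n_boot = 1000) {
  edge_type <- match.arg(edge_type)
  coefficient <- match.arg(coefficient)
  ucode <- if (edge_type == "electrical") triplets$e_code
           else .collapse_dcode(triplets$c_code)
  val <- if (coefficient == "clustering") .triplet_C(ucode) else .triplet_AC(ucode)
  keep <- !is.na(val)
  x <- triplets$z_dispersion_um[keep]
  y <- val[keep]
  if (length(y) < 3 || length(unique(x)) < 2)
    stop("need at least 3 measurable triplets with distinct dispersions")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  boot <- matrix(NA_real_, n_boot, 2)
  n <- length(y)
  for (b in seq_len(n_boot)) {
    i <- sample.int(n, n, replace = TRUE)
    if (length(unique(x[i])) < 2) next
    boot[b, ] <- stats::coef(stats::lm(y[i] ~ x[i]))
  }
  structure(list(edge_type = edge_type, coefficient = coefficient,
                 intercept = unname(cf[1]), slope = unname(cf[2]),
                 intercept_se = stats::sd(boot[, 1], na.rm = TRUE),
                 slope_se = stats::sd(boot[, 2], na.rm = TRUE),
                 n = n,
                 points = data.frame(z_dispersion_um = x, value = y)),
            class = "mli_dispersion_fit")
}

#' @export
print.mli_dispersion_fit <- function(x, ...) {
  cat(sprintf("%s %s vs z dispersion (n = %d triplets):\n",
              x$edge_type, x$coefficient, x$n))
  cat(sprintf("  intercept = %.4f (SE %.4f)   slope = %.5f /um (SE %.5f)\n",
              x$intercept, x$intercept_se, x$slope, x$slope_se))
  invisible(x)
}

#' Compare a fitted line against Monte Carlo model fits
#'
#' Two-sided Monte Carlo p-values (add-one corrected rank) for the intercept
#' and slope of a data fit relative to the distribution of the same
#' parameters fitted on model realizations over the same geometry.
#'
#' @param data_fit an `mli_dispersion_fit` (or list with `intercept`,
#'   `slope`).
#' @param model_fits data.frame with columns `intercept` and `slope`, one row
#'   per Monte Carlo realization (at least 999).
#' @return List with `p_intercept` and `p_slope`.
#' @export
compare_fits <- function(data_fit, model_fits) {
  if (nrow(model_fits) < 999)
    stop("need at least 999 Monte Carlo fits, got ", nrow(model_fits))
  list(p_intercept = mc_pvalue(data_fit$intercept, model_fits$intercept),
       p_slope = mc_pvalue(data_fit$slope, model_fits$slope))
}
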