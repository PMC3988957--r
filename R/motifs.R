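# Triad motif machinery.
#
# A triad on nodes {1,2,3} is encoded as a bit code:
#   undirected: bits for pairs (1,2), (1,3), (2,3)            -> codes 0..7
#   directed:   bits for ordered pairs (1,2), (1,3), (2,1),
#               (2,3), (3,1), (3,2)                           -> codes 0..63
# The canonical form of a code is the minimum over the 6 node permutations;
# isomorphism classes are indexed by (edge count, canonical code). This
# yields 4 undirected and 16 directed classes.

.perms3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
.u_slots <- rbind(c(1, 2), c(1, 3), c(2, 3))
.d_slots <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))

.code_from_adj <- function(adj, slots) {
  bits <- slots[, 1] * 0
  for (k in seq_len(nrow(slots))) bits[k] <- adj[slots[k, 1], slots[k, 2]]
  sum(bits * 2^(seq_len(nrow(slots)) - 1))
}

.adj_from_code <- function(code, slots, directed) {
  adj <- matrix(0L, 3, 3)
  for (k in seq_len(nrow(slots))) {
    if (bitwAnd(code, 2^(k - 1)) > 0) {
      adj[slots[k, 1], slots[k, 2]] <- 1L
      if (!directed) adj[slots[k, 2], slots[k, 1]] <- 1L
    }
  }
  adj
}

.permute_code <- function(code, perm, slots, directed) {
  adj <- .adj_from_code(code, slots, directed)
  padj <- matrix(0L, 3, 3)
  padj[perm, perm] <- adj
  .code_from_adj(padj, slots)
}

# canonical code per labeled code, for one edge type
.canon_table <- function(directed) {
  slots <- if (directed) .d_slots else .u_slots
  n <- 2^nrow(slots)
  vapply(0:(n - 1), function(code) {
    min(vapply(seq_len(6), function(p)
      .permute_code(code, .perms3[p, ], slots, directed), numeric(1)))
  }, numeric(1))
}

.bitcount <- function(codes) {
  vapply(codes, function(c) sum(bitwAnd(c, 2^(0:5)) > 0), numeric(1))
}

# transitivity of one directed class, from a representative code:
# transitive iff every 2-path i->j->k (i != k) is closed by i->k;
# not applicable iff no such 2-path exists
.transitivity_of_code <- function(code) {
  adj <- .adj_from_code(code, .d_slots, directed = TRUE)
  has_path <- FALSE
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    if (i != j && j != k && i != k && adj[i, j] == 1 && adj[j, k] == 1) {
      has_path <- TRUE
      if (adj[i, k] == 0) return("intransitive")
    }
  }
  if (has_path) "transitive" else "not_applicable"
}

.alias_reps_directed <- list(
  empty = integer(0), directed_edge = 1L, mutual = c(1L, 4L),
  v_out = c(1L, 2L), v_in = c(4L, 16L), three_chain = c(1L, 8L),
  mutual_out = c(1L, 4L, 2L), mutual_in = c(1L, 4L, 16L),
  feedforward = c(1L, 8L, 2L), three_loop = c(1L, 8L, 16L),
  double_mutual = c(1L, 4L, 2L, 16L),
  regulating_mutual = c(1L, 2L, 8L, 32L),
  converging_mutual = c(1L, 4L, 2L, 8L),
  mutual_loop = c(1L, 4L, 2L, 32L),
  five_edge = c(1L, 4L, 2L, 16L, 8L),
  complete = c(1L, 2L, 4L, 8L, 16L, 32L))

.alias_reps_undirected <- list(empty = integer(0), single_edge = 1L,
                               two_path = c(1L, 2L), triangle = c(1L, 2L, 4L))

# cached class tables, built on first use
.motif_env <- new.env(parent = emptyenv())

.motif_tables <- function(directed) {
  key <- if (directed) "directed" else "undirected"
  if (!is.null(.motif_env[[key]])) return(.motif_env[[key]])
  canon <- .canon_table(directed)
  codes <- seq_along(canon) - 1
  reps <- sort(unique(canon))
  nedge <- .bitcount(reps)
  ord <- order(nedge, reps)
  reps <- reps[ord]
  classes <- data.frame(class_id = seq_along(reps), canonical = reps,
                        n_edges = nedge[ord],
                        orbit_size = as.integer(table(factor(canon, levels = reps))[
                          as.character(reps)]))
  alias_reps <- if (directed) .alias_reps_directed else .alias_reps_undirected
  alias_canon <- vapply(alias_reps, function(bits) canon[sum(bits) + 1], numeric(1))
  classes$name <- names(alias_reps)[match(classes$canonical, alias_canon)]
  if (directed) {
    classes$transitivity <- vapply(classes$canonical, .transitivity_of_code,
                                   character(1))
  }
  out <- list(classes = classes,
              class_of_code = classes$class_id[match(canon, classes$canonical)])
  .motif_env[[key]] <- out
  out
}

#' Enumerate triad isomorphism classes
#'
#' Exhaustively enumerates all labeled 3-node graphs (8 undirected, 64
#' directed), groups them by canonical form under node permutation, and
#' returns the resulting isomorphism classes: 4 for undirected (electrical)
#' and 16 for directed (chemical) triads. Directed classes carry a
#' transitivity label: a class is `transitive` when every directed 2-path
#' A->B->C is closed by the edge A->C, `not_applicable` when no such 2-path
#' exists, and `intransitive` otherwise.
#'
#' @param edge_type `"electrical"` (undirected) or `"chemical"` (directed).
#' @return data.frame with columns `class_id`, `canonical` (minimal bit
#'   code), `n_edges`, `orbit_size` (number of labeled members), `name`
#'   (field alias, e.g. `feedforward`, `three_loop`), and for directed
#'   classes `transitivity`.
#' @export
motif_classes <- function(edge_type = c("electrical", "chemical")) {
  edge_type <- match.arg(edge_type)
  .motif_tables(edge_type == "chemical")$classes
}

#' Classify a single triad
#'
#' @param edges 2-column matrix of node indices in `1:3` (rows are edges;
#'   ordered pairs when `directed`), or an integer bit code.
#' @param directed logical; directed (chemical) or undirected (electrical).
#' @return One row of [motif_classes()].
#' @export
classify_triad <- function(edges, directed) {
  tab <- .motif_tables(directed)
  if (is.matrix(edges) || is.data.frame(edges)) {
    edges <- as.matrix(edges)
    slots <- if (directed) .d_slots else .u_slots
    code <- 0
    for (r in seq_len(nrow(edges))) {
      e <- edges[r, ]
      if (!directed) e <- sort(e)
      k <- which(slots[, 1] == e[1] & slots[, 2] == e[2])
      if (length(k) != 1) stop("invalid edge: ", paste(edges[r, ], collapse = "->"))
      code <- bitwOr(code, 2^(k - 1))
    }
  } else code <- as.integer(edges)
  tab$classes[tab$class_of_code[code + 1], ]
}

#' Transitivity label of a directed triad class
#'
#' @param class_id class index as in `motif_classes("chemical")`, or a class
#'   `name` alias.
#' @return `"transitive"`, `"intransitive"` or `"not_applicable"`.
#' @export
classify_transitivity <- function(class_id) {
  cls <- motif_classes("chemical")
  if (is.character(class_id)) {
    i <- match(class_id, cls$name)
    if (anyNA(i)) stop("unknown directed class name: ",
                       paste(class_id[is.na(i)], collapse = ", "))
  } else {
    i <- match(class_id, cls$class_id)
    if (anyNA(i)) stop("directed class_id must be in 1..16")
  }
  cls$transitivity[i]
}

# ---- triplet decomposition --------------------------------------------------

# Index structure mapping each triplet to its three pair rows and their
# orientations, so that triad codes can be recomputed cheaply for any
# (simulated) wiring on the same geometry. Vectorised over sets (sizes are
# 2-4, so triplet membership follows fixed templates per size).
.triplet_templates <- list(`3` = matrix(1:3, 1),
                           `4` = rbind(c(1, 2, 3), c(1, 2, 4),
                                       c(1, 3, 4), c(2, 3, 4)))

.triplet_index <- function(data) {
  cells <- data$cells
  pairs <- data$pairs
  ord <- order(cells$set_id)
  runs <- rle(cells$set_id[ord])
  size <- runs$lengths
  start <- cumsum(c(1L, utils::head(size, -1L)))
  # absolute cell-row indices per set, padded to width 4
  cellmat <- matrix(NA_integer_, length(size), 4)
  for (k in 1:4) {
    rows <- which(size >= k)
    cellmat[rows, k] <- ord[start[rows] + k - 1L]
  }
  trip_cells <- NULL
  trip_set <- NULL
  for (sz in c(3L, 4L)) {
    rows <- which(size == sz)
    if (length(rows) == 0) next
    tmpl <- .triplet_templates[[as.character(sz)]]
    for (t in seq_len(nrow(tmpl))) {
      trip_cells <- rbind(trip_cells, cbind(cellmat[rows, tmpl[t, 1]],
                                            cellmat[rows, tmpl[t, 2]],
                                            cellmat[rows, tmpl[t, 3]]))
      trip_set <- c(trip_set, runs$values[rows])
    }
  }
  if (is.null(trip_cells))
    return(list(set_id = character(0), cells = matrix(character(0), 0, 3),
                pidx = matrix(integer(0), 0, 3),
                orient = matrix(logical(0), 0, 3),
                z_dispersion = numeric(0)))
  ids <- matrix(cells$cell_id[trip_cells], ncol = 3)
  key <- paste(pairs$set_id,
               pmin(pairs$cell_a, pairs$cell_b),
               pmax(pairs$cell_a, pairs$cell_b))
  pidx <- matrix(NA_integer_, nrow(ids), 3)
  orient <- matrix(NA, nrow(ids), 3)
  slot <- rbind(c(1, 2), c(1, 3), c(2, 3))
  for (k in 1:3) {
    a <- ids[, slot[k, 1]]
    b <- ids[, slot[k, 2]]
    pidx[, k] <- match(paste(trip_set, pmin(a, b), pmax(a, b)), key)
    # orientation: TRUE when the stored pair (cell_a, cell_b) runs in the
    # same direction as the triplet slot
    orient[, k] <- pairs$cell_a[pidx[, k]] == a
  }
  list(set_id = trip_set, cells = ids, pidx = pidx, orient = orient,
       z_dispersion = (pairs$delta_z_um[pidx[, 1]] +
                       pairs$delta_z_um[pidx[, 2]] +
                       pairs$delta_z_um[pidx[, 3]]) / 3)
}

# vectorised triad codes for a wiring given as per-pair vectors
.triplet_codes <- function(idx, electrical, chem_ab, chem_ba) {
  p <- idx$pidx
  o <- idx$orient
  e <- function(k) as.integer(electrical[p[, k]])
  fwd <- function(k) as.integer(ifelse(o[, k], chem_ab[p[, k]], chem_ba[p[, k]]))
  rev <- function(k) as.integer(ifelse(o[, k], chem_ba[p[, k]], chem_ab[p[, k]]))
  list(ecode = e(1) + 2L * e(2) + 4L * e(3),
       # directed slots (1,2),(1,3),(2,1),(2,3),(3,1),(3,2) = bits 1,2,4,8,16,32
       ccode = fwd(1) + 2L * fwd(2) + 4L * rev(1) +
               8L * fwd(3) + 16L * rev(2) + 32L * rev(3))
}

#' Decompose recording sets into classified triplets
#'
#' Every 3-cell set yields one triplet and every 4-cell set all
#' `choose(4, 3) = 4` triplets; pairs contribute none. Each triplet is
#' classified for both edge types, and its transverse dispersion is the mean
#' of the three pairwise delta-z distances.
#'
#' @param data an [mli_data] object with tested pairs.
#' @return data.frame of class `mli_triplets` with columns `set_id`,
#'   `cell_1..3`, `z_dispersion_um`, `e_code`, `c_code`, `e_class`, `c_class`,
#'   `e_name`, `c_name`, `transitivity`.
#' @export
decompose_triplets <- function(data) {
  idx <- .triplet_index(data)
  pr <- data$pairs
  codes <- .triplet_codes(idx, pr$electrical %in% TRUE,
                          pr$chem_ab %in% TRUE, pr$chem_ba %in% TRUE)
  ut <- .motif_tables(FALSE)
  dt <- .motif_tables(TRUE)
  e_class <- ut$class_of_code[codes$ecode + 1]
  c_class <- dt$class_of_code[codes$ccode + 1]
  out <- data.frame(set_id = idx$set_id,
                    cell_1 = idx$cells[, 1], cell_2 = idx$cells[, 2],
                    cell_3 = idx$cells[, 3],
                    z_dispersion_um = idx$z_dispersion,
                    e_code = codes$ecode, c_code = codes$ccode,
                    e_class = e_class, c_class = c_class,
                    e_name = ut$classes$name[e_class],
                    c_name = dt$classes$name[c_class],
                    transitivity = dt$classes$transitivity[c_class],
                    stringsAsFactors = FALSE)
  attr(out, "triplet_index") <- idx
  class(out) <- c("mli_triplets", "data.frame")
  out
}

#' Motif census of classified triplets
#'
#' Counts and relative frequencies of each triad isomorphism class over a
#' collection of triplets; for directed censuses the transitivity grouping
#' (transitive / intransitive / not applicable) is included.
#'
#' @param triplets output of [decompose_triplets()], or a vector of class
#'   indices.
#' @param edge_type `"electrical"` or `"chemical"`.
#' @return data.frame as [motif_classes()] plus `count` and `frequency`
#'   columns; attribute `n_triplets` holds the total.
#' @export
motif_census <- function(triplets, edge_type = c("electrical", "chemical")) {
  edge_type <- match.arg(edge_type)
  cls <- motif_classes(edge_type)
  id <- if (is.data.frame(triplets)) {
    if (edge_type == "electrical") triplets$e_class else triplets$c_class
  } else triplets
  counts <- as.integer(table(factor(id, levels = cls$class_id)))
  cls$count <- counts
  cls$frequency <- if (sum(counts) > 0) counts / sum(counts) else 0 * counts
  attr(cls, "n_triplets") <- sum(counts)
  cls
}
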