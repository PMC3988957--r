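#' mlinet: motif and null-model analysis of interneuron networks
#'
#' Tools for analysing the connectivity of cerebellar molecular layer
#' interneurons recorded in simultaneous whole-cell configurations of 2-4
#' cells. Two synaptic networks are measured on the same cells: an undirected
#' electrical network (gap junctions, quantified by the coupling coefficient)
#' and a directed chemical network (GABAergic synapses, quantified by IPSC
#' amplitude). The package covers triad motif censuses, clustering and
#' anticlustering coefficients, distance-dependent Monte Carlo null models,
#' common-neighbor analysis, IPSC cross-correlogram synchrony, and
#' molecular-layer position statistics, together with a synthetic-data
#' generator for calibration and power analysis.
#'
#' @section Coordinate conventions:
#' The sagittal plane is xy and the transverse (inter-slice) axis is z, all in
#' micrometres. `ml_pos` is the soma position in the molecular layer
#' normalised between the Purkinje cell layer (0) and the pial surface (1).
#'
#' @name mlinet-package
#' @keywords internal
"_PACKAGE"

# Required columns of the two tabular formats. Distances and edge-weight
# columns of pairs.csv may be left empty (NA); booleans are stored as 0/1.
.cell_cols <- c("cell_id", "set_id", "x_um", "y_um", "z_um")
.pair_cols <- c("cell_a", "cell_b", "electrical", "cc_percent",
                "chem_ab", "chem_ba", "ipsc_ab_pa", "ipsc_ba_pa")

#' Assemble a validated recording data set
#'
#' Bundles a cell table and a pair table into a single object used by all
#' analysis functions. Validation enforces the completeness invariant of
#' simultaneous recordings: a set of n cells must contain exactly
#' `choose(n, 2)` tested pairs, every pair referencing known cells of the same
#' set. Pair distances are recomputed from the cell coordinates when absent
#' and checked for consistency when present.
#'
#' @param cells data.frame with columns `cell_id`, `set_id`, `x_um`, `y_um`,
#'   `z_um` and optionally `ml_pos` (in `[0, 1]`).
#' @param pairs data.frame with columns `cell_a`, `cell_b`, `electrical`,
#'   `cc_percent`, `chem_ab`, `chem_ba`, `ipsc_ab_pa`, `ipsc_ba_pa`;
#'   `delta_xy_um`/`delta_z_um` are recomputed if missing. Connection states
#'   may be all-`NA` for geometry-only (untested) data.
#' @param cc_threshold minimal coupling coefficient (%) for an electrical
#'   edge to exist; edges below it are dropped with a warning. Default 1.
#' @return An object of class `mli_data`: a list with elements `cells` and
#'   `pairs` (pairs gain a `set_id` column).
#' @export
mli_data <- function(cells, pairs, cc_threshold = 1) {
  miss <- setdiff(.cell_cols, names(cells))
  if (length(miss) > 0)
    stop("cells table is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(c("cell_a", "cell_b"), names(pairs))
  if (length(miss) > 0)
    stop("pairs table is missing column(s): ", paste(miss, collapse = ", "))
  for (col in .pair_cols[-(1:2)])
    if (is.null(pairs[[col]])) pairs[[col]] <- NA
  cells$cell_id <- as.character(cells$cell_id)
  cells$set_id <- as.character(cells$set_id)
  pairs$cell_a <- as.character(pairs$cell_a)
  pairs$cell_b <- as.character(pairs$cell_b)
  for (col in c("x_um", "y_um", "z_um"))
    if (any(!is.finite(cells[[col]])))
      stop("non-finite coordinate in cells column ", col)
  if (anyDuplicated(cells$cell_id))
    stop("duplicated cell_id in cells table")
  if (!is.null(cells$ml_pos)) {
    bad <- !is.na(cells$ml_pos) & (cells$ml_pos < 0 | cells$ml_pos > 1)
    if (any(bad)) stop("ml_pos outside [0, 1] for cell(s): ",
                       paste(cells$cell_id[bad], collapse = ", "))
  }
  idx_a <- match(pairs$cell_a, cells$cell_id)
  idx_b <- match(pairs$cell_b, cells$cell_id)
  if (anyNA(idx_a) || anyNA(idx_b)) {
    unknown <- unique(c(pairs$cell_a[is.na(idx_a)], pairs$cell_b[is.na(idx_b)]))
    stop("pair references unknown cell(s): ", paste(unknown, collapse = ", "))
  }
  if (any(pairs$cell_a == pairs$cell_b)) stop("self-pair in pairs table")
  set_a <- cells$set_id[idx_a]
  set_b <- cells$set_id[idx_b]
  if (any(set_a != set_b)) stop("pair spans two recording sets")
  pairs$set_id <- set_a

  # recompute distances from coordinates; validate stored values if present
  dxy <- sqrt((cells$x_um[idx_a] - cells$x_um[idx_b])^2 +
              (cells$y_um[idx_a] - cells$y_um[idx_b])^2)
  dz <- abs(cells$z_um[idx_a] - cells$z_um[idx_b])
  for (nm in c("delta_xy_um", "delta_z_um")) {
    val <- if (nm == "delta_xy_um") dxy else dz
    stored <- pairs[[nm]]
    if (!is.null(stored) && any(!is.na(stored))) {
      ok <- is.na(stored) | abs(stored - val) <= 1e-6
      if (!all(ok)) stop("stored ", nm, " disagrees with coordinates at row ",
                         which(!ok)[1])
    }
    pairs[[nm]] <- val
  }

  # completeness: every unordered pair of every set tested exactly once
  key <- paste(pmin(pairs$cell_a, pairs$cell_b), pmax(pairs$cell_a, pairs$cell_b))
  if (anyDuplicated(key)) stop("duplicated pair observation: ", key[duplicated(key)][1])
  n_cells <- table(cells$set_id)
  n_pairs <- table(factor(pairs$set_id, levels = names(n_cells)))
  expect <- choose(as.integer(n_cells), 2)
  bad <- which(as.integer(n_pairs) != expect)
  if (length(bad) > 0)
    stop("recording set ", names(n_cells)[bad[1]], " has ",
         as.integer(n_pairs)[bad[1]], " pairs, expected ", expect[bad[1]])

  for (col in c("electrical", "chem_ab", "chem_ba"))
    pairs[[col]] <- as.logical(pairs[[col]])
  drop <- !is.na(pairs$electrical) & pairs$electrical &
    !is.na(pairs$cc_percent) & pairs$cc_percent < cc_threshold
  if (any(drop)) {
    warning(sum(drop), " electrical edge(s) below the CC threshold of ",
            cc_threshold, "% dropped")
    pairs$electrical[drop] <- FALSE
    pairs$cc_percent[drop] <- NA_real_
  }
  structure(list(cells = cells, pairs = pairs), class = "mli_data")
}

#' @export
print.mli_data <- function(x, ...) {
  n_sets <- length(unique(x$cells$set_id))
  tested <- !is.na(x$pairs$electrical)
  cat("Multi-patch recording data: ", nrow(x$cells), " cells in ", n_sets,
      " sets, ", nrow(x$pairs), " pairs\n", sep = "")
  if (any(tested)) {
    cat(sprintf("  electrical edges: %d   chemical edges: %d (directed)\n",
                sum(x$pairs$electrical, na.rm = TRUE),
                sum(x$pairs$chem_ab, na.rm = TRUE) +
                  sum(x$pairs$chem_ba, na.rm = TRUE)))
  } else cat("  connectivity untested (geometry only)\n")
  invisible(x)
}

#' Read a cell table from CSV
#'
#' @param path CSV file with header `cell_id,set_id,x_um,y_um,z_um[,ml_pos]`.
#' @return data.frame of cells, one row per recorded neuron.
#' @export
read_cells <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.cell_cols, names(df))
  if (length(miss) > 0)
    stop("cells file is missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("x_um", "y_um", "z_um", if ("ml_pos" %in% names(df)) "ml_pos")) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "")
    if (length(bad) > 0)
      stop("non-numeric value in column ", col, " at row ", bad[1])
    df[[col]] <- num
  }
  df$cell_id <- as.character(df$cell_id)
  df$set_id <- as.character(df$set_id)
  df
}

#' Write a cell table to CSV
#' @param cells data.frame of cells.
#' @param path output path.
#' @export
write_cells <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pair table and assemble a recording data set
#'
#' Booleans are read as 0/1. Distances are recomputed from the cell
#' coordinates when the columns are absent or empty; recording-set
#' completeness (`choose(n, 2)` pairs per set) is enforced.
#'
#' @param path CSV file with header
#'   `cell_a,cell_b,electrical,cc_percent,chem_ab,chem_ba,ipsc_ab_pa,ipsc_ba_pa`
#'   (optionally `delta_xy_um,delta_z_um`).
#' @param cells data.frame of cells as returned by [read_cells()].
#' @inheritParams mli_data
#' @return An [mli_data] object.
#' @export
read_pairs <- function(path, cells, cc_threshold = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("cell_a", "cell_b"), names(df))
  if (length(miss) > 0)
    stop("pairs file is missing column(s): ", paste(miss, collapse = ", "))
  mli_data(cells, df, cc_threshold = cc_threshold)
}

#' Write the pair table of a data set to CSV
#' @param data an [mli_data] object.
#' @param path output path.
#' @export
write_pairs <- function(data, path) {
  df <- data$pairs
  for (col in c("electrical", "chem_ab", "chem_ba"))
    df[[col]] <- as.integer(df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build the multiplex connectivity graph of one or all recording sets
#'
#' Electrical edges are undirected (stored once per unordered pair), chemical
#' edges directed; a bidirectional chemical pair yields two directed edges.
#'
#' @param data an [mli_data] object.
#' @param set_id optional recording-set identifier; default uses all sets.
#' @return Object of class `mli_graph`: list with `nodes` (character),
#'   `electrical` (2-column character matrix, unordered pairs) and `chemical`
#'   (2-column character matrix, ordered source/target pairs).
#' @export
to_graph <- function(data, set_id = NULL) {
  cells <- data$cells
  pairs <- data$pairs
  if (!is.null(set_id)) {
    cells <- cells[cells$set_id %in% set_id, , drop = FALSE]
    pairs <- pairs[pairs$set_id %in% set_id, , drop = FALSE]
  }
  e <- !is.na(pairs$electrical) & pairs$electrical
  ab <- !is.na(pairs$chem_ab) & pairs$chem_ab
  ba <- !is.na(pairs$chem_ba) & pairs$chem_ba
  elec <- cbind(pmin(pairs$cell_a[e], pairs$cell_b[e]),
                pmax(pairs$cell_a[e], pairs$cell_b[e]))
  chem <- rbind(cbind(pairs$cell_a[ab], pairs$cell_b[ab]),
                cbind(pairs$cell_b[ba], pairs$cell_a[ba]))
  structure(list(nodes = cells$cell_id,
                 electrical = matrix(elec, ncol = 2),
                 chemical = matrix(chem, ncol = 2)),
            class = "mli_graph")
}

#' @export
print.mli_graph <- function(x, ...) {
  cat("Multiplex connectivity graph: ", length(x$nodes), " nodes, ",
      nrow(x$electrical), " electrical (undirected), ",
      nrow(x$chemical), " chemical (directed) edges\n", sep = "")
  invisible(x)
}

#' Convert a connectivity graph to igraph
#'
#' The multiplex graph becomes a directed igraph with an edge attribute
#' `type`; each undirected electrical edge is represented by a single arc
#' flagged `electrical` (interpreted symmetrically).
#'
#' @param graph an `mli_graph`.
#' @return A directed [igraph::igraph] object.
#' @export
as_igraph <- function(graph) {
  edges <- rbind(graph$electrical, graph$chemical)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2],
               type = rep(c("electrical", "chemical"),
                          c(nrow(graph$electrical), nrow(graph$chemical))),
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = graph$nodes, stringsAsFactors = FALSE))
  g
}

#' Write a connectivity graph to GraphML
#'
#' @param graph an `mli_graph`.
#' @param path output path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' Read a connectivity graph from GraphML
#'
#' Inverse of [write_graphml()]; edges with attribute `type == "electrical"`
#' become undirected electrical edges.
#'
#' @param path GraphML file written by [write_graphml()].
#' @return An `mli_graph`.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g)
  type <- igraph::edge_attr(g, "type")
  if (is.null(type)) stop("GraphML file lacks the edge attribute 'type'")
  e <- type == "electrical"
  structure(list(nodes = igraph::vertex_attr(g, "name"),
                 electrical = matrix(cbind(pmin(el[e, 1], el[e, 2]),
                                           pmax(el[e, 1], el[e, 2])), ncol = 2),
                 chemical = matrix(el[!e, , drop = FALSE], ncol = 2)),
            class = "mli_graph")
}
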