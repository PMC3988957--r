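# Synthetic multi-patch data generator. Emulates the geometry of local
# sampling (pairwise distances capped at 180 um in the sagittal plane and
# 50 um along the transverse axis), the wiring statistics (baseline
# p_E = 0.42, p_C = 0.20, logistic distance decay with electrical coupling
# confined near the sagittal plane), optional structured wiring (triadic
# closure of electrical edges, transitive closure of directed 2-paths,
# downward orientation of chemical edges in the molecular layer), IPSC event
# trains with shared presynaptic sources, and morphological point clouds.

.max_dxy <- 180
.max_dz <- 50

#' Default logistic distance-decay profiles
#'
#' Per-axis logistic decay `p(d) = 1 / (1 + exp((d - d0) / s))` multiplied
#' across axes and scaled by `p0`. The defaults qualitatively reproduce the
#' measured decay of connection probability: electrical coupling falls off
#' steeply along the transverse axis (half-distance 20 um) and more slowly in
#' the sagittal plane (60 um); chemical connectivity decays weakly on both
#' axes.
#'
#' @param type `"electrical"` or `"chemical"`.
#' @return List with elements `p0`, `d0_xy`, `s_xy`, `d0_z`, `s_z`. A
#'   profile may additionally carry `xy_max` / `z_max`, hard caps beyond
#'   which the probability is exactly zero.
#' @export
default_profile <- function(type = c("electrical", "chemical")) {
  type <- match.arg(type)
  if (type == "electrical")
    list(p0 = 0.65, d0_xy = 60, s_xy = 20, d0_z = 20, s_z = 5)
  else
    list(p0 = 0.30, d0_xy = 120, s_xy = 40, d0_z = 40, s_z = 15)
}

# evaluate a decay profile at pair distances; optional hard caps xy_max /
# z_max force the probability to exactly 0 beyond them
.profile_prob <- function(profile, dxy, dz) {
  lg <- function(d, d0, s) 1 / (1 + exp((d - d0) / s))
  p <- pmin(1, pmax(0, profile$p0 * lg(dxy, profile$d0_xy, profile$s_xy) *
                      lg(dz, profile$d0_z, profile$s_z)))
  if (!is.null(profile$xy_max)) p[dxy > profile$xy_max] <- 0
  if (!is.null(profile$z_max)) p[dz > profile$z_max] <- 0
  p
}

#' Generate recording-set geometry
#'
#' Draws `n_sets` simultaneous recording sets of 2-4 cells. Cells of a set
#' are scattered around a random local centre (Gaussian offsets with the
#' given spreads); rejection sampling enforces the tested distance range of
#' the recordings (all pairwise distances at most 180 um in xy and 50 um in
#' z). Molecular-layer positions are drawn uniformly in `ml_band`.
#'
#' @param n_sets number of recording sets.
#' @param cells_per_set integer vector of set sizes to sample from (with
#'   replacement), or a single size; default `c(2, 3, 4)`.
#' @param size_probs sampling weights for `cells_per_set`; default uniform.
#' @param xy_spread_um Gaussian SD of cell offsets in the sagittal plane
#'   (default 40).
#' @param z_spread_um Gaussian SD along the transverse axis (default 12).
#' @param ml_band range of normalized molecular-layer positions sampled
#'   (default `c(0.1, 0.9)`).
#' @param seed optional integer seed.
#' @param max_retries rejection-sampling retries per set before aborting.
#' @return An [mli_data] object with untested pairs (geometry only).
#' @export
generate_geometry <- function(n_sets, cells_per_set = c(2, 3, 4),
                              size_probs = NULL, xy_spread_um = 40,
                              z_spread_um = 12, ml_band = c(0.1, 0.9),
                              seed = NULL, max_retries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  if (xy_spread_um <= 0 || z_spread_um <= 0) stop("spreads must be positive")
  if (any(cells_per_set < 2 | cells_per_set > 4))
    stop("cells_per_set must lie in 2..4")
  sizes <- if (length(cells_per_set) == 1) rep(cells_per_set, n_sets)
           else sample(cells_per_set, n_sets, replace = TRUE, prob = size_probs)
  total <- sum(sizes)
  set_of <- rep(seq_len(n_sets), sizes)
  # vectorised rejection: redraw whole sets whose pairwise caps are violated
  x <- y <- z <- numeric(total)
  todo <- seq_len(n_sets)
  tries <- 0
  cx <- stats::runif(n_sets, 0, 500)
  cy <- stats::runif(n_sets, 0, 500)
  cz <- stats::runif(n_sets, 0, 100)
  while (length(todo) > 0) {
    if (tries >= max_retries)
      stop("could not satisfy distance caps after ", max_retries,
           " retries; reduce the spreads")
    sel <- set_of %in% todo
    x[sel] <- cx[set_of[sel]] + stats::rnorm(sum(sel), 0, xy_spread_um)
    y[sel] <- cy[set_of[sel]] + stats::rnorm(sum(sel), 0, xy_spread_um)
    z[sel] <- cz[set_of[sel]] + stats::rnorm(sum(sel), 0, z_spread_um)
    ok <- vapply(todo, function(s) {
      i <- which(set_of == s)
      if (length(i) < 2) return(TRUE)
      dxy <- stats::dist(cbind(x[i], y[i]))
      dz <- stats::dist(z[i])
      max(dxy) <= .max_dxy && max(dz) <= .max_dz
    }, logical(1))
    todo <- todo[!ok]
    tries <- tries + 1
  }
  cells <- data.frame(
    cell_id = sprintf("c%04d", seq_len(total)),
    set_id = sprintf("s%04d", set_of),
    x_um = x, y_um = y, z_um = z,
    ml_pos = stats::runif(total, ml_band[1], ml_band[2]),
    stringsAsFactors = FALSE)
  pairs <- do.call(rbind, lapply(split(cells$cell_id, cells$set_id), function(ids) {
    if (length(ids) < 2) return(NULL)
    cmb <- utils::combn(ids, 2)
    data.frame(cell_a = cmb[1, ], cell_b = cmb[2, ], stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  mli_data(cells, pairs)
}

# truncated log-normal with target (untruncated) mean and SD
.rlnorm_ms <- function(n, mean, sd, lower = 0) {
  sdlog2 <- log(1 + (sd / mean)^2)
  v <- stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
  while (any(v < lower)) {
    i <- v < lower
    v[i] <- stats::rlnorm(sum(i), meanlog = log(mean) - sdlog2 / 2,
                          sdlog = sqrt(sdlog2))
  }
  v
}

#' Wire a generated geometry
#'
#' Fills the pair observations of a geometry under one of three generative
#' models:
#' \describe{
#'   \item{`uniform`}{every electrical edge Bernoulli(`p_e`), every directed
#'     chemical edge Bernoulli(`p_c`), all independent.}
#'   \item{`distance`}{per-pair probabilities from logistic decay profiles
#'     evaluated at the pair's (delta-xy, delta-z).}
#'   \item{`structured`}{after the independent pass (uniform or distance
#'     base), a single closure pass in a fixed random order adds the third
#'     electrical edge of each open electrical 2-path with probability
#'     `clustering_bias`, adds the closing edge A->C of each directed 2-path
#'     A->B->C with probability `transitivity_bias`, and reorients each
#'     chemical edge downward in the molecular layer (from higher to lower
#'     `ml_pos`) with probability `ml_direction_bias`.}
#' }
#' Coupling coefficients for electrical edges are drawn log-normal with mean
#' 7.13% and SD 6.02%, truncated at the 1% detection threshold; IPSC
#' amplitudes log-normal with mean 11.2 pA and SD 9.2 pA.
#'
#' @param data geometry from [generate_geometry()] (an [mli_data] object).
#' @param model `"uniform"`, `"distance"` or `"structured"`.
#' @param p_e,p_c baseline probabilities (defaults 0.42 and 0.20, the
#'   measured pair-level rates).
#' @param e_profile,c_profile decay profiles for the distance model, as
#'   [default_profile()].
#' @param clustering_bias,transitivity_bias,ml_direction_bias structural
#'   biases in `[0, 1]` (structured model only).
#' @param structured_base base model for the independent pass of the
#'   structured model: `"uniform"` (default) or `"distance"`.
#' @param seed optional integer seed.
#' @return The [mli_data] object with pair observations filled in.
#' @export
wire <- function(data, model = c("uniform", "distance", "structured"),
                 p_e = 0.42, p_c = 0.20,
                 e_profile = default_profile("electrical"),
                 c_profile = default_profile("chemical"),
                 clustering_bias = 0, transitivity_bias = 0,
                 ml_direction_bias = 0,
                 structured_base = c("uniform", "distance"), seed = NULL) {
  model <- match.arg(model)
  structured_base <- match.arg(structured_base)
  if (!is.null(seed)) set.seed(seed)
  pr <- data$pairs
  n <- nrow(pr)
  base <- if (model == "distance" ||
              (model == "structured" && structured_base == "distance")) {
    list(pe = .profile_prob(e_profile, pr$delta_xy_um, pr$delta_z_um),
         pc = .profile_prob(c_profile, pr$delta_xy_um, pr$delta_z_um))
  } else list(pe = rep(p_e, n), pc = rep(p_c, n))
  pr$electrical <- stats::runif(n) < base$pe
  pr$chem_ab <- stats::runif(n) < base$pc
  pr$chem_ba <- stats::runif(n) < base$pc

  if (model == "structured") {
    pr <- .closure_pass(data$cells, pr, clustering_bias, transitivity_bias)
    if (ml_direction_bias > 0)
      pr <- .ml_reorient(data$cells, pr, ml_direction_bias)
  }

  pr$cc_percent <- NA_real_
  pr$ipsc_ab_pa <- NA_real_
  pr$ipsc_ba_pa <- NA_real_
  ne <- sum(pr$electrical)
  if (ne > 0) pr$cc_percent[pr$electrical] <- .rlnorm_ms(ne, 7.13, 6.02, lower = 1)
  if (any(pr$chem_ab))
    pr$ipsc_ab_pa[pr$chem_ab] <- .rlnorm_ms(sum(pr$chem_ab), 11.2, 9.2)
  if (any(pr$chem_ba))
    pr$ipsc_ba_pa[pr$chem_ba] <- .rlnorm_ms(sum(pr$chem_ba), 11.2, 9.2)
  data$pairs <- pr
  data
}

# one closure pass over triplets in a fixed random order
.closure_pass <- function(cells, pr, clustering_bias, transitivity_bias) {
  if (clustering_bias <= 0 && transitivity_bias <= 0) return(pr)
  key <- paste(pr$set_id, pmin(pr$cell_a, pr$cell_b), pmax(pr$cell_a, pr$cell_b))
  rowmap <- new.env(parent = emptyenv(), size = length(key))
  for (i in seq_along(key)) assign(key[i], i, envir = rowmap)
  sets <- split(cells$cell_id, cells$set_id)
  trips <- list()
  for (sid in names(sets)) {
    ids <- sets[[sid]]
    if (length(ids) < 3) next
    cmb <- utils::combn(ids, 3)
    for (j in seq_len(ncol(cmb)))
      trips[[length(trips) + 1]] <- list(sid = sid, ids = cmb[, j])
  }
  if (length(trips) == 0) return(pr)
  prow <- function(sid, a, b)
    get(paste(sid, min(a, b), max(a, b)), envir = rowmap)
  has_chem <- function(i, a, b) {
    if (pr$cell_a[i] == a) pr$chem_ab[i] else pr$chem_ba[i]
  }
  set_chem <- function(i, a) {
    if (pr$cell_a[i] == a) pr$chem_ab[i] <<- TRUE else pr$chem_ba[i] <<- TRUE
  }
  for (t in sample(seq_along(trips))) {
    sid <- trips[[t]]$sid
    ids <- trips[[t]]$ids
    rows <- c(prow(sid, ids[1], ids[2]), prow(sid, ids[1], ids[3]),
              prow(sid, ids[2], ids[3]))
    if (clustering_bias > 0) {
      e <- pr$electrical[rows]
      if (sum(e) == 2 && stats::runif(1) < clustering_bias)
        pr$electrical[rows[!e]] <- TRUE
    }
    if (transitivity_bias > 0) {
      # close each open directed 2-path A->B->C with A->C
      for (perm in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                        c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))) {
        a <- ids[perm[1]]; b <- ids[perm[2]]; cc <- ids[perm[3]]
        i_ab <- prow(sid, a, b); i_bc <- prow(sid, b, cc); i_ac <- prow(sid, a, cc)
        if (has_chem(i_ab, a, b) && has_chem(i_bc, b, cc) &&
            !has_chem(i_ac, a, cc) && stats::runif(1) < transitivity_bias)
          set_chem(i_ac, a)
      }
    }
  }
  pr
}

# reorient chemical edges downward in ml_pos with the given probability
.ml_reorient <- function(cells, pr, bias) {
  ml <- stats::setNames(cells$ml_pos, cells$cell_id)
  for (i in seq_len(nrow(pr))) {
    ml_a <- ml[pr$cell_a[i]]
    ml_b <- ml[pr$cell_b[i]]
    if (is.na(ml_a) || is.na(ml_b) || ml_a == ml_b) next
    down_is_ab <- ml_a > ml_b
    for (dir in c("ab", "ba")) {
      on <- if (dir == "ab") pr$chem_ab[i] else pr$chem_ba[i]
      if (!on) next
      if (stats::runif(1) < bias) {
        # point this edge downward
        if (down_is_ab) { pr$chem_ab[i] <- TRUE; if (dir == "ba") pr$chem_ba[i] <- FALSE }
        else { pr$chem_ba[i] <- TRUE; if (dir == "ab") pr$chem_ab[i] <- FALSE }
      }
    }
  }
  pr
}

#' Generate IPSC event trains with shared presynaptic sources
#'
#' Each cell receives a private Poisson train of rate
#' `(1 - shared_fraction) * rate_hz`; designated pairs additionally share a
#' common Poisson source of rate `shared_fraction * rate_hz` delivered to
#' both cells with independent Gaussian jitter (SD `jitter_ms`), so every
#' cell's total rate is `rate_hz`. This emulates the IPSC synchrony produced
#' by a shared presynaptic interneuron (a diverging chemical motif onto the
#' pair).
#'
#' @param cell_ids character vector of cell identifiers.
#' @param shared_pairs optional 2-column matrix/data.frame of cell-id pairs
#'   sharing a source.
#' @param rate_hz total event rate per cell (default 10).
#' @param shared_fraction fraction of the rate contributed by the shared
#'   source for designated pairs (default 0).
#' @param jitter_ms SD of the delivery jitter of shared events (default 1).
#' @param duration_s recording length (default 100).
#' @param seed optional integer seed.
#' @return Named list of `mli_event_train` objects (see [event_train()]).
#' @export
generate_event_trains <- function(cell_ids, shared_pairs = NULL, rate_hz = 10,
                                  shared_fraction = 0, jitter_ms = 1,
                                  duration_s = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (duration_s <= 0) stop("duration must be positive")
  if (rate_hz <= 0) stop("rate must be positive")
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]")
  shared_of <- stats::setNames(vector("list", length(cell_ids)), cell_ids)
  if (!is.null(shared_pairs) && shared_fraction > 0) {
    shared_pairs <- as.matrix(shared_pairs)
    for (r in seq_len(nrow(shared_pairs))) {
      src <- stats::rpois(1, shared_fraction * rate_hz * duration_s)
      times <- sort(stats::runif(src, 0, duration_s))
      for (cid in shared_pairs[r, ]) {
        jit <- times + stats::rnorm(src, 0, jitter_ms / 1000)
        shared_of[[cid]] <- c(shared_of[[cid]], jit[jit > 0 & jit < duration_s])
      }
    }
  }
  private_rate <- (1 - shared_fraction) * rate_hz
  out <- lapply(cell_ids, function(cid) {
    k <- stats::rpois(1, private_rate * duration_s)
    times <- sort(c(stats::runif(k, 0, duration_s), shared_of[[cid]]))
    event_train(times, duration_s)
  })
  stats::setNames(out, cell_ids)
}

#' Generate a morphological point cloud
#'
#' Labelled 3-D point sets emulating the somatodendritic morphology density
#' of molecular layer interneurons: along the transverse z axis, dendritic
#' points are Gaussian with SD `sigma_dendrite_z_um` and axonal points with
#' the wider SD `sigma_axon_z_um` (defaults half of the measured full widths
#' 2-sigma = 24.1 um and 41.3 um), reflecting the confinement of dendrites
#' near the sagittal plane.
#'
#' @param n_points points per compartment (default 1e4).
#' @param sigma_dendrite_z_um,sigma_axon_z_um Gaussian SDs along z.
#' @param xy_spread_um SD of the in-plane scatter (default 60).
#' @param seed optional integer seed.
#' @return data.frame with columns `compartment` (`dendrite`/`axon`), `x_um`,
#'   `y_um`, `z_um`.
#' @export
generate_morph_cloud <- function(n_points = 1e4,
                                 sigma_dendrite_z_um = 24.1 / 2,
                                 sigma_axon_z_um = 41.3 / 2,
                                 xy_spread_um = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sigma_dendrite_z_um <= 0 || sigma_axon_z_um <= 0)
    stop("sigmas must be positive")
  one <- function(label, sigma) data.frame(
    compartment = label,
    x_um = stats::rnorm(n_points, 0, xy_spread_um),
    y_um = stats::rnorm(n_points, 0, xy_spread_um),
    z_um = stats::rnorm(n_points, 0, sigma),
    stringsAsFactors = FALSE)
  rbind(one("dendrite", sigma_dendrite_z_um), one("axon", sigma_axon_z_um))
}
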