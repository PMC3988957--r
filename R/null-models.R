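# Pair-level statistics, distance-dependence estimation, random connectivity
# models conditioned on the recorded geometry, and Monte Carlo significance
# testing with Bonferroni correction.

.categories <- c("none", "electrical_only", "chemical_only", "dual",
                 "bidirectional", "bidirectional_electrical")

#' Pair-level connection probabilities and category distribution
#'
#' Estimates the electrical connection probability `p_e = n_E / n_pairs`, the
#' directed chemical connection probability `p_c = n_C / (2 n_pairs)` (each
#' pair offers two possible chemical connections), the probability of at
#' least one chemical synapse, and assigns each pair to one of six mutually
#' exclusive categories: no connection, electrical only, chemical only, dual
#' (electrical + unidirectional chemical), bidirectional chemical, and
#' bidirectional chemical with electrical.
#'
#' @param data an [mli_data] object with tested pairs.
#' @return List of class `mli_pair_stats`: `p_e`, `p_c`, `p_chem_any`,
#'   `p_dual_exclusive` (electrical + unidirectional chemical),
#'   `p_dual_any` (electrical + any chemical), `n_pairs`, `categories`
#'   (named probabilities) and `counts`.
#' @export
pair_probabilities <- function(data) {
  pr <- data$pairs
  if (nrow(pr) == 0) stop("no pairs in data")
  e <- pr$electrical %in% TRUE
  ab <- pr$chem_ab %in% TRUE
  ba <- pr$chem_ba %in% TRUE
  n <- nrow(pr)
  nchem <- ab + ba
  cat_id <- ifelse(nchem == 2 & e, "bidirectional_electrical",
            ifelse(nchem == 2, "bidirectional",
            ifelse(nchem == 1 & e, "dual",
            ifelse(nchem == 1, "chemical_only",
            ifelse(e, "electrical_only", "none")))))
  counts <- table(factor(cat_id, levels = .categories))
  structure(list(
    p_e = sum(e) / n,
    p_c = sum(nchem) / (2 * n),
    p_chem_any = sum(nchem > 0) / n,
    p_dual_exclusive = sum(e & nchem == 1) / n,
    p_dual_any = sum(e & nchem > 0) / n,
    n_pairs = n,
    counts = counts,
    categories = as.numeric(counts) / n), class = "mli_pair_stats")
}

#' @export
print.mli_pair_stats <- function(x, ...) {
  cat(sprintf("Pair statistics over %d tested pairs:\n", x$n_pairs))
  cat(sprintf("  p_E = %.3f   p_C = %.3f   p(>=1 chemical) = %.3f\n",
              x$p_e, x$p_c, x$p_chem_any))
  tab <- data.frame(category = .categories, count = as.integer(x$counts),
                    probability = round(x$categories, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Pair-category distribution under independent wiring
#'
#' Closed-form probabilities of the six pair categories when the electrical
#' edge (probability `p_e`) and each of the two directed chemical edges
#' (probability `p_c` each) are drawn independently (the uniform random
#' model).
#'
#' @param p_e electrical connection probability.
#' @param p_c directed chemical connection probability.
#' @return Named numeric vector over the six categories; sums to 1.
#' @export
pair_category_probs <- function(p_e, p_c) {
  if (p_e < 0 || p_e > 1 || p_c < 0 || p_c > 1)
    stop("probabilities must lie in [0, 1]")
  q <- c(none = (1 - p_e) * (1 - p_c)^2,
         electrical_only = p_e * (1 - p_c)^2,
         chemical_only = (1 - p_e) * 2 * p_c * (1 - p_c),
         dual = p_e * 2 * p_c * (1 - p_c),
         bidirectional = (1 - p_e) * p_c^2,
         bidirectional_electrical = p_e * p_c^2)
  q
}

#' Recover pair probabilities from a category distribution
#'
#' Inverse bookkeeping of [pair_probabilities()]: given the six category
#' probabilities (e.g. a published table), reconstruct `p_e`, `p_c` and the
#' probability of at least one chemical connection.
#'
#' @param categories numeric vector of six category probabilities, in the
#'   order none, electrical_only, chemical_only, dual, bidirectional,
#'   bidirectional_electrical (names optional).
#' @return List with `p_e`, `p_c`, `p_chem_any`, `p_dual_exclusive`,
#'   `p_dual_any`.
#' @export
category_to_pair_probs <- function(categories) {
  if (length(categories) != 6) stop("need six category probabilities")
  q <- unname(categories)
  list(p_e = q[2] + q[4] + q[6],
       p_c = (q[3] + q[4] + 2 * (q[5] + q[6])) / 2,
       p_chem_any = q[3] + q[4] + q[5] + q[6],
       p_dual_exclusive = q[4],
       p_dual_any = q[4] + q[6])
}

# ---- distance profiles ------------------------------------------------------

#' Binned connection probability versus intersomatic distance
#'
#' Empirical probability of electrical and chemical connections per distance
#' bin along one axis (sagittal-plane `xy` or transverse `z`), with
#' per-bin SD from a nonparametric bootstrap over pairs. The chemical
#' probability is per directed possibility (two per pair).
#'
#' @param data an [mli_data] object.
#' @param axis `"xy"` or `"z"`.
#' @param breaks bin edges in micrometres; defaults to 20 um bins up to
#'   180 um for `xy` and 10 um bins up to 50 um for `z`.
#' @param n_boot bootstrap resamples (>= 100; default 200).
#' @return data.frame of class `mli_profile` with columns `lower`, `upper`,
#'   `mid`, `n`, `p_e`, `p_e_sd`, `p_c`, `p_c_sd`; empty bins hold `NA`.
#' @export
estimate_profiles <- function(data, axis = c("xy", "z"), breaks = NULL,
                              n_boot = 200) {
  axis <- match.arg(axis)
  if (n_boot < 100) stop("n_boot must be at least 100")
  if (is.null(breaks))
    breaks <- if (axis == "xy") seq(0, 180, by = 20) else seq(0, 50, by = 10)
  d <- if (axis == "xy") data$pairs$delta_xy_um else data$pairs$delta_z_um
  e <- data$pairs$electrical %in% TRUE
  nchem <- (data$pairs$chem_ab %in% TRUE) + (data$pairs$chem_ba %in% TRUE)
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  nb <- length(breaks) - 1
  stat <- function(idx) {
    b <- bin[idx]
    n <- tabulate(b, nb)
    pe <- vapply(seq_len(nb), function(k)
      if (n[k] > 0) mean(e[idx][b == k]) else NA_real_, numeric(1))
    pc <- vapply(seq_len(nb), function(k)
      if (n[k] > 0) sum(nchem[idx][b == k]) / (2 * n[k]) else NA_real_,
      numeric(1))
    list(n = n, p_e = pe, p_c = pc)
  }
  obs <- stat(seq_along(d))
  boot_e <- matrix(NA_real_, n_boot, nb)
  boot_c <- matrix(NA_real_, n_boot, nb)
  for (bb in seq_len(n_boot)) {
    s <- stat(sample.int(length(d), replace = TRUE))
    boot_e[bb, ] <- s$p_e
    boot_c[bb, ] <- s$p_c
  }
  out <- data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
                    mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    n = obs$n, p_e = obs$p_e,
                    p_e_sd = apply(boot_e, 2, stats::sd, na.rm = TRUE),
                    p_c = obs$p_c,
                    p_c_sd = apply(boot_c, 2, stats::sd, na.rm = TRUE))
  attr(out, "axis") <- axis
  class(out) <- c("mli_profile", "data.frame")
  out
}

# interpolating lookup on a binned profile; empty bins filled from neighbours
.profile_fun <- function(profile, column) {
  mid <- profile$mid
  p <- profile[[column]]
  ok <- !is.na(p)
  if (!any(ok)) stop("profile has no occupied bin for ", column)
  function(d) {
    v <- stats::approx(mid[ok], p[ok], xout = d, rule = 2)$y
    pmin(pmax(v, 0), 1)
  }
}

# ---- the null-model estimator ----------------------------------------------

#' Fit a random connectivity model to recorded data
#'
#' Fits one of three generative null models to the pair data:
#' \describe{
#'   \item{`uniform`}{every electrical edge has probability `p_e` and every
#'     directed chemical edge probability `p_c`, all independent.}
#'   \item{`nonuniform_distance`}{per-pair probabilities follow the measured
#'     distance dependence: a separable product of the binned xy- and z-axis
#'     profiles, rescaled so the model reproduces the observed global
#'     connection counts on the recorded geometry.}
#'   \item{`nonuniform_distance_ml`}{additionally reweights the direction of
#'     chemical edges by a two-bin molecular-layer table (downward, i.e.
#'     towards the Purkinje cell layer, versus upward) estimated from the
#'     data.}
#' }
#'
#' @param data an [mli_data] object with tested pairs.
#' @param kind model kind, see above.
#' @param p_e,p_c optional known average connection probabilities; when
#'   supplied they replace the rates estimated from `data` (useful when the
#'   generating rates of a simulation are known, or to impose published
#'   values).
#' @param xy_breaks,z_breaks distance-bin edges passed to
#'   [estimate_profiles()].
#' @param n_boot bootstrap resamples for the profile SDs.
#' @return Object of class `mli_null` with [predict][predict.mli_null] and
#'   [simulate][simulate.mli_null] methods.
#' @seealso [sample_networks()], [motif_ratio_test()]
#' @export
fit_null_model <- function(data,
                           kind = c("uniform", "nonuniform_distance",
                                    "nonuniform_distance_ml"),
                           p_e = NULL, p_c = NULL,
                           xy_breaks = NULL, z_breaks = NULL, n_boot = 200) {
  kind <- match.arg(kind)
  stats <- pair_probabilities(data)
  obj <- list(kind = kind,
              p_e = if (is.null(p_e)) stats$p_e else p_e,
              p_c = if (is.null(p_c)) stats$p_c else p_c,
              data = data)
  if (kind != "uniform") {
    prof_xy <- estimate_profiles(data, "xy", xy_breaks, n_boot)
    prof_z <- estimate_profiles(data, "z", z_breaks, n_boot)
    obj$profile_xy <- prof_xy
    obj$profile_z <- prof_z
    # separable product normalised to reproduce the global counts on the
    # recorded geometry (one-axis marginals do not identify a 2-D rule)
    dxy <- data$pairs$delta_xy_um
    dz <- data$pairs$delta_z_um
    raw_e <- .profile_fun(prof_xy, "p_e")(dxy) * .profile_fun(prof_z, "p_e")(dz)
    raw_c <- .profile_fun(prof_xy, "p_c")(dxy) * .profile_fun(prof_z, "p_c")(dz)
    obj$scale_e <- if (mean(raw_e) > 0) obj$p_e / mean(raw_e) else 0
    obj$scale_c <- if (mean(raw_c) > 0) obj$p_c / mean(raw_c) else 0
  }
  if (kind == "nonuniform_distance_ml") {
    if (is.null(data$cells$ml_pos) || all(is.na(data$cells$ml_pos)))
      stop("nonuniform_distance_ml requires ml_pos in the cell table")
    ml <- stats::setNames(data$cells$ml_pos, data$cells$cell_id)
    pr <- data$pairs
    ml_a <- ml[pr$cell_a]
    ml_b <- ml[pr$cell_b]
    down <- sum((pr$chem_ab %in% TRUE) & ml_a > ml_b, na.rm = TRUE) +
            sum((pr$chem_ba %in% TRUE) & ml_b > ml_a, na.rm = TRUE)
    up <- sum((pr$chem_ab %in% TRUE) & ml_a < ml_b, na.rm = TRUE) +
          sum((pr$chem_ba %in% TRUE) & ml_b < ml_a, na.rm = TRUE)
    obj$p_down <- if (down + up > 0) down / (down + up) else 0.5
  }
  class(obj) <- "mli_null"
  obj
}

#' @export
print.mli_null <- function(x, ...) {
  cat("Random connectivity model (", x$kind, ")\n", sep = "")
  cat(sprintf("  global p_E = %.3f, p_C = %.3f over %d pairs\n",
              x$p_e, x$p_c, nrow(x$data$pairs)))
  if (!is.null(x$p_down))
    cat(sprintf("  chemical direction bias: P(downward | connected) = %.3f\n",
                x$p_down))
  invisible(x)
}

#' @export
summary.mli_null <- function(object, ...) {
  print(object)
  if (!is.null(object$profile_xy)) {
    cat("  xy profile:\n")
    print(as.data.frame(object$profile_xy), row.names = FALSE, digits = 3)
    cat("  z profile:\n")
    print(as.data.frame(object$profile_z), row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Per-pair connection probabilities under a fitted null model
#'
#' @param object an `mli_null` model.
#' @param newdata an [mli_data] object (default: the fitted data); per-pair
#'   probabilities are evaluated on its geometry.
#' @param ... unused.
#' @return data.frame with one row per pair: `p_e`, `p_c_ab`, `p_c_ba`
#'   (directed chemical probabilities; equal unless the model carries the
#'   molecular-layer direction bias).
#' @export
predict.mli_null <- function(object, newdata = NULL, ...) {
  data <- if (is.null(newdata)) object$data else newdata
  pr <- data$pairs
  n <- nrow(pr)
  if (object$kind == "uniform") {
    pe <- rep(object$p_e, n)
    pc <- rep(object$p_c, n)
  } else {
    pe <- pmin(1, object$scale_e *
                 .profile_fun(object$profile_xy, "p_e")(pr$delta_xy_um) *
                 .profile_fun(object$profile_z, "p_e")(pr$delta_z_um))
    pc <- pmin(1, object$scale_c *
                 .profile_fun(object$profile_xy, "p_c")(pr$delta_xy_um) *
                 .profile_fun(object$profile_z, "p_c")(pr$delta_z_um))
  }
  out <- data.frame(p_e = pe, p_c_ab = pc, p_c_ba = pc)
  if (!is.null(object$p_down)) {
    ml <- stats::setNames(data$cells$ml_pos, data$cells$cell_id)
    ml_a <- ml[pr$cell_a]
    ml_b <- ml[pr$cell_b]
    w_ab <- ifelse(is.na(ml_a) | is.na(ml_b), 1,
                   ifelse(ml_a > ml_b, 2 * object$p_down, 2 * (1 - object$p_down)))
    out$p_c_ab <- pmin(1, pc * w_ab)
    out$p_c_ba <- pmin(1, pc * ifelse(is.na(ml_a) | is.na(ml_b), 1,
                                      ifelse(ml_b > ml_a, 2 * object$p_down,
                                             2 * (1 - object$p_down))))
  }
  out
}

#' Monte Carlo wirings of a null model on a recorded geometry
#'
#' Draws `nsim` independent wirings: each electrical and directed chemical
#' edge is Bernoulli with the per-pair probability of
#' [predict.mli_null()], conditioned on the recorded geometry (cell
#' positions and set structure are kept fixed).
#'
#' @param object an `mli_null` model.
#' @param nsim number of wirings.
#' @param seed optional integer seed (restores the RNG state afterwards).
#' @param newdata optional [mli_data] geometry; default the fitted data.
#' @param ... unused.
#' @return List of class `mli_null_sim` with logical matrices `electrical`,
#'   `chem_ab`, `chem_ba` of dimension `nsim` x `n_pairs`.
#' @export
simulate.mli_null <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  p <- predict(object, newdata = newdata)
  n <- nrow(p)
  draw <- function(prob) matrix(stats::runif(nsim * n) <
                                  rep(prob, each = nsim), nsim, n)
  structure(list(electrical = draw(p$p_e),
                 chem_ab = draw(p$p_c_ab),
                 chem_ba = draw(p$p_c_ba)),
            class = "mli_null_sim")
}

#' @rdname simulate.mli_null
#' @param data geometry to wire, an [mli_data] object.
#' @param model fitted `mli_null` model.
#' @param n_samples number of Monte Carlo wirings.
#' @export
sample_networks <- function(data, model, n_samples, seed = NULL) {
  simulate(model, nsim = n_samples, seed = seed, newdata = data)
}

# ---- Monte Carlo testing ----------------------------------------------------

#' Monte Carlo p-value with add-one correction
#'
#' Rank-based p-value of an observed statistic in a null sample:
#' `p = (1 + #{null at least as extreme}) / (1 + n)`. Two-sided p-values
#' double the smaller tail and are capped at 1. With 9,999 null samples the
#' attainable one-sided floor is 1e-4.
#'
#' @param observed observed statistic.
#' @param null_stats numeric vector of null statistics (>= 999 values).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return p-value.
#' @export
mc_pvalue <- function(observed, null_stats,
                      alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- length(null_stats)
  if (n < 999) stop("need at least 999 null samples, got ", n)
  p_hi <- (1 + sum(null_stats >= observed)) / (1 + n)
  p_lo <- (1 + sum(null_stats <= observed)) / (1 + n)
  switch(alternative,
         greater = min(1, p_hi),
         less = min(1, p_lo),
         two.sided = min(1, 2 * min(p_hi, p_lo)))
}

#' Bonferroni correction
#'
#' `min(1, m * p)` per test; `m` may exceed the number of p-values supplied
#' when the family of hypotheses is larger than the set reported.
#'
#' @param p numeric vector of raw p-values.
#' @param m number of hypotheses in the family (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) stop("m must be at least the number of tests")
  pmin(1, m * p)
}

# census counts per sample, vectorised over Monte Carlo wirings
.sim_census_counts <- function(idx, sims, edge_type) {
  directed <- edge_type == "chemical"
  tab <- .motif_tables(directed)
  n_class <- nrow(tab$classes)
  nsim <- nrow(sims$electrical)
  counts <- matrix(0L, nsim, n_class)
  for (s in seq_len(nsim)) {
    codes <- .triplet_codes(idx, sims$electrical[s, ], sims$chem_ab[s, ],
                            sims$chem_ba[s, ])
    code <- if (directed) codes$ccode else codes$ecode
    counts[s, ] <- tabulate(tab$class_of_code[code + 1], n_class)
  }
  counts
}

#' Motif over/underrepresentation against a null model
#'
#' Compares the observed triad census with the census expected under a
#' fitted random connectivity model: the model is sampled `n_samples` times
#' on the recorded geometry, each sample is decomposed into triplets
#' identically to the data, and per-class ratios (observed/predicted mean
#' frequency) and Monte Carlo p-values on the class counts are reported,
#' together with Bonferroni-adjusted p-values and, for directed censuses,
#' the grouped transitive/intransitive test.
#'
#' @param data an [mli_data] object.
#' @param model a fitted [fit_null_model()] object.
#' @param edge_type `"electrical"` or `"chemical"`.
#' @param n_samples Monte Carlo wirings (>= 999; default 9999 gives a
#'   one-sided p floor of 1e-4).
#' @param seed optional seed.
#' @param alternative sidedness of the per-class tests (default two-sided).
#' @return List of class `mli_motif_test`: `census` (per-class table with
#'   `observed`, `predicted`, `ratio`, `p`, `p_adj`), `groups` (transitivity
#'   groups, directed only), `n_triplets`, `n_samples`.
#' @export
motif_ratio_test <- function(data, model,
                             edge_type = c("electrical", "chemical"),
                             n_samples = 9999, seed = NULL,
                             alternative = c("two.sided", "greater", "less")) {
  edge_type <- match.arg(edge_type)
  alternative <- match.arg(alternative)
  if (n_samples < 999) stop("need at least 999 Monte Carlo samples")
  triplets <- decompose_triplets(data)
  idx <- attr(triplets, "triplet_index")
  obs <- motif_census(triplets, edge_type)
  sims <- sample_networks(data, model, n_samples, seed = seed)
  counts <- .sim_census_counts(idx, sims, edge_type)
  n_trip <- attr(obs, "n_triplets")
  pred <- colMeans(counts) / n_trip
  ratio <- ifelse(pred > 0, obs$frequency / pred,
                  ifelse(obs$frequency > 0, Inf, NA))
  p <- vapply(seq_len(nrow(obs)), function(k) {
    if (pred[k] == 0 && obs$count[k] > 0) return(1 / (1 + n_samples))
    mc_pvalue(obs$count[k], counts[, k], alternative)
  }, numeric(1))
  census <- data.frame(obs[, c("class_id", "name", "canonical", "n_edges")],
                       observed = obs$count, frequency = obs$frequency,
                       predicted = pred, ratio = ratio, p = p,
                       p_adj = bonferroni(p))
  groups <- NULL
  if (edge_type == "chemical") {
    census$transitivity <- obs$transitivity
    gsum <- function(label, m) rowSums(m[, obs$transitivity == label, drop = FALSE])
    g_obs <- c(transitive = sum(obs$count[obs$transitivity == "transitive"]),
               intransitive = sum(obs$count[obs$transitivity == "intransitive"]))
    g_counts <- cbind(transitive = gsum("transitive", counts),
                      intransitive = gsum("intransitive", counts))
    groups <- data.frame(
      group = names(g_obs), observed = as.integer(g_obs),
      predicted = colMeans(g_counts) / n_trip,
      frequency = as.numeric(g_obs) / n_trip,
      p = c(mc_pvalue(g_obs[1], g_counts[, 1], alternative),
            mc_pvalue(g_obs[2], g_counts[, 2], alternative)))
  }
  structure(list(edge_type = edge_type, census = census, groups = groups,
                 n_triplets = n_trip, n_samples = n_samples,
                 model_kind = model$kind),
            class = "mli_motif_test")
}

#' @export
print.mli_motif_test <- function(x, ...) {
  cat(sprintf("Motif census vs %s model (%s, %d triplets, %d Monte Carlo samples)\n",
              x$model_kind, x$edge_type, x$n_triplets, x$n_samples))
  print(x$census[, setdiff(names(x$census), c("canonical"))],
        row.names = FALSE, digits = 3)
  if (!is.null(x$groups)) {
    cat("Transitivity groups:\n")
    print(x$groups, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
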