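# Molecular-layer position normalization, role-wise position statistics of
# transitive chemical motifs, and z-density width of morphological clouds.

#' Normalize a soma position within the molecular layer
#'
#' Maps the y coordinate of a cell to `[0, 1]` relative to the Purkinje cell
#' layer (0) and pial surface (1). Out-of-range cells (somata slightly
#' beyond either reference) are clamped and flagged via the `clamped`
#' attribute.
#'
#' @param y_cell soma coordinate(s).
#' @param y_pc_layer,y_pia reference coordinates of the Purkinje cell layer
#'   and pial surface (must differ).
#' @return Numeric vector in `[0, 1]` with logical attribute `clamped`.
#' @export
normalize_ml <- function(y_cell, y_pc_layer, y_pia) {
  if (y_pia == y_pc_layer) stop("reference positions must differ")
  pos <- (y_cell - y_pc_layer) / (y_pia - y_pc_layer)
  clamped <- pos < 0 | pos > 1
  pos <- pmin(pmax(pos, 0), 1)
  attr(pos, "clamped") <- clamped
  pos
}

#' Assign origin/intermediate/target roles in a transitive chemical triad
#'
#' For the feedforward motif (A->B, B->C, A->C) the origin is the node with
#' out-degree 2, the target the node with in-degree 2 and the intermediate
#' the remaining node. For the regulating-mutual motif (origin sending
#' diverging connections onto a mutually connected pair) the origin is the
#' common source; the mutual pair is ordered by molecular-layer position
#' (higher cell = intermediate), a package convention.
#'
#' @param triplet one row of [decompose_triplets()] (or a list with
#'   `cell_1..3`, `c_code`, `c_name`).
#' @param data the [mli_data] object the triplets came from (for `ml_pos`
#'   and `z_um`).
#' @return List of class `mli_roles`: `motif`, `origin`, `intermediate`,
#'   `target` (cell ids), `ml_pos` and `z_um` (named by role).
#' @export
assign_roles <- function(triplet, data) {
  name <- as.character(triplet$c_name)
  if (!name %in% c("feedforward", "regulating_mutual"))
    stop("roles are defined only for feedforward and regulating_mutual triads, got ",
         if (is.na(name)) "unnamed class" else name)
  adj <- .adj_from_code(triplet$c_code, .d_slots, directed = TRUE)
  ids <- c(triplet$cell_1, triplet$cell_2, triplet$cell_3)
  outd <- rowSums(adj)
  ind <- colSums(adj)
  ml <- stats::setNames(data$cells$ml_pos, data$cells$cell_id)[ids]
  z <- stats::setNames(data$cells$z_um, data$cells$cell_id)[ids]
  if (name == "feedforward") {
    origin <- which(outd == 2)
    target <- which(ind == 2)
    inter <- setdiff(1:3, c(origin, target))
  } else {
    origin <- which(outd == 2 & ind == 0)
    mutual <- setdiff(1:3, origin)
    # convention: higher cell of the mutual pair is the intermediate
    inter <- mutual[which.max(ml[mutual])]
    target <- setdiff(mutual, inter)
  }
  roles <- c(origin = ids[origin], intermediate = ids[inter],
             target = ids[target])
  structure(list(motif = name, origin = roles[["origin"]],
                 intermediate = roles[["intermediate"]],
                 target = roles[["target"]],
                 ml_pos = stats::setNames(ml[c(origin, inter, target)],
                                          names(roles)),
                 z_um = stats::setNames(z[c(origin, inter, target)],
                                        names(roles))),
            class = "mli_roles")
}

#' Position statistics of roles in transitive chemical motifs
#'
#' Tests the vertical organization of transitive triads in the molecular
#' layer: paired t-tests of origin versus target and intermediate versus
#' target positions, and a one-way ANOVA across the three roles, on the
#' normalized molecular-layer positions. The same tests on the transverse z
#' coordinate serve as a negative control (no directionality is expected
#' along the slice depth).
#'
#' @param data an [mli_data] object.
#' @param triplets optional output of [decompose_triplets()] (computed if
#'   missing); all feedforward and regulating-mutual triplets are used.
#' @return List of class `mli_role_test` with elements `ml` and `z`, each
#'   holding `p_origin_target`, `p_intermediate_target`, `p_anova` and `n`,
#'   plus the per-triplet `positions` table.
#' @export
role_position_tests <- function(data, triplets = NULL) {
  if (is.null(triplets)) triplets <- decompose_triplets(data)
  sel <- triplets$c_name %in% c("feedforward", "regulating_mutual")
  if (sum(sel) < 3) stop("need at least 3 transitive triplets, got ", sum(sel))
  roles <- lapply(which(sel), function(i) assign_roles(triplets[i, ], data))
  ml <- t(vapply(roles, `[[`, numeric(3), "ml_pos"))
  z <- t(vapply(roles, `[[`, numeric(3), "z_um"))
  one_axis <- function(m) {
    keep <- stats::complete.cases(m)
    m <- m[keep, , drop = FALSE]
    n <- nrow(m)
    if (n < 3) return(list(p_origin_target = NA, p_intermediate_target = NA,
                           p_anova = NA, n = n))
    p_ot <- if (stats::sd(m[, 1] - m[, 3]) == 0) 1
            else stats::t.test(m[, 1], m[, 3], paired = TRUE)$p.value
    p_it <- if (stats::sd(m[, 2] - m[, 3]) == 0) 1
            else stats::t.test(m[, 2], m[, 3], paired = TRUE)$p.value
    long <- data.frame(pos = as.vector(m),
                       role = factor(rep(c("origin", "intermediate", "target"),
                                         each = n)))
    p_aov <- summary(stats::aov(pos ~ role, data = long))[[1]][["Pr(>F)"]][1]
    list(p_origin_target = p_ot, p_intermediate_target = p_it,
         p_anova = p_aov, n = n)
  }
  structure(list(ml = one_axis(ml), z = one_axis(z),
                 positions = data.frame(
                   motif = vapply(roles, `[[`, character(1), "motif"),
                   origin_ml = ml[, 1], intermediate_ml = ml[, 2],
                   target_ml = ml[, 3], origin_z = z[, 1],
                   intermediate_z = z[, 2], target_z = z[, 3])),
            class = "mli_role_test")
}

#' @export
print.mli_role_test <- function(x, ...) {
  cat(sprintf("Role positions over %d transitive triplets\n", x$ml$n))
  cat(sprintf("  ML: origin vs target p = %.4g, intermediate vs target p = %.4g, ANOVA p = %.4g\n",
              x$ml$p_origin_target, x$ml$p_intermediate_target, x$ml$p_anova))
  cat(sprintf("  z (control): origin vs target p = %.4g, ANOVA p = %.4g\n",
              x$z$p_origin_target, x$z$p_anova))
  invisible(x)
}

#' Width of a density profile along the transverse axis
#'
#' Fits a Gaussian to the binned, normalized density of point z coordinates
#' by least squares and returns the full width 2-sigma — the measure used to
#' compare the transverse extent of dendritic and axonal clouds (dendrites
#' are narrower, confining electrical coupling near the sagittal plane).
#'
#' @param z_um numeric vector of z coordinates (>= 10 points).
#' @param n_bins histogram bins (default 50).
#' @return List: `two_sigma_um`, `sigma_um`, `center_um`, `fit` (optim
#'   result).
#' @export
density_width <- function(z_um, n_bins = 50) {
  z_um <- z_um[is.finite(z_um)]
  if (length(z_um) < 10) stop("need at least 10 points")
  if (stats::sd(z_um) == 0) stop("degenerate input: zero variance")
  h <- graphics::hist(z_um, breaks = n_bins, plot = FALSE)
  x <- h$mids
  y <- h$density / max(h$density)
  obj <- function(par) {
    amp <- par[1]; mu <- par[2]; sig <- exp(par[3])
    sum((y - amp * exp(-(x - mu)^2 / (2 * sig^2)))^2)
  }
  start <- c(1, mean(z_um), log(stats::sd(z_um)))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  sigma <- exp(fit$par[3])
  list(two_sigma_um = 2 * sigma, sigma_um = sigma, center_um = fit$par[2],
       fit = fit)
}
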