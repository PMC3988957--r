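# Common-neighbor analysis: how the presence and type of a shared connected
# neighbor relates to the connection probability of a pair.

#' Annotate pairs with common-neighbor categories
#'
#' For every pair (A, B) in recording sets of at least 3 cells, examines each
#' third recorded cell N:
#' \describe{
#'   \item{`electrical_cn`}{N-A and N-B are both electrical.}
#'   \item{`chemical_cn_any`}{N has a chemical connection (either direction)
#'     with both A and B.}
#'   \item{`chemical_chain_cn`}{the chemical links through N form a directed
#'     chain X->N->Y with `{X, Y} = {A, B}` (strict direction; a convergent
#'     A->N<-B neighbor does not qualify).}
#'   \item{`mixed_cn`}{N has exactly one electrical link to one member and
#'     one chemical link to the other, and the pair qualifies for neither
#'     pure category (pairs with a common electrical neighbor or a common
#'     chemical neighbor are excluded, isolating the cross-network effect).}
#' }
#'
#' @param data an [mli_data] object.
#' @return data.frame of class `mli_neighbors`: one row per pair in sets of
#'   >= 3 cells, with the pair's connection state and logical category
#'   columns; attribute `neighbors` lists the qualifying neighbor ids.
#' @export
annotate_common_neighbors <- function(data) {
  cells <- data$cells
  pr <- data$pairs
  key <- paste(pr$set_id, pmin(pr$cell_a, pr$cell_b), pmax(pr$cell_a, pr$cell_b))
  prow <- function(sid, a, b) match(paste(sid, min(a, b), max(a, b)), key)
  e_of <- function(i) pr$electrical[i] %in% TRUE
  chem_dir <- function(i, from) {
    if (pr$cell_a[i] == from) pr$chem_ab[i] %in% TRUE else pr$chem_ba[i] %in% TRUE
  }
  chem_any <- function(i) (pr$chem_ab[i] %in% TRUE) || (pr$chem_ba[i] %in% TRUE)

  sets <- split(cells$cell_id, cells$set_id)
  rows <- list()
  nbrs <- list()
  for (sid in names(sets)) {
    ids <- sets[[sid]]
    if (length(ids) < 3) next
    cmb <- utils::combn(ids, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      i_ab <- prow(sid, a, b)
      others <- setdiff(ids, c(a, b))
      cat_n <- list(electrical_cn = character(0), mixed_candidate = character(0),
                    chemical_cn_any = character(0),
                    chemical_chain_cn = character(0))
      for (nn in others) {
        i_na <- prow(sid, nn, a)
        i_nb <- prow(sid, nn, b)
        e_na <- e_of(i_na); e_nb <- e_of(i_nb)
        c_na <- chem_any(i_na); c_nb <- chem_any(i_nb)
        if (e_na && e_nb)
          cat_n$electrical_cn <- c(cat_n$electrical_cn, nn)
        if (c_na && c_nb)
          cat_n$chemical_cn_any <- c(cat_n$chemical_cn_any, nn)
        if ((chem_dir(i_na, a) && chem_dir(i_nb, nn)) ||
            (chem_dir(i_nb, b) && chem_dir(i_na, nn)))
          cat_n$chemical_chain_cn <- c(cat_n$chemical_chain_cn, nn)
        # exactly one electrical link to one member, one chemical to the other
        if ((e_na && !e_nb && c_nb && !c_na) || (e_nb && !e_na && c_na && !c_nb))
          cat_n$mixed_candidate <- c(cat_n$mixed_candidate, nn)
      }
      mixed <- length(cat_n$mixed_candidate) > 0 &&
        length(cat_n$electrical_cn) == 0 && length(cat_n$chemical_cn_any) == 0
      rows[[length(rows) + 1]] <- data.frame(
        set_id = sid, cell_a = a, cell_b = b, pair_row = i_ab,
        electrical = e_of(i_ab), chemical_any = chem_any(i_ab),
        electrical_cn = length(cat_n$electrical_cn) > 0,
        mixed_cn = mixed,
        chemical_cn_any = length(cat_n$chemical_cn_any) > 0,
        chemical_chain_cn = length(cat_n$chemical_chain_cn) > 0,
        stringsAsFactors = FALSE)
      nbrs[[length(nbrs) + 1]] <- cat_n
    }
  }
  if (length(rows) == 0) stop("no recording set with at least 3 cells")
  out <- do.call(rbind, rows)
  attr(out, "neighbors") <- nbrs
  class(out) <- c("mli_neighbors", "data.frame")
  out
}

#' Connection probabilities of pairs with a given common-neighbor type
#'
#' Computes three non-exclusive outcome indicators for the pairs in a
#' category — P(no connection), P(electrical present), P(chemical present,
#' any direction); dual pairs count in both of the latter — and compares
#' them (i) against all other annotated pairs by a 2x2 chi-squared test
#' without continuity correction and (ii) against a fitted random
#' connectivity model by Monte Carlo sampling on the category pairs'
#' geometry.
#'
#' @param data an [mli_data] object.
#' @param annotations output of [annotate_common_neighbors()] (computed if
#'   missing).
#' @param category one of `"electrical_cn"`, `"mixed_cn"`,
#'   `"chemical_cn_any"`, `"chemical_chain_cn"`.
#' @param model optional fitted [fit_null_model()] for the Monte Carlo
#'   comparison.
#' @param n_samples Monte Carlo wirings (default 9999).
#' @param seed optional seed.
#' @return List of class `mli_neighbor_test`: `n_category`, `n_other`,
#'   `probs` (category/other/model outcome probabilities), `chisq_p` and
#'   `mc_p` per outcome.
#' @export
neighbor_probability_test <- function(data, annotations = NULL,
                                      category = c("electrical_cn", "mixed_cn",
                                                   "chemical_cn_any",
                                                   "chemical_chain_cn"),
                                      model = NULL, n_samples = 9999,
                                      seed = NULL) {
  category <- match.arg(category)
  if (is.null(annotations)) annotations <- annotate_common_neighbors(data)
  sel <- annotations[[category]]
  if (!any(sel)) stop("no pair in category ", category)
  outcome <- function(e, chem) {
    c(none = mean(!e & !chem), electrical = mean(e), chemical = mean(chem))
  }
  p_cat <- outcome(annotations$electrical[sel], annotations$chemical_any[sel])
  p_other <- if (any(!sel))
    outcome(annotations$electrical[!sel], annotations$chemical_any[!sel])
  else c(none = NA, electrical = NA, chemical = NA)

  chisq_p <- rep(NA_real_, 3)
  names(chisq_p) <- names(p_cat)
  if (any(!sel)) {
    ind <- cbind(none = !annotations$electrical & !annotations$chemical_any,
                 electrical = annotations$electrical,
                 chemical = annotations$chemical_any)
    for (k in 1:3) {
      tab <- table(factor(sel, levels = c(TRUE, FALSE)),
                   factor(ind[, k], levels = c(TRUE, FALSE)))
      chisq_p[k] <- suppressWarnings(
        stats::chisq.test(tab, correct = FALSE)$p.value)
    }
  }

  mc_p <- NULL
  p_model <- NULL
  if (!is.null(model)) {
    rows <- annotations$pair_row[sel]
    sims <- sample_networks(data, model, n_samples, seed = seed)
    e <- sims$electrical[, rows, drop = FALSE]
    chem <- sims$chem_ab[, rows, drop = FALSE] | sims$chem_ba[, rows, drop = FALSE]
    null_stats <- cbind(none = rowMeans(!e & !chem),
                        electrical = rowMeans(e), chemical = rowMeans(chem))
    p_model <- colMeans(null_stats)
    mc_p <- vapply(1:3, function(k) mc_pvalue(p_cat[k], null_stats[, k]),
                   numeric(1))
    names(mc_p) <- names(p_cat)
  }
  structure(list(category = category, n_category = sum(sel),
                 n_other = sum(!sel),
                 probs = rbind(category = p_cat, other = p_other,
                               model = if (is.null(p_model)) c(NA, NA, NA)
                                       else p_model),
                 chisq_p = chisq_p, mc_p = mc_p),
            class = "mli_neighbor_test")
}

#' @export
print.mli_neighbor_test <- function(x, ...) {
  cat(sprintf("Common-neighbor analysis, category %s (n = %d vs %d other pairs)\n",
              x$category, x$n_category, x$n_other))
  print(round(x$probs, 4))
  cat("chi-squared p (vs other pairs):",
      paste(sprintf("%s = %.3g", names(x$chisq_p), x$chisq_p), collapse = ", "),
      "\n")
  if (!is.null(x$mc_p))
    cat("Monte Carlo p (vs model):",
        paste(sprintf("%s = %.3g", names(x$mc_p), x$mc_p), collapse = ", "),
        "\n")
  invisible(x)
}
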