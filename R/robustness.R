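#' Perturbation robustness scan of the stage energy trend
#'
#' Tests how stable the stage ordering of mean Hopfield energies is when the
#' network is rebuilt from perturbed inputs. Two protocols are provided:
#' `"gene-subset"` rebuilds the network from a seeded random subset of
#' `round(f * M)` of the selected HVGs; `"expression-permutation"` permutes a
#' seeded random f-fraction of genes' expression values across cells before
#' the whole pipeline is re-run. Within each (fraction, seed) run, per-stage
#' mean energies are standardized (z-scored across stages) so runs with
#' different gene counts share one scale, and `rank_preserved` records
#' whether the stage ordering by mean energy matches the unperturbed
#' pipeline.
#'
#' @param x An [expression_matrix()] with stage labels.
#' @param hvg_fraction HVG fraction for the baseline pipeline (default 0.1).
#' @param fractions Perturbation fractions in (0, 1] (default
#'   `c(0.1, 0.2, 0.4, 0.6, 0.8, 0.9)`).
#' @param mode `"gene-subset"` (default) or `"expression-permutation"`.
#' @param n_seeds Number of perturbation replicates per fraction (default 20).
#' @param seed Base seed; replicate r of fraction f uses a seed derived
#'   deterministically from it.
#' @param grouping,convention Passed to [energy_profile()].
#' @return An object of class `RobustnessScan`: data.frame with columns
#'   `mode`, `fraction`, `seed`, `stage`, `energy_mean`, `energy_std`
#'   (standardized), `rank_preserved`; the unperturbed per-stage means are
#'   attached as `attr(, "baseline")`.
#' @export
robustness_scan <- function(x, hvg_fraction = 0.1,
                            fractions = c(0.1, 0.2, 0.4, 0.6, 0.8, 0.9),
                            mode = c("gene-subset", "expression-permutation"),
                            n_seeds = 20L, seed = 1L,
                            grouping = "self", convention = "zero-one") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  mode <- match.arg(mode)
  if (is.null(x$stage_labels)) {
    stop("robustness_scan requires stage labels", call. = FALSE)
  }
  if (!all(vapply(fractions, is_fraction, logical(1L)))) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  stages <- unique(x$stage_labels)

  run_pipeline <- function(xx) {
    z <- zscore_genes(xx)
    hv <- select_hvgs(xx, hvg_fraction)
    b <- binarize(z, hv)
    list(b = b, prof = energy_profile(b, grouping, convention))
  }
  stage_means <- function(prof) {
    vapply(stages, function(s) mean(prof$energy[prof$stage == s]), numeric(1L))
  }

  base <- run_pipeline(x)
  base_means <- stage_means(base$prof)
  base_order <- order(base_means)
  m <- ncol(base$b$states)

  rows <- list()
  for (f in fractions) {
    for (r in seq_len(n_seeds)) {
      run_seed <- seed + 1000L * match(f, fractions) + r
      if (f < 1) {
        if (mode == "gene-subset") {
          n_keep <- round(f * m)
          if (n_keep < 2L) stop("empty gene subset: fraction too small",
                                call. = FALSE)
          keep <- with_seed(run_seed, sample.int(m, n_keep))
          sub <- binary_state_matrix(base$b$states[, sort(keep), drop = FALSE],
                                     stage_labels = base$b$stage_labels)
          prof <- energy_profile(sub, grouping, convention)
        } else {
          n_perm <- round(f * nrow(x$values))
          if (n_perm < 1L) stop("empty permutation set: fraction too small",
                                call. = FALSE)
          vals <- x$values
          with_seed(run_seed, {
            sel <- sample.int(nrow(vals), n_perm)
            for (g in sel) vals[g, ] <- vals[g, sample.int(ncol(vals))]
          })
          xp <- expression_matrix(vals, x$gene_ids, x$cell_ids,
                                  x$stage_labels)
          prof <- run_pipeline(xp)$prof
        }
      } else {
        prof <- base$prof   # fraction 1.0 is the identity perturbation
      }
      means <- stage_means(prof)
      std <- if (stats::sd(means) > 0) {
        (means - mean(means)) / stats::sd(means)
      } else {
        rep(0, length(means))
      }
      rank_ok <- identical(order(means), base_order)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, fraction = f, seed = run_seed, stage = stages,
        energy_mean = unname(means), energy_std = unname(std),
        rank_preserved = rank_ok, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline") <- base_means
  class(out) <- c("RobustnessScan", "data.frame")
  out
}

#' PC1-energy landscape fit
#'
#' Runs centred PCA on the z-scored HVG matrix (cells as observations),
#' orients PC1 to correlate positively with the stage index when stage
#' labels are available (PCA signs are otherwise arbitrary), and fits the
#' relation between PC1 and per-cell Hopfield energy: Pearson correlation
#' plus a least-squares polynomial fit of energy on PC1, the quantitative
#' backbone of the Waddington landscape figure.
#'
#' @param z A [zscore_genes()] result (or a plain cells x genes matrix).
#' @param hvgs HVG selection restricting `z`; ignored when `z` is already a
#'   cells x genes matrix.
#' @param energies An [energy_profile()] or a numeric vector aligned to the
#'   cells.
#' @param degree Polynomial degree of the fitted landscape curve (default 3).
#' @return An object of class `LandscapeFit`: list with `coordinates`
#'   (data.frame `cell_id`, `PC1`, `PC2`, `energy`, `stage`), `pearson_R`,
#'   `undefined_correlation`, `degree`, `coefficients` (intercept first),
#'   `fit` (the `lm` object).
#' @export
landscape_fit <- function(z, hvgs = NULL, energies, degree = 3L) {
  if (inherits(z, "ZScoredMatrix")) {
    ids <- if (inherits(hvgs, "HVGSelection")) hvgs$selected_gene_ids
           else if (!is.null(hvgs)) as.character(hvgs) else z$gene_ids
    mat <- t(z$values[match(ids, z$gene_ids), , drop = FALSE])
    cell_ids <- z$cell_ids
    stage <- z$stage_labels
  } else {
    mat <- as.matrix(z)
    cell_ids <- rownames(mat)
    if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(mat)))
    stage <- NULL
  }
  if (nrow(mat) < 3L) stop("landscape_fit needs at least 3 cells",
                           call. = FALSE)
  e <- if (inherits(energies, "EnergyProfile") || is.data.frame(energies)) {
    energies$energy[match(cell_ids, energies$cell_id)]
  } else {
    as.numeric(energies)
  }
  if (length(e) != nrow(mat) || anyNA(e)) {
    stop("energies must align one-to-one with the cells", call. = FALSE)
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  pc1 <- pc$x[, 1L]
  pc2 <- if (ncol(pc$x) >= 2L) pc$x[, 2L] else rep(0, nrow(mat))
  if (!is.null(stage)) {
    stage_idx <- match(stage, unique(stage))
    if (stats::sd(stage_idx) > 0 && stats::cor(pc1, stage_idx) < 0) {
      pc1 <- -pc1
    }
  }
  undefined <- stats::sd(e) == 0 || stats::sd(pc1) == 0
  r <- if (undefined) NA_real_ else stats::cor(pc1, e)
  fit <- stats::lm(e ~ stats::poly(pc1, degree, raw = TRUE))
  structure(
    list(coordinates = data.frame(
           cell_id = cell_ids, PC1 = unname(pc1), PC2 = unname(pc2),
           energy = e,
           stage = if (is.null(stage)) NA_character_ else stage,
           stringsAsFactors = FALSE),
         pearson_R = r, undefined_correlation = undefined,
         degree = degree, coefficients = unname(stats::coef(fit)),
         fit = fit),
    class = "LandscapeFit"
  )
}

#' @export
print.LandscapeFit <- function(x, ...) {
  cat(sprintf("LandscapeFit: %d cells, degree-%d fit, Pearson R = %s\n",
              nrow(x$coordinates), x$degree,
              if (x$undefined_correlation) "undefined"
              else sprintf("%.3f", x$pearson_R)))
  invisible(x)
}
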