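#' Resolved run configuration
#'
#' Collects the tunable parameters of the end-to-end workflows. Defaults
#' match the module-level defaults; every pipeline writes the resolved
#' configuration to `config.json` in its output directory so runs are
#' self-documenting.
#'
#' @param hvg_fraction HVG fraction (0.05 typical for bulk, 0.10 for
#'   single-cell; default 0.10).
#' @param convention Energy/state convention, `"zero-one"` or `"spin"`.
#' @param grouping Attractor grouping, `"self"` or `"phenotype"`.
#' @param steps,repeats Ladder mixing steps and node assignments per step.
#' @param fractions,mode,n_seeds Robustness-scan parameters.
#' @param degree Landscape polynomial degree.
#' @param seed Global seed.
#' @return A `RunConfig` list.
#' @export
hop_config <- function(hvg_fraction = 0.10,
                       convention = c("zero-one", "spin"),
                       grouping = c("self", "phenotype"),
                       steps = 100L, repeats = 20L,
                       fractions = c(0.1, 0.2, 0.4, 0.6, 0.8, 0.9),
                       mode = c("gene-subset", "expression-permutation"),
                       n_seeds = 20L, degree = 3L, seed = 1L) {
  structure(
    list(hvg_fraction = hvg_fraction, convention = match.arg(convention),
         grouping = match.arg(grouping), steps = as.integer(steps),
         repeats = as.integer(repeats), fractions = fractions,
         mode = match.arg(mode), n_seeds = as.integer(n_seeds),
         degree = as.integer(degree), seed = as.integer(seed)),
    class = "RunConfig"
  )
}

echo_config <- function(config, outdir, extra = list()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(c(unclass(config), extra),
                       file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
}

log_msg <- function(...) message("[hopscape] ", sprintf(...))

resolve_input <- function(expression, metadata = NULL) {
  if (inherits(expression, "ExpressionMatrix")) return(expression)
  read_expression(expression, metadata = metadata)
}

#' Per-gene majority-vote archetype of a stage
#'
#' Collapses a stage's binarized cells to one representative network state:
#' each gene takes the majority state across the stage's cells, with ties
#' resolved to 1 (the up-state, consistent with the `sgn(0) = 1`
#' convention).
#'
#' @param b A [binarize()] result with stage labels.
#' @param stage Stage label.
#' @return Named \{0,1\} vector.
#' @export
stage_archetype <- function(b, stage) {
  stopifnot(inherits(b, "BinaryStateMatrix"))
  if (is.null(b$stage_labels)) stop("stage labels required", call. = FALSE)
  idx <- which(b$stage_labels == stage)
  if (!length(idx)) stop("unknown stage label: ", stage, call. = FALSE)
  frac <- colMeans(b$states[idx, , drop = FALSE])
  stats::setNames(ifelse(frac >= 0.5, 1, 0), b$gene_ids)
}

#' Energy workflow: preprocess, score, fit the landscape
#'
#' Reads an expression matrix, z-scores it, selects HVGs, binarizes, scores
#' every cell's Hopfield energy and fits the PC1-energy landscape. Writes
#' `energy.csv`, `landscape.csv`, `fit.json` and `config.json` to `outdir`.
#'
#' @param expression Path to an expression file (or an `ExpressionMatrix`).
#' @param metadata Optional metadata TSV path.
#' @param outdir Output directory.
#' @param config A [hop_config()].
#' @return Invisibly, a list with `profile` ([energy_profile()]), `fit`
#'   ([landscape_fit()]), `hvgs`, `binary`.
#' @export
run_energy_pipeline <- function(expression, metadata = NULL,
                                outdir = "hopscape_out",
                                config = hop_config()) {
  x <- resolve_input(expression, metadata)
  if (config$grouping == "phenotype" && is.null(x$stage_labels)) {
    stop("phenotype grouping requires a metadata file with stage labels",
         call. = FALSE)
  }
  z <- zscore_genes(x)
  hv <- select_hvgs(x, config$hvg_fraction)
  b <- binarize(z, hv)
  log_msg("selected %d HVGs (fraction %.3g), convention %s, grouping %s",
          length(hv$selected_gene_ids), config$hvg_fraction,
          config$convention, config$grouping)
  prof <- energy_profile(b, config$grouping, config$convention)
  fit <- landscape_fit(z, hv, prof, degree = config$degree)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(prof, file.path(outdir, "energy.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fit$coordinates, file.path(outdir, "landscape.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(R = fit$pearson_R, undefined = fit$undefined_correlation,
         degree = fit$degree, coefficients = fit$coefficients),
    file.path(outdir, "fit.json"), auto_unbox = TRUE, digits = NA)
  echo_config(config, outdir, list(command = "energy",
                                   n_hvgs = length(hv$selected_gene_ids)))
  invisible(list(profile = prof, fit = fit, hvgs = hv, binary = b))
}

#' Transition workflow: ladder and driver genes between two stages
#'
#' Forms majority-vote archetype states for the two stages, builds the
#' mixing-ladder energy profile between them, drives the network from A to
#' B and scores driver-gene importance. Writes `ladder.csv`,
#' `importance.csv` and `config.json` to `outdir`.
#'
#' @inheritParams run_energy_pipeline
#' @param stageA,stageB Stage labels present in the metadata.
#' @return Invisibly, list with `ladder`, `importance`, `transition`,
#'   `stateA`, `stateB`.
#' @export
run_ladder_pipeline <- function(expression, metadata = NULL, stageA, stageB,
                                outdir = "hopscape_out",
                                config = hop_config()) {
  x <- resolve_input(expression, metadata)
  if (is.null(x$stage_labels)) {
    stop("the ladder workflow requires stage labels", call. = FALSE)
  }
  for (s in c(stageA, stageB)) {
    if (!s %in% x$stage_labels) stop("unknown stage label: ", s,
                                     call. = FALSE)
  }
  z <- zscore_genes(x)
  hv <- select_hvgs(x, config$hvg_fraction)
  b <- binarize(z, hv)
  a_state <- stage_archetype(b, stageA)
  b_state <- stage_archetype(b, stageB)
  log_msg("archetypes: %s (%d active) -> %s (%d active)",
          stageA, sum(a_state), stageB, sum(b_state))
  ladder <- build_ladder(a_state, b_state, steps = config$steps,
                         repeats = config$repeats, seed = config$seed,
                         convention = config$convention)
  trans <- drive_transition(a_state, b_state, order_seed = config$seed)
  imp <- importance_scores(trans)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(ladder, file.path(outdir, "ladder.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(imp, file.path(outdir, "importance.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  echo_config(config, outdir,
              list(command = "ladder", stageA = stageA, stageB = stageB))
  invisible(list(ladder = ladder, importance = imp, transition = trans,
                 stateA = a_state, stateB = b_state))
}

#' Robustness workflow
#'
#' Thin wrapper over [robustness_scan()]; writes `scan.csv` and
#' `config.json` to `outdir`.
#'
#' @inheritParams run_energy_pipeline
#' @return Invisibly, the `RobustnessScan`.
#' @export
run_perturb_pipeline <- function(expression, metadata = NULL,
                                 outdir = "hopscape_out",
                                 config = hop_config()) {
  x <- resolve_input(expression, metadata)
  scan <- robustness_scan(x, hvg_fraction = config$hvg_fraction,
                          fractions = config$fractions, mode = config$mode,
                          n_seeds = config$n_seeds, seed = config$seed,
                          grouping = config$grouping,
                          convention = config$convention)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(scan, file.path(outdir, "scan.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  echo_config(config, outdir, list(command = "perturb"))
  invisible(scan)
}

#' Simulation workflow
#'
#' Generates stage-structured synthetic data and writes the dense TSV +
#' metadata TSV dialects the other workflows consume, plus a JSON echo of
#' the generating spec.
#'
#' @param spec A [synthetic_spec()] or path to a spec JSON.
#' @param outdir Output directory.
#' @return Invisibly, the generated `ExpressionMatrix`.
#' @export
run_simulate <- function(spec = synthetic_spec(), outdir = "hopscape_out") {
  if (is.character(spec)) spec <- read_spec(spec)
  stopifnot(inherits(spec, "SyntheticSpec"))
  x <- generate_stage_data(spec)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_expression(x, file.path(outdir, "expression.tsv"),
                   file.path(outdir, "metadata.tsv"))
  write_spec(spec, file.path(outdir, "spec.json"))
  log_msg("simulated %d genes x %d cells (seed %d) -> %s",
          nrow(x$values), ncol(x$values), spec$seed, outdir)
  invisible(x)
}
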