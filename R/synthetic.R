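#' Specification for stage-structured synthetic expression data
#'
#' Describes a gene pool partitioned into per-stage activation modules plus
#' constant background. A cell at stage t expresses modules 1..t (direction
#' `"differentiation"`) or modules 1..(n_stages - t + 1) (direction
#' `"reprogramming"`, where potency — and hence Hopfield energy — rises
#' toward the final stage) at `active_level`, all other genes at
#' `base_level`, with multiplicative lognormal noise. This emulates the core
#' structure the energy model consumes: a progressively changing set of
#' above-mean highly variable genes along a staged process.
#'
#' @param n_stages Number of stages (default 5).
#' @param cells_per_stage Cells per stage (default 40).
#' @param n_genes Total gene pool before HVG selection (default 2000).
#' @param module_size Genes activated per stage step (default 40).
#' @param base_level Baseline expression mean (default 1.0).
#' @param active_level Active expression mean (default 10.0); must exceed
#'   `base_level`.
#' @param noise_sd Lognormal noise scale `sdlog` (default 0.3); 0 gives
#'   noiseless data.
#' @param direction `"differentiation"` or `"reprogramming"`.
#' @param dropout Bernoulli zeroing probability (default 0, off).
#' @param seed RNG seed (default 1).
#' @return An object of class `SyntheticSpec` (a validated list).
#' @export
synthetic_spec <- function(n_stages = 5L, cells_per_stage = 40L,
                           n_genes = 2000L, module_size = 40L,
                           base_level = 1.0, active_level = 10.0,
                           noise_sd = 0.3,
                           direction = c("differentiation", "reprogramming"),
                           dropout = 0, seed = 1L) {
  direction <- match.arg(direction)
  spec <- structure(
    list(n_stages = as.integer(n_stages),
         cells_per_stage = as.integer(cells_per_stage),
         n_genes = as.integer(n_genes), module_size = as.integer(module_size),
         base_level = as.numeric(base_level),
         active_level = as.numeric(active_level),
         noise_sd = as.numeric(noise_sd), direction = direction,
         dropout = as.numeric(dropout),
         seed = as.integer(seed)),
    class = "SyntheticSpec"
  )
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  with(spec, {
    if (!is_count(n_stages) || !is_count(cells_per_stage) ||
        !is_count(n_genes) || !is_count(module_size)) {
      stop("all counts in the spec must be positive integers", call. = FALSE)
    }
    if (!(active_level > base_level) || base_level < 0) {
      stop("need active_level > base_level >= 0", call. = FALSE)
    }
    if (module_size * n_stages > n_genes) {
      stop("module_size * n_stages must not exceed n_genes", call. = FALSE)
    }
    if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
    if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)",
                                          call. = FALSE)
  })
  invisible(spec)
}

# modules active for a cell at stage t (1-based stage index)
active_modules <- function(spec, t) {
  if (spec$direction == "differentiation") seq_len(t)
  else seq_len(spec$n_stages - t + 1L)
}

# gene indices of module j
module_genes <- function(spec, j) {
  ((j - 1L) * spec$module_size + 1L):(j * spec$module_size)
}

synthetic_ids <- function(spec) {
  list(genes = sprintf("G%04d", seq_len(spec$n_genes)),
       cells = sprintf("cell%04d", seq_len(spec$n_stages * spec$cells_per_stage)),
       stages = sprintf("S%d", seq_len(spec$n_stages)))
}

#' Generate a stage-labeled synthetic expression matrix
#'
#' @param spec A [synthetic_spec()].
#' @return An [expression_matrix()] with stage labels `"S1"..` in stage
#'   order; fully reproducible from `spec$seed`.
#' @export
generate_stage_data <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  validate_spec(spec)
  ids <- synthetic_ids(spec)
  n_cells <- spec$n_stages * spec$cells_per_stage
  stage_of_cell <- rep(seq_len(spec$n_stages), each = spec$cells_per_stage)
  mu <- matrix(spec$base_level, spec$n_genes, n_cells)
  for (t in seq_len(spec$n_stages)) {
    g_active <- unlist(lapply(active_modules(spec, t), module_genes,
                              spec = spec))
    mu[g_active, stage_of_cell == t] <- spec$active_level
  }
  vals <- with_seed(spec$seed, {
    v <- if (spec$noise_sd > 0) {
      mu * matrix(stats::rlnorm(length(mu), meanlog = 0,
                                sdlog = spec$noise_sd),
                  nrow(mu), ncol(mu))
    } else {
      mu
    }
    if (spec$dropout > 0) {
      v[matrix(stats::runif(length(v)) < spec$dropout, nrow(v), ncol(v))] <- 0
    }
    v
  })
  expression_matrix(vals, gene_ids = ids$genes, cell_ids = ids$cells,
                    stage_labels = ids$stages[stage_of_cell])
}

#' Noiseless archetype states and ground-truth drivers for a stage pair
#'
#' Returns the binary archetype state of each stage (1 for genes in active
#' modules, 0 elsewhere, over the full gene pool) and the genes whose states
#' differ — the planted drivers a transition analysis should recover.
#'
#' @param spec A [synthetic_spec()].
#' @param stageA,stageB Stage indices in `1..n_stages`.
#' @return List with `stateA`, `stateB` (named \{0,1\} vectors) and
#'   `driver_genes` (character, the symmetric difference of active sets).
#' @export
generate_transition_pair <- function(spec, stageA, stageB) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  validate_spec(spec)
  for (s in c(stageA, stageB)) {
    if (!is_count(s) || s > spec$n_stages) {
      stop("stage indices must lie in 1..n_stages", call. = FALSE)
    }
  }
  ids <- synthetic_ids(spec)
  archetype <- function(t) {
    st <- stats::setNames(numeric(spec$n_genes), ids$genes)
    st[unlist(lapply(active_modules(spec, t), module_genes, spec = spec))] <- 1
    st
  }
  a <- archetype(stageA)
  b <- archetype(stageB)
  list(stateA = a, stateB = b, driver_genes = ids$genes[a != b])
}

#' Serialize / deserialize a SyntheticSpec as JSON
#'
#' @param spec A [synthetic_spec()].
#' @param path Output (or input) JSON file.
#' @return `write_spec` returns `path` invisibly; `read_spec` a
#'   `SyntheticSpec`.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(synthetic_spec, vals)
}
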