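#' Encode binary \{0,1\} states in a weight convention
#'
#' `"zero-one"` keeps states as 0/1 (the literal gene-state encoding, which
#' reproduces the energy magnitudes reported for attractor scoring);
#' `"spin"` maps them to -1/+1 (the classic Hopfield encoding, required for
#' non-degenerate update dynamics).
#'
#' @param g Vector or matrix over \{0, 1\}.
#' @param convention `"zero-one"` or `"spin"`.
#' @return Encoded states.
#' @export
encode_states <- function(g, convention = c("zero-one", "spin")) {
  convention <- match.arg(convention)
  if (!all(g %in% c(0, 1))) stop("states must be 0 or 1", call. = FALSE)
  if (convention == "spin") 2 * g - 1 else g + 0
}

check_state_convention <- function(state, convention) {
  ok <- if (convention == "spin") all(state %in% c(-1, 1))
        else all(state %in% c(0, 1))
  if (!ok) {
    stop(sprintf("state values do not match the `%s` convention", convention),
         call. = FALSE)
  }
}

# down-state value of a convention (sgn(0) maps to the up-state, 1)
down_state <- function(convention) if (convention == "spin") -1 else 0

#' Build a symmetric Hebbian weight matrix from attractor patterns
#'
#' Stores one or more binary cell states as attractors via the Hebbian sum
#' `w_ij = sum_mu s_i^mu s_j^mu` for `i != j`, with zero diagonal. States are
#' encoded per `convention` before the sum.
#'
#' @param patterns A `BinaryStateMatrix`, a cells x genes \{0,1\} matrix, or a
#'   single \{0,1\} vector; each row is one attractor pattern.
#' @param convention `"zero-one"` (default; paper-literal scoring) or
#'   `"spin"` (recall dynamics).
#' @return An object of class `WeightMatrix`: list with `weights` (M x M),
#'   `p` (number of patterns), `symmetric = TRUE`, `convention`, `gene_ids`.
#' @export
build_weights <- function(patterns, convention = c("zero-one", "spin")) {
  convention <- match.arg(convention)
  pat <- as_pattern_matrix(patterns)
  if (nrow(pat) < 1L) stop("need at least one attractor pattern", call. = FALSE)
  s <- encode_states(pat, convention)
  w <- crossprod(s)            # t(s) %*% s: w_ij = sum_mu s_i s_j
  diag(w) <- 0
  structure(
    list(weights = w, p = nrow(pat), symmetric = TRUE,
         convention = convention, gene_ids = colnames(pat)),
    class = "WeightMatrix"
  )
}

as_pattern_matrix <- function(patterns) {
  if (inherits(patterns, "BinaryStateMatrix")) return(patterns$states)
  if (is.vector(patterns)) patterns <- matrix(patterns, nrow = 1L)
  pat <- as.matrix(patterns)
  if (!all(pat %in% c(0, 1))) stop("patterns must be 0/1", call. = FALSE)
  if (is.null(colnames(pat))) colnames(pat) <- paste0("g", seq_len(ncol(pat)))
  pat
}

#' Hopfield energy of a state
#'
#' `E = -1/2 * sum_{i != j} w_ij s_i s_j`, the quadratic form of the
#' zero-diagonal weight matrix at the given state. Lower (more negative)
#' energy corresponds to deeper attractors; in the potency interpretation,
#' higher energy means higher differentiation potency.
#'
#' @param state State vector in the weight matrix's convention (\{0,1\} for
#'   zero-one, \{-1,1\} for spin).
#' @param w A [build_weights()] result (or an `AsymmetricCoupling`).
#' @return Scalar energy.
#' @export
hopfield_energy <- function(state, w) {
  stopifnot(inherits(w, c("WeightMatrix", "AsymmetricCoupling")))
  if (length(state) != nrow(w$weights)) {
    stop("state length does not match weight matrix dimension", call. = FALSE)
  }
  check_state_convention(state, w$convention)
  # diagonal is identically zero, so the full quadratic form equals the
  # i != j sum
  -0.5 * drop(crossprod(state, w$weights %*% state))
}

#' Per-cell Hopfield energy profile
#'
#' Scores every cell's binary state against an attractor network. With
#' `grouping = "self"` each cell is its own single stored attractor (p = 1,
#' the single-cell protocol); with `grouping = "phenotype"` the weight matrix
#' for a cell is built from all cells sharing its stage label (p = group
#' size, the bulk protocol) and the cell is scored at its own state.
#'
#' @param b A [binarize()] result.
#' @param grouping `"self"` or `"phenotype"`.
#' @param convention Weight/state encoding; `"zero-one"` is the default
#'   scoring convention.
#' @param normalize Divide weights by p within each phenotype group so group
#'   size does not inflate energy magnitude. Default `FALSE`.
#' @return An object of class `EnergyProfile`: data.frame with columns
#'   `cell_id`, `stage`, `k_active`, `energy`, `grouping`, `convention`.
#' @export
energy_profile <- function(b, grouping = c("self", "phenotype"),
                           convention = c("zero-one", "spin"),
                           normalize = FALSE) {
  stopifnot(inherits(b, "BinaryStateMatrix"))
  grouping <- match.arg(grouping)
  convention <- match.arg(convention)
  n <- nrow(b$states)
  energy <- numeric(n)
  if (grouping == "self") {
    for (i in seq_len(n)) {
      w <- build_weights(b$states[i, ], convention)
      s <- encode_states(b$states[i, ], convention)
      energy[i] <- hopfield_energy(s, w)
    }
  } else {
    if (is.null(b$stage_labels)) {
      stop("phenotype grouping requires stage labels", call. = FALSE)
    }
    for (lab in unique(b$stage_labels)) {
      idx <- which(b$stage_labels == lab)
      w <- build_weights(b$states[idx, , drop = FALSE], convention)
      if (normalize) w$weights <- w$weights / w$p
      for (i in idx) {
        s <- encode_states(b$states[i, ], convention)
        energy[i] <- hopfield_energy(s, w)
      }
    }
  }
  out <- data.frame(
    cell_id = b$cell_ids,
    stage = if (is.null(b$stage_labels)) NA_character_ else b$stage_labels,
    k_active = rowSums(b$states),
    energy = energy,
    grouping = grouping,
    convention = convention,
    stringsAsFactors = FALSE
  )
  class(out) <- c("EnergyProfile", "data.frame")
  out
}

#' One sweep of the Hopfield update rule
#'
#' Applies the cell-automaton threshold rule `s_i <- sgn(sum_j w_ij s_j)`
#' with `sgn(0) = +1` (the up-state, matching the `>= 0` binarization
#' branch). Synchronous mode updates all genes from the incoming state at
#' once; asynchronous mode updates genes one at a time in a seeded random
#' order, each update seeing the current state.
#'
#' @param state State vector in `w`'s convention.
#' @param w A `WeightMatrix` or `AsymmetricCoupling`.
#' @param mode `"asynchronous"` (default) or `"synchronous"`.
#' @param order_seed Seed for the asynchronous update order (required in
#'   asynchronous mode).
#' @return List with `state` (updated vector) and `flips`, a data.frame with
#'   one row per changed gene in update order: `gene`, `index`, `from`, `to`,
#'   and for asynchronous updates `energy_after` (energy immediately after
#'   that single flip).
#' @export
update_state <- function(state, w, mode = c("asynchronous", "synchronous"),
                         order_seed = NULL) {
  stopifnot(inherits(w, c("WeightMatrix", "AsymmetricCoupling")))
  mode <- match.arg(mode)
  m <- nrow(w$weights)
  if (length(state) != m) stop("state length mismatch", call. = FALSE)
  check_state_convention(state, w$convention)
  down <- down_state(w$convention)
  genes <- w$gene_ids
  if (mode == "synchronous") {
    h <- drop(w$weights %*% state)
    new <- ifelse(h >= 0, 1, down)
    changed <- which(new != state)
    flips <- data.frame(gene = genes[changed], index = changed,
                        from = state[changed], to = new[changed],
                        stringsAsFactors = FALSE)
    return(list(state = new, flips = flips))
  }
  if (is.null(order_seed)) {
    stop("asynchronous updates require `order_seed`", call. = FALSE)
  }
  ord <- with_seed(order_seed, sample.int(m))
  cur <- state
  e <- hopfield_energy(cur, w)
  rows <- vector("list", m)
  nf <- 0L
  for (i in ord) {
    h <- sum(w$weights[i, ] * cur)   # w_ii = 0, so self term vanishes
    new_i <- if (h >= 0) 1 else down
    if (new_i != cur[i]) {
      # exact incremental energy of a single flip: row and column terms
      # (identical for symmetric weights, where this reduces to -delta * h)
      h_col <- sum(w$weights[, i] * cur)
      e <- e - 0.5 * (new_i - cur[i]) * (h + h_col)
      nf <- nf + 1L
      rows[[nf]] <- data.frame(gene = genes[i], index = i, from = cur[i],
                               to = new_i, energy_after = e,
                               stringsAsFactors = FALSE)
      cur[i] <- new_i
    }
  }
  flips <- if (nf) do.call(rbind, rows[seq_len(nf)]) else
    data.frame(gene = character(), index = integer(), from = numeric(),
               to = numeric(), energy_after = numeric(),
               stringsAsFactors = FALSE)
  list(state = cur, flips = flips)
}

#' Iterate Hopfield updates to a fixed point
#'
#' Repeats [update_state()] sweeps until no gene flips or `max_iters` sweeps
#' have run. Synchronous dynamics can enter a period-2 oscillation; this is
#' detected and reported (`converged = FALSE`, both cycle states returned)
#' rather than treated as an error.
#'
#' @inheritParams update_state
#' @param max_iters Maximum number of sweeps (>= 1).
#' @return List with `state` (final state), `energies` (energy after each
#'   sweep, in `w`'s convention), `converged`, `n_sweeps`, `flips` (row-bound
#'   flip logs with a `sweep` column), and `cycle` (list of the two
#'   oscillating states, synchronous non-convergence only).
#' @export
converge <- function(state, w, mode = c("asynchronous", "synchronous"),
                     max_iters = 100L, order_seed = NULL) {
  mode <- match.arg(mode)
  if (!is_count(max_iters)) stop("max_iters must be >= 1", call. = FALSE)
  cur <- state
  prev2 <- NULL
  energies <- numeric(0)
  logs <- list()
  converged <- FALSE
  cycle <- NULL
  for (it in seq_len(max_iters)) {
    seed_it <- if (is.null(order_seed)) NULL else order_seed + it - 1L
    res <- update_state(cur, w, mode, order_seed = seed_it)
    if (nrow(res$flips)) res$flips$sweep <- it
    logs[[it]] <- res$flips
    energies <- c(energies, hopfield_energy(res$state, w))
    if (!nrow(res$flips)) {
      converged <- TRUE
      cur <- res$state
      break
    }
    if (mode == "synchronous" && !is.null(prev2) &&
        all(res$state == prev2)) {
      cycle <- list(cur, res$state)
      cur <- res$state
      break
    }
    prev2 <- cur
    cur <- res$state
  }
  flips <- if (length(logs)) do.call(rbind, logs) else NULL
  list(state = cur, energies = energies, converged = converged,
       n_sweeps = length(energies), flips = flips, cycle = cycle)
}
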