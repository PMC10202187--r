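#' Build an asymmetric coupling between two cell states
#'
#' For a transition from an old state A to a new state B, the coupling is
#' `w'_ij = sum_mu s_i^{mu,B} s_j^{mu,A}` for `i != j` with zero diagonal:
#' row index i carries the target (B) role and column index j the source (A)
#' role, so the matrix is generally not symmetric.
#'
#' @param statesB Target-state pattern(s): \{0,1\} vector or patterns x genes
#'   matrix (or `BinaryStateMatrix`).
#' @param statesA Source-state pattern(s), same shape as `statesB`.
#' @param convention `"zero-one"` (default, energy scoring) or `"spin"`
#'   (update dynamics).
#' @return An object of class `AsymmetricCoupling`: list with `weights`,
#'   `p`, `convention`, `gene_ids`, `symmetric = FALSE`.
#' @export
build_asym_weights <- function(statesB, statesA,
                               convention = c("zero-one", "spin")) {
  convention <- match.arg(convention)
  pb <- as_pattern_matrix(statesB)
  pa <- as_pattern_matrix(statesA)
  if (!identical(dim(pb), dim(pa))) {
    stop("A and B must have the same number of patterns and genes",
         call. = FALSE)
  }
  sb <- encode_states(pb, convention)
  sa <- encode_states(pa, convention)
  w <- crossprod(sb, sa)        # w_ij = sum_mu sb[mu, i] * sa[mu, j]
  diag(w) <- 0
  structure(
    list(weights = w, p = nrow(pb), symmetric = FALSE,
         convention = convention, gene_ids = colnames(pb)),
    class = "AsymmetricCoupling"
  )
}

#' Energy of a (mixed) state under an asymmetric coupling
#'
#' `E = -1/2 sum_{i != j} w'_ij s_i s_j`, the transition analogue of the
#' symmetric Hopfield energy; the diagonal is excluded, consistent with the
#' zero diagonal of the coupling. For a symmetric coupling this equals
#' [hopfield_energy()].
#'
#' @param state State in the coupling's convention.
#' @param coupling An [build_asym_weights()] result.
#' @return Scalar energy.
#' @export
ladder_energy <- function(state, coupling) {
  stopifnot(inherits(coupling, c("AsymmetricCoupling", "WeightMatrix")))
  hopfield_energy(state, coupling)
}

#' Drive the network from state A toward state B
#'
#' Runs the cell-automaton rule `g_i <- sgn(sum_j w'_ij g_j)` from `stateA`
#' under the asymmetric coupling built from (B, A), recording every gene flip
#' with its sweep index for importance scoring. Dynamics default to the spin
#' encoding, where the rule is non-degenerate.
#'
#' @param stateA,stateB \{0,1\} state vectors of equal length.
#' @param convention Encoding for the dynamics, default `"spin"`.
#' @param mode `"asynchronous"` (default) or `"synchronous"`.
#' @param order_seed Seed for asynchronous update order.
#' @param max_iters Maximum sweeps (>= 1).
#' @return An object of class `HopTransition`: list with `initial`, `final`,
#'   `target` (all \{0,1\}), `reached_target`, `converged`, `flips` (ordered
#'   log with per-flip \{0,1\} values), `coupling`, `gene_ids`.
#' @export
drive_transition <- function(stateA, stateB, convention = c("spin", "zero-one"),
                             mode = c("asynchronous", "synchronous"),
                             order_seed = 1L, max_iters = 100L) {
  convention <- match.arg(convention)
  mode <- match.arg(mode)
  if (length(stateA) != length(stateB)) {
    stop("stateA and stateB must have equal length", call. = FALSE)
  }
  if (!is_count(max_iters)) stop("max_iters must be >= 1", call. = FALSE)
  if (!all(stateA %in% c(0, 1)) || !all(stateB %in% c(0, 1))) {
    stop("states must be 0/1", call. = FALSE)
  }
  a <- as.numeric(stateA)
  b <- as.numeric(stateB)
  genes <- names(stateA)
  if (is.null(genes)) genes <- paste0("g", seq_along(a))
  names(a) <- names(b) <- genes
  coupling <- build_asym_weights(matrix(b, 1, dimnames = list(NULL, genes)),
                                 matrix(a, 1, dimnames = list(NULL, genes)),
                                 convention)
  enc_a <- encode_states(a, convention)
  res <- converge(enc_a, coupling, mode = mode, max_iters = max_iters,
                  order_seed = order_seed)
  to01 <- function(s) if (convention == "spin") (s + 1) / 2 else s
  flips <- res$flips
  if (!is.null(flips) && nrow(flips)) {
    flips$from <- to01(flips$from)
    flips$to <- to01(flips$to)
  } else {
    flips <- data.frame(gene = character(), index = integer(),
                        from = numeric(), to = numeric(), sweep = integer(),
                        stringsAsFactors = FALSE)
  }
  final <- to01(res$state)
  structure(
    list(initial = a, final = final, target = b,
         reached_target = all(final == b), converged = res$converged,
         flips = flips, coupling = coupling, gene_ids = genes,
         convention = convention),
    class = "HopTransition"
  )
}

#' Step-decomposed transition energy ladder
#'
#' Decomposes the A -> B transition into `steps` mixing steps. At step s a
#' seeded random subset of `round(s / steps * M)` gene positions takes its
#' state from B and the rest from A; the energy of each mixed state is
#' computed under the configured coupling policy, and mean and SD over
#' `repeats` random node assignments are recorded. Step 0 is pure A and step
#' `steps` pure B, so the ladder endpoints equal the pure-state energies for
#' every seed.
#'
#' @param stateA,stateB \{0,1\} state vectors of equal length.
#' @param coupling_policy `"self"` (default): both coupling roles are the
#'   step's mixed state, so each step's energy is the self-energy of the
#'   mixed network and the endpoints reduce exactly to the symmetric
#'   attractor energies. `"endpoint"`: target role is the final state B,
#'   source role the mixed state.
#' @param steps Number of mixing steps (default 100).
#' @param repeats Random node assignments averaged per step (default 20).
#' @param seed Seed for the node assignments.
#' @param convention Encoding for energies, default `"zero-one"`.
#' @param exhaustive If `TRUE`, enumerate all `choose(M, n_B)` assignments at
#'   each step instead of sampling (small M only).
#' @return An object of class `TransitionLadder`: data.frame with columns
#'   `step`, `mixing_fraction`, `energy_mean`, `energy_sd`, `repeats`,
#'   `seed`.
#' @export
build_ladder <- function(stateA, stateB, coupling_policy = c("self", "endpoint"),
                         steps = 100L, repeats = 20L, seed = 1L,
                         convention = c("zero-one", "spin"),
                         exhaustive = FALSE) {
  coupling_policy <- match.arg(coupling_policy)
  convention <- match.arg(convention)
  if (length(stateA) != length(stateB)) {
    stop("stateA and stateB must have equal length", call. = FALSE)
  }
  if (!is_count(steps)) stop("steps must be >= 1", call. = FALSE)
  if (!is_count(repeats)) stop("repeats must be >= 1", call. = FALSE)
  a <- as.numeric(stateA)
  b <- as.numeric(stateB)
  m <- length(a)
  genes <- names(stateA)
  if (is.null(genes)) genes <- paste0("g", seq_len(m))

  step_energy <- function(mix) {
    mixed_mat <- matrix(mix, 1, dimnames = list(NULL, genes))
    cp <- if (coupling_policy == "self") {
      build_asym_weights(mixed_mat, mixed_mat, convention)
    } else {
      build_asym_weights(matrix(b, 1, dimnames = list(NULL, genes)),
                         mixed_mat, convention)
    }
    ladder_energy(encode_states(mix, convention), cp)
  }

  rows <- with_seed(seed, {
    lapply(0:steps, function(s) {
      n_b <- round(s / steps * m)
      if (n_b == 0L || n_b == m) {
        # endpoints: the assignment is forced, no sampling variance
        e <- step_energy(if (n_b == 0L) a else b)
        return(data.frame(step = s, mixing_fraction = s / steps,
                          energy_mean = e, energy_sd = 0, repeats = 1L,
                          seed = seed))
      }
      es <- if (exhaustive) {
        combos <- utils::combn(m, n_b, simplify = FALSE)
        vapply(combos, function(idx) {
          mix <- a; mix[idx] <- b[idx]; step_energy(mix)
        }, numeric(1L))
      } else {
        vapply(seq_len(repeats), function(r) {
          idx <- sample.int(m, n_b)
          mix <- a; mix[idx] <- b[idx]
          step_energy(mix)
        }, numeric(1L))
      }
      data.frame(step = s, mixing_fraction = s / steps,
                 energy_mean = mean(es),
                 energy_sd = if (length(es) > 1L) stats::sd(es) else 0,
                 repeats = length(es), seed = seed)
    })
  })
  out <- do.call(rbind, rows)
  class(out) <- c("TransitionLadder", "data.frame")
  out
}

#' Driver-gene importance scores from a transition trajectory
#'
#' For each gene i that flipped during the trajectory, compares the gene's
#' connection pattern immediately before and after its flip with the pattern
#' in the defined stable state. The connection pattern is
#' `a_ij = g_i - g_j` over all partner genes j (values in \{-1, 0, 1\},
#' computed on \{0,1\} gene states); agreement is the simple-matching count
#' of positions where two patterns coincide. Then
#' `IS = (|A^2 agree A^0| - |A^1 agree A^0|) / M`, so genes whose flip moves
#' the network's connections toward the stable state score positively. Genes
#' that never flip score 0; genes with `IS > 0.1` are flagged as retained
#' drivers. For genes that flip more than once the last flip is scored.
#'
#' @param transition A [drive_transition()] result.
#' @param stable_state \{0,1\} reference state defining `A^0`; defaults to the
#'   transition's target state B.
#' @param include_self Count the self position (j = i, always agreeing) in
#'   the agreement totals. Default `FALSE`; the denominator stays M either
#'   way.
#' @return An object of class `ImportanceTable`: data.frame with columns
#'   `gene_id`, `IS`, `retained`, `flip_step` (NA for genes that never
#'   flipped), sorted by decreasing IS.
#' @export
importance_scores <- function(transition, stable_state = NULL,
                              include_self = FALSE) {
  stopifnot(inherits(transition, "HopTransition"))
  genes <- transition$gene_ids
  m <- length(genes)
  stable <- if (is.null(stable_state)) transition$target
            else as.numeric(stable_state)
  if (length(stable) != m || !all(stable %in% c(0, 1))) {
    stop("stable_state must be a 0/1 vector of length M", call. = FALSE)
  }
  flips <- transition$flips
  is_vec <- stats::setNames(numeric(m), genes)
  flip_step <- stats::setNames(rep(NA_integer_, m), genes)

  if (nrow(flips)) {
    bad <- setdiff(flips$gene, genes)
    if (length(bad)) {
      stop("flipped gene missing from trajectory: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    agreement <- function(i, gi, g_state) {
      # a_ij = g_i - g_j vs a0_ij = stable_i - stable_j, counted over j
      ai <- gi - g_state
      a0 <- stable[i] - stable
      agree <- ai == a0
      if (!include_self) agree[i] <- FALSE
      sum(agree)
    }
    # replay the trajectory to recover the state before/after each flip
    cur <- transition$initial
    for (r in seq_len(nrow(flips))) {
      i <- flips$index[r]
      before <- cur
      cur[i] <- flips$to[r]
      # last flip wins for multiply-flipping genes
      n1 <- agreement(i, before[i], before)
      n2 <- agreement(i, cur[i], cur)
      is_vec[i] <- (n2 - n1) / m
      flip_step[i] <- r
    }
  }
  out <- data.frame(gene_id = genes, IS = unname(is_vec),
                    retained = unname(is_vec) > 0.1,
                    flip_step = unname(flip_step),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$IS, out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("ImportanceTable", "data.frame")
  out
}
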