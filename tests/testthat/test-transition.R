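test_that("asymmetric couplings match direct substitution", {
  cp <- build_asym_weights(c(1, 0), c(0, 1))
  # w'_12 = b1 * a2 = 1, w'_21 = b2 * a1 = 0
  expect_equal(unname(cp$weights), matrix(c(0, 0, 1, 0), 2))
  expect_false(identical(cp$weights, t(cp$weights)))

  # A = B reduces to the symmetric Hebbian matrix for p = 1
  pat <- c(1, 1, 0, 1)
  cp2 <- build_asym_weights(pat, pat)
  expect_equal(cp2$weights, build_weights(pat)$weights)

  expect_true(all(build_asym_weights(c(1, 1), c(0, 0))$weights == 0))
  expect_error(build_asym_weights(c(1, 0), c(1, 0, 1)), "same number")
})

test_that("ladder_energy agrees with the symmetric energy and closed form", {
  set.seed(71)
  for (trial in 1:20) {
    m <- sample(3:15, 1)
    s <- random_binary(m)
    cp <- build_asym_weights(s, s)
    expect_identical(ladder_energy(s, cp), closed_form_energy(sum(s)))
    expect_identical(ladder_energy(s, cp),
                     hopfield_energy(s, build_weights(s)))
  }
  expect_identical(ladder_energy(rep(0, 5),
                                 build_asym_weights(rep(1, 5), rep(0, 5))), 0)
})

test_that("drive_transition reaches the target state", {
  a <- c(1, 0, 1)
  tr0 <- drive_transition(a, a, order_seed = 1)
  expect_true(tr0$reached_target)
  expect_equal(nrow(tr0$flips), 0)

  # one differing gene: brute-force over all 8 states confirms B is the
  # unique fixed point reachable from A under the (B, A) coupling
  b <- c(1, 1, 1)
  tr <- drive_transition(a, b, order_seed = 3)
  expect_true(tr$reached_target)
  expect_equal(tr$flips$gene, "g2")
  expect_error(drive_transition(a, b, max_iters = 0), "max_iters")
  expect_error(drive_transition(a, c(1, 0)), "equal length")
})

test_that("ladder endpoints equal pure-state energies for every seed", {
  set.seed(73)
  a <- random_binary(20)
  b <- random_binary(20)
  ea <- closed_form_energy(sum(a))
  eb <- closed_form_energy(sum(b))
  for (seed in c(1, 99, 2024)) {
    lad <- build_ladder(a, b, steps = 10, repeats = 5, seed = seed)
    expect_identical(lad$energy_mean[1], ea)
    expect_identical(lad$energy_mean[11], eb)
    expect_identical(lad$energy_sd[c(1, 11)], c(0, 0))
  }
})

test_that("identical endpoints give a flat zero-sd ladder", {
  a <- c(1, 1, 0, 1, 0, 0)
  lad <- build_ladder(a, a, steps = 8, repeats = 6, seed = 5)
  expect_true(all(lad$energy_mean == closed_form_energy(3)))
  expect_true(all(lad$energy_sd == 0))
  expect_equal(lad$mixing_fraction, (0:8) / 8)
})

test_that("exhaustive ladder means match brute-force enumeration", {
  # oracle: enumerate node assignments directly and average the closed form
  set.seed(79)
  for (m in c(4, 8, 12)) {
    a <- random_binary(m)
    b <- random_binary(m)
    lad <- build_ladder(a, b, steps = 2, repeats = 1, seed = 1,
                        exhaustive = TRUE)
    n_b <- round(m / 2)
    combos <- utils::combn(m, n_b, simplify = FALSE)
    oracle <- mean(vapply(combos, function(idx) {
      mix <- a; mix[idx] <- b[idx]
      closed_form_energy(sum(mix))
    }, numeric(1)))
    expect_equal(lad$energy_mean[2], oracle, tolerance = 1e-12)
    expect_equal(lad$repeats[2], choose(m, n_b))
  }
})

test_that("ladder energy trends monotonically on nested state pairs", {
  spec <- synthetic_spec(n_genes = 50, module_size = 5)
  tp <- generate_transition_pair(spec, 1, 4)
  lad <- build_ladder(tp$stateA, tp$stateB, steps = 20, repeats = 50,
                      seed = 13)
  rho <- stats::cor(lad$step, lad$energy_mean, method = "spearman")
  expect_gte(abs(rho), 0.95)
  expect_lte(lad$energy_mean[21], lad$energy_mean[1])  # B larger: deeper
})

test_that("importance scores reproduce the worked 3-gene case", {
  # stable = (1,1,0); gene 1 flips 0 -> 1 with the other genes at (1, 0):
  # agreements (self excluded) go from 0 to 2, so IS = 2/3
  tr <- structure(
    list(initial = c(0, 1, 0), final = c(1, 1, 0), target = c(1, 1, 0),
         reached_target = TRUE, converged = TRUE,
         flips = data.frame(gene = "g1", index = 1L, from = 0, to = 1,
                            sweep = 1L, stringsAsFactors = FALSE),
         gene_ids = c("g1", "g2", "g3"), convention = "spin"),
    class = "HopTransition")
  imp <- importance_scores(tr, stable_state = c(1, 1, 0))
  expect_equal(imp$IS[imp$gene_id == "g1"], 2 / 3, tolerance = 1e-12)
  expect_true(imp$retained[imp$gene_id == "g1"])
  expect_equal(imp$IS[imp$gene_id != "g1"], c(0, 0))
  expect_false(any(imp$retained[imp$gene_id != "g1"]))
})

test_that("importance scores stay in [-1, 1] and flag only flipped genes", {
  set.seed(83)
  for (trial in 1:10) {
    m <- 30
    a <- random_binary(m)
    b <- a
    idx <- sample.int(m, 4)
    b[idx] <- 1 - b[idx]
    tr <- drive_transition(a, b, order_seed = trial)
    imp <- importance_scores(tr)
    expect_true(all(imp$IS >= -1 & imp$IS <= 1))
    expect_true(all(is.na(imp$flip_step[imp$IS == 0])))
  }
})

test_that("planted drivers occupy the top IS ranks and pass the filter", {
  set.seed(89)
  m <- 50
  d <- 5
  hits <- 0L
  n_inst <- 20
  for (inst in seq_len(n_inst)) {
    a <- random_binary(m)
    names(a) <- sprintf("g%02d", seq_len(m))
    b <- a
    idx <- sample.int(m, d)
    b[idx] <- 1 - b[idx]
    tr <- drive_transition(a, b, order_seed = inst)
    imp <- importance_scores(tr)
    top <- imp$gene_id[seq_len(d)]
    if (setequal(top, names(a)[idx]) && all(imp$IS[seq_len(d)] > 0.1)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_inst, 0.95)
})
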