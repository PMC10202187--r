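test_that("Hebbian weights match hand-computed sums", {
  w1 <- build_weights(c(1, 1, 0))
  expect_equal(unname(w1$weights),
               matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3))
  expect_equal(w1$p, 1)

  w2 <- build_weights(rbind(c(1, 1, 0), c(1, 0, 1)))
  expect_equal(unname(w2$weights),
               matrix(c(0, 1, 1, 1, 0, 0, 1, 0, 0), 3))
  expect_equal(w2$p, 2)

  w0 <- build_weights(c(0, 0, 0))
  expect_true(all(w0$weights == 0))
})

test_that("weights are symmetric with zero diagonal after every build", {
  set.seed(5)
  for (trial in 1:20) {
    pat <- matrix(random_binary(8 * 3), 3)
    w <- build_weights(pat, sample(c("zero-one", "spin"), 1))
    expect_identical(w$weights, t(w$weights))
    expect_true(all(diag(w$weights) == 0))
    expect_true(all(abs(w$weights) <= w$p))
  }
})

test_that("self-attractor zero-one energy equals -k(k-1)/2 closed form", {
  set.seed(17)
  for (trial in 1:100) {
    m <- sample(2:200, 1)
    s <- random_binary(m, stats::runif(1, 0.1, 0.9))
    w <- build_weights(s, "zero-one")
    expect_identical(hopfield_energy(s, w), closed_form_energy(sum(s)))
  }
  # spot values: k = 3 -> -3; M = 10 all ones -> -45
  s3 <- c(1, 1, 1, 0, 0)
  expect_identical(hopfield_energy(s3, build_weights(s3)), -3)
  s10 <- rep(1, 10)
  expect_identical(hopfield_energy(s10, build_weights(s10)), -45)
  expect_identical(hopfield_energy(rep(0, 4), build_weights(s3[1:4])), 0)
})

test_that("vectorized energy matches the naive double-loop oracle", {
  set.seed(23)
  for (trial in 1:50) {
    m <- sample(3:40, 1)
    conv <- sample(c("zero-one", "spin"), 1)
    pat <- matrix(random_binary(m * 3), 3)
    w <- build_weights(pat, conv)
    s <- encode_states(random_binary(m), conv)
    expect_equal(hopfield_energy(s, w), naive_energy(s, w$weights),
                 tolerance = 1e-9)
  }
})

test_that("energy API validates lengths and conventions", {
  w <- build_weights(c(1, 0, 1), "spin")
  expect_error(hopfield_energy(c(1, -1), w), "length")
  expect_error(hopfield_energy(c(1, 0, 1), w), "convention")
  expect_error(build_weights(matrix(numeric(0), 0, 3)), "at least one")
})

test_that("energy_profile groupings agree where they must", {
  states <- rbind(c(1, 1, 0, 1), c(1, 1, 0, 1), c(0, 1, 0, 0))
  rownames(states) <- paste0("c", 1:3)
  b <- binary_state_matrix(states, stage_labels = c("A", "A", "B"))
  prof <- energy_profile(b, "self")
  expect_equal(prof$energy, closed_form_energy(c(3, 3, 1)))
  # identical states -> identical energies
  expect_identical(prof$energy[1], prof$energy[2])
  # a phenotype group of one sample reduces to per-cell-self
  by_ph <- energy_profile(b, "phenotype")
  expect_identical(by_ph$energy[3], prof$energy[3])
  # p = 2 group of identical patterns doubles the weights, normalize undoes it
  expect_identical(by_ph$energy[1], 2 * prof$energy[1])
  norm <- energy_profile(b, "phenotype", normalize = TRUE)
  expect_identical(norm$energy[1], prof$energy[1])
  b_nolab <- binary_state_matrix(states)
  expect_error(energy_profile(b_nolab, "phenotype"), "stage labels")
})

test_that("stored patterns and their complements are fixed points (spin)", {
  set.seed(41)
  for (trial in 1:10) {
    m <- 30
    pat <- random_binary(m)
    w <- build_weights(pat, "spin")
    s <- encode_states(pat, "spin")
    for (mode in c("synchronous", "asynchronous")) {
      res <- update_state(s, w, mode, order_seed = trial)
      expect_equal(res$state, s, ignore_attr = TRUE)
      expect_equal(nrow(res$flips), 0)
      resc <- update_state(-s, w, mode, order_seed = trial)
      expect_equal(resc$state, -s, ignore_attr = TRUE)
    }
  }
})

test_that("zero local field maps to the up-state", {
  # two opposing stored patterns cancel: w12 = 1*1 + 1*(-1) = 0 in spin,
  # so every local field is 0 and sgn(0) must give the up-state
  w <- build_weights(rbind(c(1, 1), c(1, 0)), "spin")
  expect_true(all(w$weights == 0))
  res <- update_state(c(-1, -1), w, "synchronous")
  expect_equal(res$state, c(1, 1), ignore_attr = TRUE)
  res2 <- update_state(c(-1, -1), w, "asynchronous", order_seed = 1)
  expect_equal(unname(res2$state), c(1, 1))
})

test_that("asynchronous spin updates never increase the energy", {
  set.seed(53)
  violations <- 0L
  for (trial in 1:200) {
    m <- 50
    pat <- matrix(random_binary(m * 3), 3)
    w <- build_weights(pat, "spin")
    s <- encode_states(random_binary(m), "spin")
    res <- converge(s, w, "asynchronous", max_iters = 30, order_seed = trial)
    e <- c(hopfield_energy(s, w), res$flips$energy_after)
    if (any(diff(e) > 1e-9)) violations <- violations + 1L
    expect_true(res$converged)
  }
  expect_identical(violations, 0L)
})

test_that("per-flip incremental energies match full recomputation", {
  set.seed(59)
  m <- 20
  w <- build_weights(matrix(random_binary(m * 2), 2), "spin")
  s <- encode_states(random_binary(m), "spin")
  res <- update_state(s, w, "asynchronous", order_seed = 9)
  cur <- s
  for (r in seq_len(nrow(res$flips))) {
    cur[res$flips$index[r]] <- res$flips$to[r]
    expect_equal(res$flips$energy_after[r], hopfield_energy(cur, w),
                 tolerance = 1e-9)
  }
})

test_that("converge stops at stored patterns in one sweep", {
  pat <- c(1, 0, 1, 1, 0)
  w <- build_weights(pat, "spin")
  res <- converge(encode_states(pat, "spin"), w, "synchronous")
  expect_true(res$converged)
  expect_equal(res$n_sweeps, 1)
  expect_length(res$energies, 1)
})

test_that("synchronous dynamics report period-2 oscillations", {
  # antiferromagnetic pair: each spin wants the opposite of its neighbour
  w <- build_weights(c(1, 0), "spin")  # w12 = w21 = -1 in spin encoding
  expect_equal(unname(w$weights), matrix(c(0, -1, -1, 0), 2))
  res <- converge(c(1, 1), w, "synchronous", max_iters = 10)
  expect_false(res$converged)
  expect_false(is.null(res$cycle))
  expect_equal(res$cycle[[1]], -res$cycle[[2]], ignore_attr = TRUE)
})

test_that("noisy probes recall a single stored spin pattern", {
  set.seed(61)
  m <- 100
  ok <- 0L
  n_trials <- 100
  for (trial in seq_len(n_trials)) {
    pat <- random_binary(m)
    w <- build_weights(pat, "spin")
    s <- encode_states(pat, "spin")
    d <- sample(0:10, 1)
    probe <- s
    if (d > 0) {
      idx <- sample.int(m, d)
      probe[idx] <- -probe[idx]
    }
    res <- converge(probe, w, "asynchronous", max_iters = 50,
                    order_seed = trial)
    if (all(res$state == s) || all(res$state == -s)) ok <- ok + 1L
  }
  expect_gte(ok / n_trials, 0.99)
})
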