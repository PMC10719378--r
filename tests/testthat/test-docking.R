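small_cfg <- function(...) {
  de_config(population_size = 8, generations = 3, seed = 42, ...)
}

test_that("population initialization respects bounds, modes and seeds", {
  s <- toy_helix()
  fx <- toy_fixture("T", 3)
  bounds <- make_bounds(fx$sd, "local", fx$params)
  cfg <- small_cfg()
  set.seed(cfg$seed)
  pop <- initialize_population(s, fx$sd, bounds, "local", cfg)
  expect_length(pop, 8)
  for (ind in pop) {
    expect_equal(square_well_penalty(ind$params, bounds), 0)
    expect_equal(ind$flip, 0L)
  }
  # determinism
  set.seed(cfg$seed)
  pop2 <- initialize_population(s, fx$sd, bounds, "local", cfg)
  expect_identical(pop, pop2)
  # global mode splits the flip orientations 50/50 and slides z to contact
  gb <- make_bounds(fx$sd, "global", fx$params)
  set.seed(cfg$seed)
  gpop <- initialize_population(s, fx$sd, gb, "global", cfg)
  flips <- vapply(gpop, `[[`, 0L, "flip")
  expect_equal(sum(flips == 0), 4)
  expect_equal(sum(flips == 1), 4)
  for (ind in gpop) expect_gt(ind$params[["z"]], 0)
  expect_error(initialize_population(list(), fx$sd, bounds, "local", cfg),
               "empty")
})

test_that("de_step implements rand/1/bin with a forced crossover position", {
  s <- toy_helix()
  fx <- toy_fixture("T", 3)
  bounds <- make_bounds(fx$sd, "local", fx$params)
  set.seed(1)
  pop <- initialize_population(s, fx$sd, bounds, "local", small_cfg())
  # CR = 0: the trial differs from the target in exactly one parameter
  set.seed(2)
  tr0 <- de_step(pop, de_config(recombination_rate = 0, mutation_rate = 0.1))
  for (i in seq_along(pop)) {
    ndiff <- sum(abs(tr0[[i]]$params - pop[[i]]$params) > 1e-12)
    expect_equal(ndiff, 1)
    expect_equal(tr0[[i]]$bb, pop[[i]]$bb)
  }
  # CR = 1: the trial equals the full donor vector a + F (b - c)
  set.seed(3)
  tr1 <- de_step(pop, de_config(recombination_rate = 1, mutation_rate = 0.5))
  params_mat <- t(vapply(pop, function(p) p$params[PARAM_NAMES], numeric(6)))
  for (i in seq_along(pop)) {
    v <- tr1[[i]]$params[PARAM_NAMES]
    # the donor must be expressible as a + 0.5 (b - c) from three others
    found <- FALSE
    others <- setdiff(seq_along(pop), i)
    for (a in others) for (b in others) for (cc in others) {
      if (length(unique(c(a, b, cc))) < 3) next
      donor <- params_mat[a, ] + 0.5 * (params_mat[b, ] - params_mat[cc, ])
      if (max(abs(donor - v)) < 1e-9) found <- TRUE
    }
    expect_true(found)
  }
  expect_error(de_step(pop[1:3], small_cfg()), "at least 4")
})

test_that("the empirical crossover rate matches the binomial scheme", {
  # with CR = 0.7 and one forced position out of six, the expected
  # per-parameter donor fraction is 0.7 + 0.3/6 = 0.75 (computed oracle)
  s <- toy_helix()
  fx <- toy_fixture("T", 3)
  bounds <- make_bounds(fx$sd, "local", fx$params)
  set.seed(4)
  pop <- initialize_population(s, fx$sd, bounds, "local",
                               de_config(population_size = 20))
  cfg <- de_config(recombination_rate = 0.7, mutation_rate = 0.3)
  set.seed(5)
  diffs <- 0; total <- 0
  for (rep in 1:850) {
    trials <- de_step(pop, cfg)
    for (i in seq_along(pop)) {
      diffs <- diffs + sum(abs(trials[[i]]$params - pop[[i]]$params) > 1e-12)
      total <- total + 6
    }
  }
  expect_equal(diffs / total, 0.75, tolerance = 0.011)
})

test_that("sliding moves step 0.3 A and stop on clashes or step budget", {
  s <- toy_helix()
  fx <- toy_fixture("T", 3)
  ctx <- cubedock:::dock_context(s, fx$sd)
  cfg <- de_config()
  # a single translation step moves the subunit COM by exactly the step
  p1 <- cubedock:::params_after_translation(fx$params, 0, c(0, 0, -0.3), 3)
  com0 <- cubedock:::placement_com(fx$params)
  com1 <- cubedock:::placement_com(p1)
  expect_equal(sqrt(sum((com1 - com0)^2)), 0.3, tolerance = 1e-9)
  # the translation preserves the global orientation (same assembly shape)
  asm0 <- place_and_expand(s, fx$params, fx$sd)
  asm1 <- place_and_expand(s, p1, fx$sd)
  d <- chain_com(asm0$chains[[1]]) - chain_com(asm1$chains[[1]])
  expect_equal(unname(d), c(0, 0, 0.3), tolerance = 1e-9)
  # already-clashing start: parameters unchanged
  clashy <- fx$params; clashy[["z"]] <- fx$params[["z"]] - 3
  bounds <- make_bounds(fx$sd, "local", clashy)
  ind <- cubedock:::new_individual(1L, clashy)
  out <- cubedock:::slide_individual(ctx, ind, bounds, cfg)
  expect_equal(out$params, clashy)
  # nothing in reach: the full step budget is spent on the setup axis
  lonely <- fx$params; lonely[["z"]] <- 500; lonely[["x"]] <- 12
  gbounds <- make_bounds(fx$sd, "global", lonely)
  ind <- cubedock:::new_individual(1L, lonely)
  out <- cubedock:::slide_individual(ctx, ind, gbounds, cfg)
  slid <- cubedock:::placement_com(lonely) - cubedock:::placement_com(out$params)
  # each fold slides slide_max steps of 0.3 A along its chosen axis; the
  # setup-axis (z) share alone accounts for >= 30 A
  expect_gte(slid[3], cfg$slide_max * cfg$slide_step - 1e-6)
  # out-of-bounds slides revert to the start
  nb <- make_bounds(fx$sd, "local", lonely)
  ind <- cubedock:::new_individual(1L, lonely)
  out2 <- cubedock:::slide_individual(ctx, ind, nb, cfg)
  expect_equal(out2$params, lonely)
})

test_that("local search never returns a worse state and obeys Metropolis", {
  s <- toy_helix()
  fx <- toy_fixture("T", 3)
  ctx <- cubedock:::dock_context(s, fx$sd)
  bounds <- make_bounds(fx$sd, "local", fx$params)
  cfg <- de_config(seed = 9)
  start <- fx$params
  start[["z"]] <- start[["z"]] + 1.5
  start[["psi"]] <- start[["psi"]] + 4
  ind <- cubedock:::new_individual(1L, start)
  set.seed(9)
  e_start <- cubedock:::ctx_iscore(ctx, start)
  out <- cubedock:::local_search_individual(ctx, ind, bounds, cfg)
  expect_lte(out$iscore, e_start + 1e-9)
  # starting at the optimum: cannot end worse (best-state bookkeeping)
  ind0 <- cubedock:::new_individual(1L, fx$params)
  set.seed(10)
  out0 <- cubedock:::local_search_individual(ctx, ind0, bounds, cfg)
  expect_lte(out0$iscore, cubedock:::ctx_iscore(ctx, fx$params) + 1e-9)
  # a downhill move is always Metropolis-accepted
  expect_true(cubedock:::metropolis_accept(-1, 1))
})

test_that("selection keeps the lower Iscore and ties keep the parent", {
  a <- cubedock:::new_individual(1L, rigid_body_params(), iscore = -3)
  b <- cubedock:::new_individual(1L, rigid_body_params(psi = 1), iscore = -5)
  expect_identical(select_individual(a, b), b)
  expect_identical(select_individual(b, a), b)
  tie <- cubedock:::new_individual(1L, rigid_body_params(psi = 2),
                                   iscore = -3)
  expect_identical(select_individual(a, tie), a)
})

test_that("backbone trials only ever improve the Iscore", {
  s <- toy_helix()
  s2 <- make_toy_subunit(16, seed = 3, noise = 0.2)
  fx <- toy_fixture("T", 3)
  ctxs <- lapply(list(s, s2), cubedock:::dock_context, sd = fx$sd)
  bounds <- make_bounds(fx$sd, "local", fx$params)
  ind <- cubedock:::new_individual(1L, fx$params)
  ind <- cubedock:::eval_individual(ctxs, ind, bounds)
  # probability 0: identity
  cfg0 <- de_config(bb_trial_probability = 0)
  set.seed(1)
  expect_identical(cubedock:::bb_trial_individual(ind, ctxs, bounds, cfg0),
                   ind)
  # probability 1 with a 2-member ensemble: swap happens or reverts by score
  cfg1 <- de_config(bb_trial_probability = 1)
  set.seed(2)
  out <- cubedock:::bb_trial_individual(ind, ctxs, bounds, cfg1)
  expect_lte(out$iscore, ind$iscore)
  expect_true(out$bb %in% c(1L, 2L))
})

test_that("runs are reproducible and elitist", {
  s <- toy_helix()
  fx <- toy_fixture("T", 3)
  cfg <- small_cfg()
  r1 <- run_docking(s, fx$sd, "recapitulate", cfg)
  r2 <- run_docking(s, fx$sd, "recapitulate", cfg)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$archive, r2$archive)
  expect_true(all(diff(r1$log$best_iscore) <= 1e-9))
  expect_error(run_docking(s, symmetry_def("T", 3), "recapitulate", cfg),
               "template")
})

test_that("perturb_params draws uniformly within the stated ranges", {
  ctr <- rigid_body_params(psi = 5, z = 20, x = 3)
  zero <- c(psi = 0, theta = 0, phi = 0, z = 0, x = 0, lam = 0)
  expect_equal(perturb_params(ctr, zero), ctr)
  rng <- c(psi = 4, theta = 2, phi = 1, z = 3, x = 1, lam = 5)
  set.seed(11)
  draws <- t(replicate(4000, perturb_params(ctr, rng)))
  for (nm in PARAM_NAMES) {
    expect_gte(min(draws[, nm]), ctr[[nm]] - rng[[nm]] - 1e-12)
    expect_lte(max(draws[, nm]), ctr[[nm]] + rng[[nm]] + 1e-12)
    expect_equal(mean(draws[, nm]), ctr[[nm]],
                 tolerance = 0.1 * max(rng[[nm]], 1))
  }
  # bounds clipping
  b <- make_bounds(symmetry_def("T", 3), "local", ctr)
  set.seed(12)
  clipped <- t(replicate(500, perturb_params(ctr, c(psi = 80, theta = 0,
                                                    phi = 0, z = 0, x = 0,
                                                    lam = 0), b)))
  expect_gte(min(clipped[, "psi"]), b$bounds["psi", "lo"] - 1e-12)
  expect_lte(max(clipped[, "psi"]), b$bounds["psi", "hi"] + 1e-12)
})
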