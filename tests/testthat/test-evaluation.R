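test_that("symmetric RMSD is zero across symmetry-equivalent configurations", {
  fx <- toy_fixture("I", 3)
  expect_equal(symmetric_rmsd(fx$assembly, fx$assembly, "I", 3), 0,
               tolerance = 1e-9)
  # model rotated by 360/n about the setup fold is equivalent
  rot <- rigid_move_assembly(fx$assembly, rot_z(120), c(0, 0, 0))
  expect_lt(symmetric_rmsd(rot, fx$assembly, "I", 3), 1e-6)
  # any global rigid motion is removed by superposition
  moved <- rigid_move_assembly(fx$assembly, rot_axis(c(1, 2, 3), 50),
                               c(5, -2, 8))
  expect_lt(symmetric_rmsd(moved, fx$assembly, "I", 3), 1e-6)
  # the rotation grid has exactly n configurations
  expect_length(cubedock:::setup_fold_permutations("I", 5), 5)
  expect_length(cubedock:::setup_fold_permutations("T", 3), 3)
  expect_error(symmetric_rmsd(assembly(fx$assembly$chains[1:6]),
                              fx$assembly, "I", 3), "chain count")
})

test_that("DockQ matches an independent straightforward implementation", {
  # independent oracle: plain-loop DockQ on residue-numbered chain pairs
  oracle_dockq <- function(mp, np) {
    heavy <- function(ch) ch$atoms[ch$atoms$element != "H", ]
    resd <- function(a1, a2, r1, r2) {
      x1 <- a1[a1$resno == r1, c("x", "y", "z")]
      x2 <- a2[a2$resno == r2, c("x", "y", "z")]
      min(sqrt(cubedock:::cross_dist2(as.matrix(x1), as.matrix(x2))))
    }
    na <- heavy(np[[1]]); nb <- heavy(np[[2]])
    ma <- heavy(mp[[1]]); mb <- heavy(mp[[2]])
    ra <- unique(na$resno); rb <- unique(nb$resno)
    natc <- list(); ifa <- c(); ifb <- c()
    for (i in ra) for (j in rb) {
      d <- resd(na, nb, i, j)
      if (d < 5) natc[[length(natc) + 1]] <- c(i, j)
      if (d < 10) { ifa <- c(ifa, i); ifb <- c(ifb, j) }
    }
    kept <- 0
    for (p in natc) if (resd(ma, mb, p[1], p[2]) < 5) kept <- kept + 1
    fnat <- kept / length(natc)
    bb <- function(ch, res) {
      a <- ch$atoms[ch$atoms$atom %in% c("N", "CA", "C", "O") &
                      ch$atoms$resno %in% res, ]
      as.matrix(a[, c("x", "y", "z")])
    }
    ifa <- unique(ifa); ifb <- unique(ifb)
    irms <- superpose(rbind(bb(mp[[1]], ifa), bb(mp[[2]], ifb)),
                      rbind(bb(np[[1]], ifa), bb(np[[2]], ifb)))$rmsd
    sp <- superpose(bb(mp[[1]], ra), bb(np[[1]], ra))
    ml <- sweep(bb(mp[[2]], rb) %*% t(sp$R), 2, -sp$t)
    lrms <- coord_rmsd(ml, bb(np[[2]], rb))
    (fnat + 1 / (1 + (irms / 1.5)^2) + 1 / (1 + (lrms / 8.5)^2)) / 3
  }
  fx <- toy_fixture("T", 3)
  j <- cubedock:::fold_partner(fx$assembly, "T", 3, 3)
  nat <- list(fx$assembly$chains[[1]], fx$assembly$chains[[j]])
  expect_equal(dockq(nat, nat), 1.0, tolerance = 1e-9)
  set.seed(21)
  for (rep in 1:5) {
    mod <- list(
      transform_chain(nat[[1]], rot_axis(rnorm(3), runif(1, 1, 8)),
                      rnorm(3, 0, 1.5)),
      transform_chain(nat[[2]], rot_axis(rnorm(3), runif(1, 1, 8)),
                      rnorm(3, 0, 1.5)))
    expect_equal(dockq(mod, nat), oracle_dockq(mod, nat), tolerance = 0.01)
  }
  # far-displaced ligand scores near zero
  far <- list(nat[[1]], transform_chain(nat[[2]], diag(3), c(100, 0, 0)))
  expect_lt(dockq(far, nat), 0.1)
  # a native pair without contacts is an error
  expect_error(dockq(far, far), "no interface contacts")
})

test_that("delta SASA matches a brute-force oracle and decays with distance", {
  fx <- toy_fixture("T", 3)
  j <- cubedock:::fold_partner(fx$assembly, "T", 3, 3)
  ds <- delta_sasa(fx$assembly, 1, j)
  expect_gt(ds, 50)
  # R-level Shrake-Rupley oracle
  r_sasa <- function(atoms) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    radii <- cubedock:::atom_radius_for_sasa(atoms) + 1.4
    n <- nrow(xyz)
    ga <- pi * (3 - sqrt(5)); i <- seq_len(960) - 0.5
    z <- 1 - 2 * i / 960; r <- sqrt(1 - z^2)
    pts <- cbind(r * cos(ga * (i - 0.5)), r * sin(ga * (i - 0.5)), z)
    # match the kernel's spiral exactly
    pts <- cbind(r * cos(ga * (seq_len(960) - 1)),
                 r * sin(ga * (seq_len(960) - 1)), z)
    total <- 0
    for (a in seq_len(n)) {
      sph <- sweep(pts * radii[a], 2, xyz[a, ], "+")
      acc <- rep(TRUE, 960)
      for (b in seq_len(n)) {
        if (b == a) next
        d2 <- rowSums(sweep(sph, 2, xyz[b, ])^2)
        acc <- acc & d2 >= radii[b]^2
      }
      total <- total + 4 * pi * radii[a]^2 * mean(acc)
    }
    total
  }
  a1 <- fx$assembly$chains[[1]]$atoms
  a2 <- fx$assembly$chains[[j]]$atoms
  oracle <- r_sasa(a1) + r_sasa(a2) - r_sasa(rbind(a1, a2))
  expect_equal(ds, oracle, tolerance = 1e-6)
  # non-contacting pair buries nothing
  k_far <- which.max(vapply(fx$assembly$chains, function(ch)
    sum((chain_com(ch) - chain_com(fx$assembly$chains[[1]]))^2), 0))
  expect_lt(abs(delta_sasa(fx$assembly, 1, k_far)), 1e-6)
  # monotone decay as the partner is pulled away
  pulls <- vapply(c(0, 3, 8, 30), function(d) {
    asm <- fx$assembly
    dir <- chain_com(asm$chains[[j]]) - chain_com(asm$chains[[1]])
    dir <- dir / sqrt(sum(dir^2))
    asm$chains[[j]] <- transform_chain(asm$chains[[j]], diag(3), d * dir)
    delta_sasa(asm, 1, j)
  }, 0)
  expect_true(all(diff(pulls) <= 1e-6))
})

test_that("pairwise DockQ weights interfaces by buried area", {
  fx <- toy_fixture("O", 3)
  # this toy contacts only some of the unique fold interfaces; the others
  # are skipped with a warning and the weights renormalized
  expect_warning(pd <- pairwise_dockq(fx$assembly, fx$assembly, "O", 3),
                 "skipped")
  expect_equal(pd$pairwise_dockq, 1.0, tolerance = 1e-9)
  expect_equal(sum(pd$interfaces$weight), 1, tolerance = 1e-9)
  expect_true(all(pd$interfaces$fold %in% c(2, 3, 4)))
  # weights are proportional to the measured buried areas
  expect_equal(pd$interfaces$weight,
               pd$interfaces$delta_sasa / sum(pd$interfaces$delta_sasa),
               tolerance = 1e-12)
  # a perturbed model scores below the native
  set.seed(31)
  mod <- fx$assembly
  for (i in seq_along(mod$chains))
    mod$chains[[i]] <- transform_chain(mod$chains[[i]],
                                       rot_axis(rnorm(3), 4), rnorm(3, 0, 1))
  pd2 <- suppressWarnings(pairwise_dockq(mod, fx$assembly, "O", 3))
  expect_lt(pd2$pairwise_dockq, 1)
  expect_gt(pd2$pairwise_dockq, 0)
})

test_that("the assembly TM-score behaves like a similarity in (0, 1]", {
  fx <- toy_fixture("T", 3)
  expect_equal(tm_score_assembly(fx$assembly, fx$assembly, "T", 3), 1,
               tolerance = 1e-9)
  moved <- rigid_move_assembly(fx$assembly, rot_axis(c(3, 1, -2), 35),
                               c(4, 4, -7))
  expect_equal(tm_score_assembly(moved, fx$assembly, "T", 3), 1,
               tolerance = 1e-6)
  # scrambled coordinates score low
  set.seed(41)
  scram <- fx$assembly
  for (i in seq_along(scram$chains)) {
    a <- scram$chains[[i]]$atoms
    a[, c("x", "y", "z")] <- matrix(rnorm(nrow(a) * 3, 0, 20), ncol = 3)
    scram$chains[[i]]$atoms <- a
  }
  expect_lt(tm_score_assembly(scram, fx$assembly, "T", 3), 0.3)
  expect_error(tm_score_assembly(assembly(fx$assembly$chains[1:3]),
                                 fx$assembly, "T", 3), "residue count")
})

test_that("quality classification follows the DockQ/TM thresholds", {
  expect_equal(classify_quality(0.99, 0.85), "highly-accurate")
  expect_equal(classify_quality(0.95, 0.10), "none")
  expect_equal(classify_quality(0.89, 0.90), "acceptable") # TM below 0.9
  expect_equal(classify_quality(0.95, 0.50), "successful")
  expect_equal(classify_quality(0.90, 0.23), "successful")
  expect_equal(classify_quality(0.90, 0.80), "highly-accurate")
  # monotone in both arguments
  expect_true(match(classify_quality(0.95, 0.5),
                    c("none", "acceptable", "successful", "highly-accurate")) >=
                match(classify_quality(0.85, 0.5),
                      c("none", "acceptable", "successful", "highly-accurate")))
})

test_that("the success bootstrap matches binomial expectations", {
  all_good <- make_runs_table(100, 100, 1, 20)
  bs <- success_bootstrap(all_good, 1:5, reps = 50, seed = 1)
  expect_equal(bs$table$success, rep(1, 5))
  expect_equal(unname(bs$runs_needed["80"]), 1L)
  none <- make_runs_table(100, 0, 1, 20)
  bs0 <- success_bootstrap(none, 1:5, reps = 50, seed = 1)
  expect_equal(bs0$table$success, rep(0, 5))
  half <- make_runs_table(100, 50, 1, 20)
  bs5 <- success_bootstrap(half, 1:4, reps = 200, seed = 2)
  expect_equal(bs5$table$success[1], 0.5, tolerance = 0.2)
  expect_equal(bs5$table$success[2], 0.75, tolerance = 0.15)
})

test_that("evaluate_model aggregates the metrics coherently", {
  fx <- toy_fixture("T", 3)
  ev <- suppressWarnings(evaluate_model(fx$assembly, fx$assembly, "T", 3))
  expect_equal(ev$tm_score, 1, tolerance = 1e-9)
  expect_equal(ev$pairwise_dockq, 1, tolerance = 1e-9)
  expect_equal(ev$rmsd, 0, tolerance = 1e-9)
  expect_equal(ev$quality_class, "highly-accurate")
})
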