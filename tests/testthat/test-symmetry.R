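test_that("cubic groups have the right order and group structure", {
  orders <- c(T = 12, O = 24, I = 60)
  for (kind in names(orders)) {
    g <- group_rotations(kind)
    expect_equal(g$order, unname(orders[kind]))
    # identity present
    expect_true(any(vapply(g$rotations, function(M)
      max(abs(M - diag(3))) < 1e-10, TRUE)))
    # orthonormal, determinant +1
    for (M in g$rotations) {
      expect_lt(max(abs(t(M) %*% M - diag(3))), 1e-10)
      expect_equal(det(M), 1, tolerance = 1e-10)
    }
    # closure and inverse membership, brute force over all ordered pairs
    mats <- g$rotations
    in_group <- function(M) {
      any(vapply(mats, function(X) sqrt(sum((X - M)^2)) < 1e-8, TRUE))
    }
    pairs <- expand.grid(i = seq_along(mats), j = seq_along(mats))
    if (kind == "I") { # sample pairs to keep the suite fast
      set.seed(1)
      pairs <- pairs[sample(nrow(pairs), 400), ]
    }
    for (r in seq_len(nrow(pairs)))
      expect_true(in_group(mats[[pairs$i[r]]] %*% mats[[pairs$j[r]]]))
    for (M in mats) expect_true(in_group(t(M)))
  }
})

test_that("fold axes are counted, normalized and conjugation-closed", {
  expect_equal(nrow(fold_axes(group_rotations("O"), 4)), 3)
  expect_equal(nrow(fold_axes(group_rotations("I"), 5)), 6)
  expect_equal(nrow(fold_axes(group_rotations("I"), 2)), 15)
  expect_equal(nrow(fold_axes(group_rotations("T"), 3)), 4)
  expect_error(fold_axes(group_rotations("T"), 5), "not available")
  g <- group_rotations("O")
  A <- fold_axes(g, 4)
  expect_equal(rowSums(A^2), rep(1, nrow(A)), tolerance = 1e-10)
  # the axis set (as lines) is invariant under every group rotation
  for (M in g$rotations) {
    moved <- A %*% t(M)
    for (i in seq_len(nrow(moved))) {
      d <- apply(A, 1, function(a) min(sum((a - moved[i, ])^2),
                                       sum((a + moved[i, ])^2)))
      expect_lt(min(d), 1e-12)
    }
  }
})

test_that("place_and_expand produces a symmetric assembly of full order", {
  s <- toy_helix()
  sd <- symmetry_def("I", 3)
  p <- rigid_body_params(psi = 8, theta = 20, phi = -15, z = 30, x = 6,
                         lam = 12)
  asm <- place_and_expand(s, p, sd)
  expect_equal(length(asm$chains), 60)
  # all chain centers of mass equidistant from the assembly center
  d <- vapply(asm$chains, function(ch) sqrt(sum(chain_com(ch)^2)), 0)
  expect_lt(diff(range(d)), 1e-8)
  # exactly invariant under every group rotation (atoms map onto atoms of
  # some chain)
  g <- oriented_group("I", 3)
  coords <- lapply(asm$chains, chain_coords)
  set.seed(2)
  for (k in sample(60, 5)) {
    M <- g$rotations[[k]]
    moved <- coords[[7]] %*% t(M)
    errs <- vapply(coords, function(X) max(abs(X - moved)), 0)
    expect_lt(min(errs), 1e-8)
  }
  expect_error(place_and_expand(s, replace(p, 1, NA), sd), "finite")
})

test_that("extract_params inverts place_and_expand", {
  s <- toy_helix()
  for (spec in list(list("T", 3), list("O", 4), list("I", 2))) {
    kind <- spec[[1]]; fold <- spec[[2]]
    sd <- symmetry_def(kind, fold)
    p <- rigid_body_params(psi = 14, theta = 22, phi = -9, z = 25, x = 4.5,
                           lam = 0.3 * (360 / fold) / 2)
    asm <- place_and_expand(s, p, sd)
    p2 <- extract_params(asm, kind, fold, subunit = s)
    expect_lt(max(abs(p2[c("psi", "theta", "phi", "lam")] -
                        p[c("psi", "theta", "phi", "lam")])), 0.1)
    expect_lt(max(abs(p2[c("z", "x")] - p[c("z", "x")])), 0.01)
  }
})

test_that("extract_params is invariant to a rigid motion of the assembly", {
  s <- toy_helix()
  sd <- symmetry_def("T", 3)
  p <- rigid_body_params(psi = 14, theta = 22, phi = -9, z = 20, x = 4,
                         lam = 15)
  asm <- place_and_expand(s, p, sd)
  moved <- rigid_move_assembly(asm, rot_axis(c(2, -1, 4), 63), c(7, -3, 11))
  p2 <- extract_params(moved, "T", 3, subunit = s)
  expect_lt(max(abs(p2[PARAM_NAMES] - p[PARAM_NAMES])), 0.1)
  # regeneration agrees by symmetric RMSD
  regen <- place_and_expand(s, p2, sd)
  expect_lt(symmetric_rmsd(regen, asm, "T", 3), 0.1)
})

test_that("extract_params tolerates imperfect symmetry", {
  s <- toy_helix()
  sd <- symmetry_def("T", 3)
  p <- rigid_body_params(psi = 14, theta = 22, phi = -9, z = 20, x = 4,
                         lam = 15)
  asm <- place_and_expand(s, p, sd)
  set.seed(7)
  for (i in seq_along(asm$chains)) {
    a <- asm$chains[[i]]$atoms
    a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] +
      matrix(rnorm(nrow(a) * 3, 0, 0.5), ncol = 3)
    asm$chains[[i]]$atoms <- a
  }
  p2 <- extract_params(asm, "T", 3, subunit = s)
  regen <- place_and_expand(s, p2, sd)
  expect_lt(symmetric_rmsd(regen, asm, "T", 3), 1)
  # wrong chain count is rejected
  expect_error(extract_params(assembly(asm$chains[1:6]), "T", 3),
               "requires 12")
})

test_that("build_subsystem keeps the energy-complete neighborhood", {
  fx <- toy_fixture("T", 3)
  sub <- build_subsystem(fx$assembly, fx$sd, cutoff = 12)
  expect_lt(length(sub$chains), length(fx$assembly$chains))
  expect_gt(length(sub$chains), 1)
  # interface score of the main subunit matches the full assembly
  full <- brute_force_iscore(fx$assembly)
  subs <- brute_force_iscore(sub)
  expect_lt(abs(full - subs) / abs(full), 1e-6)
  # cutoff 0 keeps the main subunit only
  expect_warning(solo <- build_subsystem(fx$assembly, fx$sd, cutoff = 0))
  expect_equal(length(solo$chains), 1)
  # idempotence
  sub2 <- build_subsystem(sub, fx$sd, cutoff = 12)
  expect_equal(length(sub2$chains), length(sub$chains))
})

test_that("bounds follow the lambda arithmetic and square-well depth", {
  ctr <- rigid_body_params()
  b <- make_bounds(symmetry_def("I", 2), "global", ctr)
  expect_equal(unname(b$bounds["lam", ]), c(-90, 90))
  b5 <- make_bounds(symmetry_def("I", 5), "global", ctr)
  expect_equal(unname(b5$bounds["lam", ]), c(-36, 36))
  bl <- make_bounds(symmetry_def("I", 2), "local", ctr)
  expect_equal(unname(bl$bounds["lam", ]), c(-45, 45))
  expect_equal(unname(bl$bounds["psi", ]), c(-40, 40))
  expect_equal(unname(bl$bounds["x", ]), c(-5, 5))
  expect_equal(unname(b$bounds["z", ]), c(0, 1000))
  # square-well penalty: zero inside, 1e9 per violated parameter
  inside <- rigid_body_params(z = 500, x = 2)
  expect_equal(square_well_penalty(inside, b), 0)
  neg_z <- rigid_body_params(z = -1, x = 2)
  expect_gte(square_well_penalty(neg_z, b), 1e9)
  two <- rigid_body_params(z = -1, x = 20)
  expect_equal(square_well_penalty(two, b), 2e9)
})

test_that("flip_orientation is an involution that reverses axis polarity", {
  s <- toy_helix()
  sd <- symmetry_def("T", 3)
  p <- rigid_body_params(psi = 10, theta = 25, phi = 5, z = 22, x = 4,
                         lam = 10)
  asm <- place_and_expand(s, p, sd)
  pf <- flip_orientation(p)
  pff <- flip_orientation(pf)
  back <- place_and_expand(s, pff, sd)
  expect_lt(symmetric_rmsd(back, asm, "T", 3), 1e-6)
  # a marker atom's z offset from the chain COM flips sign
  marker_z <- function(params) {
    ch <- place_and_expand(s, params, sd)$chains[[1]]
    (chain_coords(ch)[1, ] - chain_com(ch))[3]
  }
  expect_lt(marker_z(p) * marker_z(pf), 0)
  # the flip commutes with the lambda rotation up to the sign of lambda
  expect_lt(max(abs(rot_x(180) %*% rot_z(7) - rot_z(-7) %*% rot_x(180))),
            1e-12)
})

test_that("symmetry definition files round trip", {
  fx <- toy_fixture("T", 3)
  path <- withr::local_tempfile(fileext = ".symm")
  write_symdef(fx$sd, path)
  back <- read_symdef(path)
  expect_equal(back$kind, "T")
  expect_equal(back$setup_fold, 3)
  expect_equal(back$params[PARAM_NAMES], fx$sd$params[PARAM_NAMES],
               tolerance = 1e-5)
  expect_equal(back$subsystem, fx$sd$subsystem)
})
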