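# Cubic point-group machinery: rotation sets, fold axes, the six-parameter
# placement of the main subunit, symmetry expansion, subsystem selection,
# parameter extraction from native assemblies, and parameter bounds.
#
# Conventions (fixed for reproducibility):
#  * the setup-fold axis is the global z axis;
#  * subunit orientation is the intrinsic Z-Y-Z Euler rotation
#    euler_zyz(psi, theta, phi) about the subunit center of mass;
#  * placement order: Euler rotation -> translate COM to (x, 0, z) ->
#    rotate by lambda about z -> copy through every group rotation.

.cubedock_env <- new.env(parent = emptyenv())

GROUP_FOLDS <- list(T = c(2, 3), O = c(2, 3, 4), I = c(2, 3, 5))
GROUP_ORDER <- c(T = 12, O = 24, I = 60)

golden <- (1 + sqrt(5)) / 2

# stable text key for a numeric matrix/vector (normalizes negative zero)
num_key <- function(x, digits = 9) {
  v <- round(x, digits)
  v[v == 0] <- 0
  paste(sprintf("%+.*f", digits, v), collapse = ",")
}

canonical_group_order <- function(mats) {
  keyinfo <- lapply(mats, function(M) {
    aa <- axis_angle(M)
    c(round(aa$angle, 6), round(aa$axis, 6))
  })
  keys <- vapply(keyinfo, num_key, "", digits = 6)
  mats[order(vapply(keyinfo, `[`, 0, 1), keys)]
}

build_group_O <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  mats <- list()
  for (p in perms) {
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      M <- matrix(0, 3, 3)
      M[1, p[1]] <- s1; M[2, p[2]] <- s2; M[3, p[3]] <- s3
      if (abs(det(M) - 1) < 1e-9) mats[[length(mats) + 1]] <- M
    }
  }
  mats
}

build_group_T <- function() {
  verts <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  keep <- function(M) {
    moved <- verts %*% t(M)
    all(apply(moved, 1, function(v)
      any(rowSums(abs(sweep(verts, 2, v))) < 1e-9)))
  }
  Filter(keep, build_group_O())
}

build_group_I <- function() {
  # closure of a 2-fold on z and a 5-fold axis in the xz plane
  gens <- list(rot_z(180), rot_axis(c(golden, 0, 1), 72))
  mats <- list(diag(3))
  key <- num_key
  seen <- new.env(parent = emptyenv())
  assign(key(diag(3)), TRUE, envir = seen)
  queue <- mats
  while (length(queue)) {
    M <- queue[[1]]; queue <- queue[-1]
    for (g in gens) {
      P <- g %*% M
      k <- key(P)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        mats[[length(mats) + 1]] <- P
        queue[[length(queue) + 1]] <- P
      }
    }
  }
  if (length(mats) != 60) stop("icosahedral closure failed")
  mats
}

#' Rotation set of a cubic point group
#'
#' Returns the full rotation group of the tetrahedron (order 12), octahedron
#' (order 24) or icosahedron (order 60) in a fixed standard orientation
#' (octahedron aligned to the coordinate axes; tetrahedron as the rotation
#' subgroup of the octahedral frame; icosahedron with a 2-fold on z and a
#' 5-fold axis in the xz plane). Element order is deterministic.
#'
#' @param kind one of `"T"`, `"O"`, `"I"`.
#' @return object of class `symmetry_group` with fields `kind`, `rotations`
#'   (list of 3x3 matrices, identity first), `order` and `folds`.
#' @export
group_rotations <- function(kind) {
  kind <- match.arg(kind, c("T", "O", "I"))
  cache_key <- paste0("group_", kind)
  if (!is.null(.cubedock_env[[cache_key]])) return(.cubedock_env[[cache_key]])
  mats <- switch(kind, T = build_group_T(), O = build_group_O(),
                 I = build_group_I())
  mats <- canonical_group_order(mats)
  g <- structure(list(kind = kind, rotations = mats, order = length(mats),
                      folds = GROUP_FOLDS[[kind]]),
                 class = "symmetry_group")
  if (g$order != GROUP_ORDER[[kind]])
    stop("group order mismatch for ", kind)
  .cubedock_env[[cache_key]] <- g
  g
}

#' @export
print.symmetry_group <- function(x, ...) {
  cat("<symmetry_group>", x$kind, "- order", x$order,
      "- folds", paste(x$folds, collapse = ","), "\n")
  invisible(x)
}

canonical_axis <- function(ax, tol = 1e-8) {
  flip <- if (abs(ax[3]) > tol) ax[3] < 0
          else if (abs(ax[2]) > tol) ax[2] < 0
          else ax[1] < 0
  if (flip) -ax else ax
}

#' Fold axes of a cubic group
#'
#' The distinct rotation-axis lines of all group elements with rotation angle
#' `360 / n`, each returned as a unit vector with a canonical sign, ordered
#' by descending z component then lexicographically.
#'
#' @param group a [group_rotations()] object.
#' @param n fold order; must be one of `group$folds`.
#' @return matrix with one unit axis per row.
#' @export
fold_axes <- function(group, n) {
  if (!n %in% group$folds)
    stop("fold ", n, " not available in group ", group$kind)
  target <- 360 / n
  axes <- list()
  for (M in group$rotations) {
    aa <- axis_angle(M)
    if (abs(aa$angle - target) < 1e-3)
      axes[[length(axes) + 1]] <- canonical_axis(aa$axis)
  }
  A <- do.call(rbind, axes)
  A <- A[!duplicated(round(A, 8)), , drop = FALSE]
  ord <- order(-round(A[, 3], 8), round(A[, 1], 8), round(A[, 2], 8))
  A[ord, , drop = FALSE]
}

#' Cubic group rotated so that a chosen fold axis lies on z
#'
#' The placement convention puts the setup-fold axis on the global z axis,
#' so the group is conjugated by the minimal rotation taking its first
#' canonical `n`-fold axis onto z. The conjugated set is the same abstract
#' group; element order is preserved.
#'
#' @param kind `"T"`, `"O"` or `"I"`.
#' @param setup_fold fold order whose axis becomes z.
#' @return a `symmetry_group` with an extra `setup_fold` field.
#' @export
oriented_group <- function(kind, setup_fold) {
  cache_key <- paste0("oriented_", kind, "_", setup_fold)
  if (!is.null(.cubedock_env[[cache_key]])) return(.cubedock_env[[cache_key]])
  g <- group_rotations(kind)
  ax <- fold_axes(g, setup_fold)[1, ]
  z <- c(0, 0, 1)
  if (sum(ax * z) > 1 - 1e-12) {
    R <- diag(3)
  } else {
    rotax <- pracma_cross(ax, z)
    R <- rot_axis(rotax, rad2deg(acos(max(-1, min(1, sum(ax * z))))))
  }
  g$rotations <- lapply(g$rotations, function(M) R %*% M %*% t(R))
  g$setup_fold <- setup_fold
  g$orientation <- R
  .cubedock_env[[cache_key]] <- g
  g
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# stacked (3K x 3) rotation matrix block for the C++ kernels
stack_rotations <- function(group) {
  do.call(rbind, group$rotations)
}

#' Rigid-body parameter vector
#'
#' The six docking degrees of freedom: `psi`, `theta`, `phi` (degrees,
#' intrinsic Z-Y-Z rotation about the subunit center of mass), `z` (Angstrom,
#' translation along the setup-fold axis), `x` (Angstrom, translation
#' perpendicular to it) and `lam` (degrees, rotation of the placed subunit
#' about the setup-fold axis).
#'
#' @param psi,theta,phi Euler angles in degrees.
#' @param z,x translations in Angstrom.
#' @param lam rotation about the setup-fold axis in degrees.
#' @return named numeric vector of length 6.
#' @export
rigid_body_params <- function(psi = 0, theta = 0, phi = 0, z = 0, x = 0,
                              lam = 0) {
  p <- c(psi = unname(psi), theta = unname(theta), phi = unname(phi),
         z = unname(z), x = unname(x), lam = unname(lam))
  if (!all(is.finite(p))) stop("rigid body parameters must be finite")
  p
}

PARAM_NAMES <- c("psi", "theta", "phi", "z", "x", "lam")

#' Symmetry definition
#'
#' Couples a cubic symmetry kind with the setup fold used for the placement
#' parametrization, optionally carrying the generating rigid-body parameters
#' and the energy-complete subsystem chain indices.
#'
#' @param kind `"T"`, `"O"` or `"I"`.
#' @param setup_fold fold order of the setup axis.
#' @param params optional [rigid_body_params()].
#' @param subsystem optional integer chain indices.
#' @return object of class `symmetry_def`.
#' @export
symmetry_def <- function(kind, setup_fold, params = NULL, subsystem = NULL) {
  kind <- match.arg(kind, c("T", "O", "I"))
  if (!setup_fold %in% GROUP_FOLDS[[kind]])
    stop("setup fold ", setup_fold, " invalid for ", kind)
  structure(list(kind = kind, setup_fold = setup_fold, params = params,
                 subsystem = subsystem),
            class = "symmetry_def")
}

#' @export
print.symmetry_def <- function(x, ...) {
  cat("<symmetry_def>", x$kind, "with", x$setup_fold, "-fold setup axis\n")
  if (!is.null(x$params))
    cat("  params:", paste(sprintf("%s=%.3f", PARAM_NAMES, x$params[PARAM_NAMES]),
                           collapse = " "), "\n")
  invisible(x)
}

# rotation + translation of the main subunit for a parameter set
placement_transform <- function(params, flip = 0) {
  E <- euler_zyz(params[["psi"]], params[["theta"]], params[["phi"]])
  if (flip) E <- rot_x(180) %*% E
  Rl <- rot_z(params[["lam"]])
  list(R = Rl %*% E,
       t = as.vector(Rl %*% c(params[["x"]], 0, params[["z"]])))
}

#' Place a subunit and expand it through a cubic group
#'
#' The subunit is rotated by the intrinsic Z-Y-Z Euler angles about its
#' center of mass, translated so its COM sits at `(x, 0, z)`, rotated by
#' `lam` about z, and copied through every rotation of the oriented group.
#' Chain 1 of the result is the main subunit.
#'
#' @param subunit a `chain_model`.
#' @param params [rigid_body_params()].
#' @param sd a [symmetry_def()].
#' @param flip apply the 180-degree orientation flip about x before placing.
#' @return an [assembly()] with `group order` chains.
#' @export
place_and_expand <- function(subunit, params, sd, flip = 0) {
  if (!all(is.finite(params))) stop("non-finite rigid body parameters")
  g <- oriented_group(sd$kind, sd$setup_fold)
  pt <- placement_transform(params, flip)
  com <- chain_com(subunit)
  xyz0 <- sweep(chain_coords(subunit), 2, com) # center on COM
  chains <- vector("list", g$order)
  for (k in seq_len(g$order)) {
    G <- g$rotations[[k]]
    R <- G %*% pt$R
    t <- as.vector(G %*% pt$t)
    ch <- subunit
    moved <- xyz0 %*% t(R)
    moved <- sweep(moved, 2, -t)
    ch$atoms$x <- moved[, 1]; ch$atoms$y <- moved[, 2]; ch$atoms$z <- moved[, 3]
    ch$chain_id <- CHAIN_ID_POOL[k]
    chains[[k]] <- ch
  }
  assembly(chains, symmetry = sd$kind)
}

#' Energy-complete subsystem of a symmetric assembly
#'
#' Keeps the main subunit (chain 1) plus every chain with any CB atom
#' (CA for glycine) within `cutoff` of a main-subunit CB/CA(gly) atom. With
#' the default cutoff matching the scoring interaction range, scoring the
#' main subunit inside the subsystem reproduces the full-assembly value.
#'
#' @param x an [assembly()].
#' @param sd the generating [symmetry_def()] (used for bookkeeping only).
#' @param cutoff distance cutoff in Angstrom.
#' @return an [assembly()]; the kept chain indices are in
#'   `attr(, "subsystem")`.
#' @export
build_subsystem <- function(x, sd = NULL, cutoff = 12) {
  contact_pts <- function(chain) {
    a <- chain$atoms
    sel <- (a$atom == "CB") | (a$atom == "CA" & a$resname == "GLY")
    as.matrix(a[sel, c("x", "y", "z")])
  }
  main <- contact_pts(x$chains[[1]])
  keep <- 1L
  for (k in seq_along(x$chains)[-1]) {
    other <- contact_pts(x$chains[[k]])
    d2min <- min(cross_dist2(main, other))
    if (d2min <= cutoff^2) keep <- c(keep, k)
  }
  if (length(keep) == 1 && length(x$chains) > 1)
    warning("subsystem contains only the main subunit")
  out <- assembly(x$chains[keep], symmetry = x$symmetry, center = x$center)
  attr(out, "subsystem") <- keep
  out
}

# squared cross-distance matrix between two n x 3 coordinate sets
cross_dist2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  outer(an, bn, "+") - 2 * A %*% t(B)
}

#' Parameter bounds for docking
#'
#' Lambda bounds are `+-(360/n)/2` in global mode and half that in local
#' mode; the Euler angles are bounded `+-40` degrees and `x` `+-5` Angstrom
#' around the center; `z` is `+-5` Angstrom around the center in local (and
#' recapitulation) mode and `[0, 1000]` Angstrom in global mode. Outside the
#' bounds a square-well penalty of depth 1e9 per violated parameter applies.
#'
#' @param sd a [symmetry_def()].
#' @param mode `"local"` or `"global"` (recapitulation uses local bounds).
#' @param center [rigid_body_params()] the bounds are centered on.
#' @return object of class `bounds_spec`: a 6 x 2 matrix of closed intervals
#'   plus `mode`, `setup_fold` and `penalty_depth` fields.
#' @export
make_bounds <- function(sd, mode = c("local", "global"),
                        center = rigid_body_params()) {
  mode <- match.arg(mode)
  n <- sd$setup_fold
  half_lam <- if (mode == "global") (360 / n) / 2 else (360 / n) / 4
  b <- matrix(NA_real_, 6, 2, dimnames = list(PARAM_NAMES, c("lo", "hi")))
  for (p in c("psi", "theta", "phi"))
    b[p, ] <- center[[p]] + c(-40, 40)
  b["x", ] <- center[["x"]] + c(-5, 5)
  b["lam", ] <- center[["lam"]] + c(-half_lam, half_lam)
  b["z", ] <- if (mode == "global") c(0, 1000) else center[["z"]] + c(-5, 5)
  structure(list(bounds = b, mode = mode, setup_fold = n,
                 penalty_depth = 1e9, center = center),
            class = "bounds_spec")
}

#' Square-well out-of-bounds penalty
#'
#' Adds the penalty depth (default 1e9) once per parameter outside its
#' closed interval; zero when all parameters are within bounds.
#'
#' @param params [rigid_body_params()].
#' @param bounds a [make_bounds()] object.
#' @return non-negative penalty.
#' @export
square_well_penalty <- function(params, bounds) {
  b <- bounds$bounds
  v <- sum(params[PARAM_NAMES] < b[, "lo"] | params[PARAM_NAMES] > b[, "hi"])
  v * bounds$penalty_depth
}

#' Orientation flip of a placement
#'
#' Returns the parameters of the placement related to the input by a
#' 180-degree turn about the global x axis through the subunit center of
#' mass (the two ways to put an oligomer into a cubic symmetry). Applying
#' the flip twice regenerates the original assembly.
#'
#' @param params [rigid_body_params()].
#' @return flipped [rigid_body_params()].
#' @export
flip_orientation <- function(params) {
  E <- euler_zyz(params[["psi"]], params[["theta"]], params[["phi"]])
  ang <- matrix_to_euler_zyz(rot_x(180) %*% E)
  rigid_body_params(psi = ang[["psi"]], theta = ang[["theta"]],
                    phi = ang[["phi"]], z = params[["z"]], x = params[["x"]],
                    lam = params[["lam"]])
}

# Rotations S_k relating chain 1 to chain k about the assembly center
# (assembly assumed centered at the origin).
chain_relations <- function(x) {
  ca1 <- chain_coords(x$chains[[1]], "CA")
  lapply(seq_along(x$chains), function(k) {
    if (k == 1) return(diag(3))
    kabsch(ca1, chain_coords(x$chains[[k]], "CA"))
  })
}

# Deduplicated fold axes (canonical sign) of an observed rotation set.
observed_fold_axes <- function(relations, n, tol = 2) {
  target <- 360 / n
  axes <- list()
  for (S in relations) {
    aa <- axis_angle(S)
    if (abs(aa$angle - target) < tol)
      axes[[length(axes) + 1]] <- aa$axis
  }
  if (!length(axes)) return(NULL)
  A <- do.call(rbind, lapply(axes, canonical_axis))
  A[!duplicated(round(A, 4)), , drop = FALSE]
}

# Rotation aligning an observed symmetry frame onto the oriented standard
# group frame. Candidates are scored by how well conjugation maps the
# observed chain relations into the standard rotation set.
align_to_standard <- function(relations, kind, setup_fold, com1) {
  g <- oriented_group(kind, setup_fold)
  n <- setup_fold
  m <- max(setdiff(GROUP_FOLDS[[kind]], n))
  setup_axes <- observed_fold_axes(relations, n)
  sec_axes <- observed_fold_axes(relations, m)
  if (is.null(setup_axes) || is.null(sec_axes))
    stop("could not identify fold axes; chains may not form ", kind,
         " symmetry")
  # observed setup axis: the one nearest the main-subunit COM direction
  com_hat <- com1 / sqrt(sum(com1^2))
  scores <- abs(setup_axes %*% com_hat)
  a_line <- setup_axes[which.max(scores), ]
  a_candidates <- list(a_line, -a_line)
  a_candidates <- Filter(function(a) sum(a * com_hat) > 0, a_candidates)
  # standard target: z plus the closest standard m-fold axis
  std_sec <- fold_axes(g, m)
  zdots <- round(std_sec[, 3], 6)
  b0 <- std_sec[which.max(zdots), ]
  ang0 <- acos(max(-1, min(1, b0[3])))
  best <- NULL
  for (a in a_candidates) {
    for (i in seq_len(nrow(sec_axes))) {
      for (sgn in c(1, -1)) {
        b <- sgn * sec_axes[i, ]
        ang <- acos(max(-1, min(1, sum(a * b))))
        if (abs(ang - ang0) > 0.2) next
        R <- frame_rotation(a, b, c(0, 0, 1), b0)
        err <- conjugation_error(relations, R, g)
        if (is.null(best) || err < best$err) best <- list(R = R, err = err)
      }
    }
  }
  if (is.null(best)) stop("could not align assembly onto the standard frame")
  best
}

# rotation mapping the frame spanned by (a, b) onto (a0, b0)
frame_rotation <- function(a, b, a0, b0) {
  gs <- function(u, v) {
    e1 <- u / sqrt(sum(u^2))
    w <- v - sum(v * e1) * e1
    e2 <- w / sqrt(sum(w^2))
    cbind(e1, e2, pracma_cross(e1, e2))
  }
  gs(a0, b0) %*% t(gs(a, b))
}

conjugation_error <- function(relations, R, g) {
  G <- g$rotations
  errs <- vapply(relations, function(S) {
    C <- R %*% S %*% t(R)
    min(vapply(G, function(M) sqrt(sum((C - M)^2)), 0))
  }, 0)
  max(errs)
}

#' Extract rigid-body parameters from a symmetric assembly
#'
#' Recovers the six placement parameters that regenerate the assembly via
#' [place_and_expand()]. The assembly is centered at the origin, its
#' symmetry frame is aligned onto the standard oriented group frame by
#' matching fold axes, and the parameters of the main subunit are read off;
#' `lam` is wrapped into `(-180/n, 180/n]`. The result is unique up to
#' group equivalence.
#'
#' @param x an [assembly()] with the full chain count for `kind`.
#' @param kind `"T"`, `"O"` or `"I"`.
#' @param setup_fold fold order of the setup axis.
#' @param subunit reference subunit defining the zero orientation; defaults
#'   to chain 1 of the assembly (in which case the Euler angles describe the
#'   orientation relative to that chain's own frame).
#' @return [rigid_body_params()]; the aligning rotation is attached as
#'   `attr(, "alignment")`.
#' @export
extract_params <- function(x, kind, setup_fold, subunit = NULL) {
  kind <- match.arg(kind, c("T", "O", "I"))
  g <- oriented_group(kind, setup_fold)
  if (length(x$chains) != g$order)
    stop("assembly has ", length(x$chains), " chains; ", kind,
         " requires ", g$order)
  # center the assembly
  allxyz <- do.call(rbind, lapply(x$chains, chain_coords))
  ctr <- colMeans(allxyz)
  xc <- x
  for (k in seq_along(xc$chains))
    xc$chains[[k]] <- transform_chain(xc$chains[[k]], diag(3), -ctr)
  # chains must be superposable copies of one subunit
  ca1 <- chain_coords(xc$chains[[1]], "CA")
  for (k in seq_along(xc$chains)[-1]) {
    cak <- chain_coords(xc$chains[[k]], "CA")
    if (nrow(cak) != nrow(ca1)) stop("chains differ in residue count")
    if (superpose(ca1, cak)$rmsd > 2)
      stop("chains are not superposable copies (CA RMSD > 2 A)")
  }
  relations <- chain_relations(xc)
  com1 <- chain_com(xc$chains[[1]])
  al <- align_to_standard(relations, kind, setup_fold, com1)
  R <- al$R
  ch1 <- transform_chain(xc$chains[[1]], R, c(0, 0, 0))
  p <- chain_com(ch1)
  zval <- p[3]
  xval <- sqrt(p[1]^2 + p[2]^2)
  lam_raw <- if (xval > 1e-6) rad2deg(atan2(p[2], p[1])) else 0
  lam <- wrap_angle(lam_raw, 360 / setup_fold)
  # orientation relative to the reference subunit
  ref <- if (is.null(subunit)) xc$chains[[1]] else subunit
  refca <- chain_coords(ref, "CA")
  refc <- sweep(refca, 2, colMeans(refca))
  obsca <- chain_coords(ch1, "CA")
  obsc <- sweep(obsca, 2, colMeans(obsca))
  M0 <- kabsch(refc, obsc)
  E <- rot_z(-lam_raw) %*% M0
  ang <- matrix_to_euler_zyz(E)
  out <- rigid_body_params(psi = ang[["psi"]], theta = ang[["theta"]],
                           phi = ang[["phi"]], z = unname(zval),
                           x = unname(xval), lam = lam)
  attr(out, "alignment") <- R
  attr(out, "alignment_error") <- al$err
  out
}

#' Write / read a symmetry definition file
#'
#' A small versioned structured-text format carrying the symmetry kind, the
#' setup fold, the six named rigid-body parameters and optional subsystem
#' chain indices.
#'
#' @param sd a [symmetry_def()] (with `params` set for writing).
#' @param path file path.
#' @return `read_symdef` returns a [symmetry_def()].
#' @export
write_symdef <- function(sd, path) {
  lines <- c("cubedock_symdef 1",
             paste("kind", sd$kind),
             paste("setup_fold", sd$setup_fold))
  if (!is.null(sd$params))
    lines <- c(lines, vapply(PARAM_NAMES, function(p)
      sprintf("%s %.6f", p, sd$params[[p]]), ""))
  if (!is.null(sd$subsystem))
    lines <- c(lines, paste("subsystem",
                            paste(sd$subsystem, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_symdef
#' @export
read_symdef <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "cubedock_symdef"))
    stop("not a cubedock symmetry definition file: ", path)
  kv <- strsplit(lines[-1], "\\s+")
  vals <- stats::setNames(lapply(kv, `[`, -1), vapply(kv, `[`, "", 1))
  params <- NULL
  if (all(PARAM_NAMES %in% names(vals))) {
    params <- rigid_body_params()
    for (p in PARAM_NAMES) params[[p]] <- as.numeric(vals[[p]][1])
  }
  subsystem <- if ("subsystem" %in% names(vals))
    as.integer(vals$subsystem) else NULL
  symmetry_def(vals$kind[1], as.integer(vals$setup_fold[1]), params,
               subsystem)
}
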