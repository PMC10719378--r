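# CloudContactScore: a fast backbone point-cloud score for finding
# clash-free, well-packed subunit orientations.
#
# A subunit is reduced to its surface backbone + CB atoms; interchain
# interactions are scored as a linear combination of a clash count, two
# backbone hydrogen-bond terms (short/long range) and a connection-density
# weighted CB-CB contact bonus.

KIND_CODE <- c(N = 0L, CA = 1L, C = 2L, O = 3L, CB = 4L)

# Lennard-Jones-like radii (Angstrom). CB is overridden to 1.5 A to allow
# the closer surface contacts the contact score rewards; SASA uses the
# unreduced element radii.
LJ_RADII <- c(N = 1.75, CA = 2.0, C = 2.0, O = 1.55, CB = 1.5)
ELEMENT_RADII <- c(C = 2.0, N = 1.75, O = 1.55, S = 1.8, H = 1.0)

#' CloudContactScore configuration
#'
#' All tunable constants of the point-cloud score. Defaults follow the
#' published description: residues with more than 20 A^2 SASA (or classified
#' as surface by the sidechain-neighbor-cone rule) are surface; two atoms
#' clash when their spheres overlap by more than 20 percent, except N-O
#' pairs (clash below 1.2 A, allowing hydrogen bonds) and CB atoms (radius
#' reduced to 1.5 A); CB-CB contacts count within 12 A, weighted by the
#' connection density `min(neighbors/20, 1)` of each CB.
#'
#' @param sasa_surface_threshold per-residue SASA above which a residue is
#'   surface (A^2).
#' @param overlap_fraction sphere overlap fraction defining a clash.
#' @param n_o_clash_distance clash distance for N-O pairs (A).
#' @param cb_radius reduced CB sphere radius (A).
#' @param cb_contact_cutoff CB-CB contact distance (A).
#' @param density_neighbor_cutoff neighbor distance for connection density (A).
#' @param density_denominator denominator of the density clamp.
#' @param clash_penalty score added per clash.
#' @param hb_window N...O distance window of the surrogate hydrogen bond (A).
#' @param sr_separation residue-separation boundary between short- and
#'   long-range hydrogen bonds.
#' @param term_weights weights of (clashes, hb_sr, hb_lr, cb contacts); the
#'   contact weight is applied with a negative sign (a bonus).
#' @param cone_half_angle,cone_length,cone_count sidechain-neighbor-cone
#'   burial classifier: a residue is surface if fewer than `cone_count`
#'   CA->CB vectors of other residues fall inside its cone.
#' @param probe_radius,sphere_points Shrake-Rupley SASA settings.
#' @return list of class `ccs_config`.
#' @export
ccs_config <- function(sasa_surface_threshold = 20,
                       overlap_fraction = 0.20,
                       n_o_clash_distance = 1.2,
                       cb_radius = 1.5,
                       cb_contact_cutoff = 12,
                       density_neighbor_cutoff = 12,
                       density_denominator = 20,
                       clash_penalty = 1000,
                       hb_window = c(1.9, 3.2),
                       sr_separation = 5,
                       term_weights = c(clash = 1, hb_sr = 1, hb_lr = 1,
                                        cb = 1),
                       cone_half_angle = 60,
                       cone_length = 10,
                       cone_count = 12,
                       probe_radius = 1.4,
                       sphere_points = 960) {
  cfg <- list(sasa_surface_threshold = sasa_surface_threshold,
              overlap_fraction = overlap_fraction,
              n_o_clash_distance = n_o_clash_distance,
              cb_radius = cb_radius,
              cb_contact_cutoff = cb_contact_cutoff,
              density_neighbor_cutoff = density_neighbor_cutoff,
              density_denominator = density_denominator,
              clash_penalty = clash_penalty,
              hb_window = hb_window,
              sr_separation = sr_separation,
              term_weights = term_weights,
              cone_half_angle = cone_half_angle,
              cone_length = cone_length,
              cone_count = cone_count,
              probe_radius = probe_radius,
              sphere_points = sphere_points)
  stopifnot(all(vapply(cfg[c(1:8, 10)], function(v) all(v > 0), TRUE)))
  class(cfg) <- "ccs_config"
  cfg
}

# kernel cfg vector shared by the C++ entry points (see src/kernels.cpp)
kernel_cfg <- function(ccs, energy = energy_config()) {
  c(ccs$overlap_fraction, ccs$n_o_clash_distance, ccs$cb_contact_cutoff,
    ccs$hb_window[1], ccs$hb_window[2],
    energy$lj_eps, energy$lj_cap, energy$lj_cutoff,
    energy$contact_switch[1], energy$contact_switch[2],
    ccs$sr_separation)
}

#' Connection density of a CB atom
#'
#' `min(count / denominator, 1)` with the published denominator of 20:
#' the burial weight used for CB-CB contact bonuses.
#'
#' @param n_internal_neighbors number of same-subunit CB atoms within the
#'   neighbor cutoff.
#' @param cfg a [ccs_config()].
#' @return density in `[0, 1]`.
#' @export
connection_density <- function(n_internal_neighbors, cfg = ccs_config()) {
  stopifnot(all(n_internal_neighbors >= 0))
  pmin(n_internal_neighbors / cfg$density_denominator, 1.0)
}

atom_radius_for_sasa <- function(atoms) {
  r <- ELEMENT_RADII[atoms$element]
  r[is.na(r)] <- 1.8
  unname(r)
}

# per-residue SASA (summed over atoms) of a chain
residue_sasa <- function(chain, cfg) {
  a <- chain$atoms
  s <- cpp_sasa(as.matrix(a[, c("x", "y", "z")]), atom_radius_for_sasa(a),
                cfg$probe_radius, as.integer(cfg$sphere_points))
  tapply(s, a$resno, sum)
}

# CB coordinate (CA for glycine) per residue, plus the CA->CB direction used
# by the burial cone (glycine gets an ideal pseudo-CB direction).
residue_cb_frame <- function(chain) {
  a <- chain$atoms
  resnos <- unique(a$resno)
  ca <- cb <- matrix(NA_real_, length(resnos), 3)
  for (i in seq_along(resnos)) {
    sel <- a$resno == resnos[i]
    ca[i, ] <- unlist(a[sel & a$atom == "CA", c("x", "y", "z")])
    if (any(sel & a$atom == "CB")) {
      cb[i, ] <- unlist(a[sel & a$atom == "CB", c("x", "y", "z")][1, ])
    } else {
      # glycine: pseudo-CB from the backbone frame
      n <- unlist(a[sel & a$atom == "N", c("x", "y", "z")])
      c_ <- unlist(a[sel & a$atom == "C", c("x", "y", "z")])
      b1 <- ca[i, ] - n; b2 <- ca[i, ] - c_
      d <- b1 + b2
      nrm <- pracma_cross(b1, b2)
      dir <- d / sqrt(sum(d^2)) + 0.5 * nrm / sqrt(sum(nrm^2))
      cb[i, ] <- ca[i, ] + 1.53 * dir / sqrt(sum(dir^2))
    }
  }
  list(resno = resnos, ca = ca, cb = cb)
}

# TRUE for residues classified as surface by the sidechain-neighbor cone.
cone_surface <- function(chain, cfg) {
  fr <- residue_cb_frame(chain)
  nres <- length(fr$resno)
  v <- fr$cb - fr$ca
  v <- v / sqrt(rowSums(v^2))
  counts <- integer(nres)
  cosmax <- cos(deg2rad(cfg$cone_half_angle))
  for (i in seq_len(nres)) {
    w <- sweep(fr$cb[-i, , drop = FALSE], 2, fr$ca[i, ])
    d <- sqrt(rowSums(w^2))
    inside <- d <= cfg$cone_length &
      (w %*% v[i, ]) / pmax(d, 1e-9) >= cosmax
    counts[i] <- sum(inside)
  }
  counts < cfg$cone_count
}

new_point_cloud <- function(coords, kind, radius, density, resi, odir, com,
                            n_res) {
  structure(list(coords = coords, kind = kind, radius = radius,
                 density = density, resi = resi, odir = odir, com = com,
                 n_res = n_res),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("<point_cloud>", nrow(x$coords), "points from", x$n_res, "residues\n")
  invisible(x)
}

#' Build the CloudContactScore point cloud of a subunit
#'
#' Surface residues are identified by per-residue SASA above the threshold
#' or by the sidechain-neighbor-cone classifier (logical OR); surface
#' non-glycine residues are reduced to alanine (atoms beyond CB dropped), a
#' second SASA pass removes fully buried atoms, and the remaining N, CA, C,
#' O and CB atoms become cloud points. Each CB point carries its connection
#' density; each O point carries its carbonyl direction for the surrogate
#' hydrogen bond.
#'
#' @param subunit a `chain_model` with a complete backbone.
#' @param cfg a [ccs_config()].
#' @param surface_only set `FALSE` to keep all residues and skip the SASA
#'   filtering (the representation used by the surrogate interface energy).
#' @return a `point_cloud`; coordinates are stored relative to the subunit
#'   center of mass (`$com`).
#' @export
build_point_cloud <- function(subunit, cfg = ccs_config(),
                              surface_only = TRUE) {
  a <- subunit$atoms
  if (nrow(a) == 0) stop("empty chain")
  com <- chain_com(subunit)
  resnos <- unique(a$resno)
  if (surface_only) {
    rs <- residue_sasa(subunit, cfg)
    surf_sasa <- rs > cfg$sasa_surface_threshold
    surf_cone <- cone_surface(subunit, cfg)
    surface <- surf_sasa | surf_cone
    surf_res <- resnos[surface]
    # reduce surface residues to alanine (drop sidechain beyond CB)
    keep <- !(a$resno %in% surf_res) |
      a$atom %in% c("N", "CA", "C", "O", "CB")
    red <- subunit
    red$atoms <- a[keep, ]
    s2 <- cpp_sasa(chain_coords(red), atom_radius_for_sasa(red$atoms),
                   cfg$probe_radius, as.integer(cfg$sphere_points))
    sel <- red$atoms$atom %in% names(KIND_CODE) & s2 > 0 &
      red$atoms$resno %in% surf_res
    pts <- red$atoms[sel, ]
  } else {
    pts <- a[a$atom %in% names(KIND_CODE), ]
  }
  if (nrow(pts) == 0) stop("point cloud is empty")
  # connection density against all CB atoms of the full-length subunit
  cb_all <- as.matrix(a[a$atom == "CB", c("x", "y", "z")])
  density <- numeric(nrow(pts))
  is_cb <- pts$atom == "CB"
  if (any(is_cb) && nrow(cb_all) > 1) {
    d2 <- cross_dist2(as.matrix(pts[is_cb, c("x", "y", "z")]), cb_all)
    counts <- rowSums(d2 <= cfg$density_neighbor_cutoff^2 & d2 > 1e-9)
    density[is_cb] <- connection_density(counts, cfg)
  }
  # carbonyl O directions (unit C -> O) for hydrogen-bond geometry
  odir <- matrix(0, nrow(pts), 3)
  is_o <- pts$atom == "O"
  for (i in which(is_o)) {
    csel <- a$resno == pts$resno[i] & a$atom == "C"
    cxyz <- unlist(a[csel, c("x", "y", "z")][1, ])
    v <- c(pts$x[i], pts$y[i], pts$z[i]) - cxyz
    odir[i, ] <- v / sqrt(sum(v^2))
  }
  radius <- unname(LJ_RADII[pts$atom])
  radius[pts$atom == "CB"] <- cfg$cb_radius
  coords <- sweep(as.matrix(pts[, c("x", "y", "z")]), 2, com)
  new_point_cloud(coords, unname(KIND_CODE[pts$atom]), radius, density,
                  as.integer(pts$resno), odir, com, length(resnos))
}

# absolute coordinates of a cloud under a rigid transform (R, t); the
# identity transform reproduces the cloud at its original position.
cloud_absolute <- function(cloud, R = diag(3), t = c(0, 0, 0)) {
  xyz <- sweep(cloud$coords %*% t(R), 2, -(as.vector(R %*% cloud$com) + t))
  od <- cloud$odir %*% t(R)
  list(xyz = xyz, odir = od)
}

pair_terms_clouds <- function(cloudA, transA, cloudB, transB, cfg, energy,
                              clash_only = FALSE) {
  A <- cloud_absolute(cloudA, transA$R, transA$t)
  B <- cloud_absolute(cloudB, transB$R, transB$t)
  cpp_pair_terms(A$xyz, cloudA$kind, cloudA$radius, cloudA$density,
                 cloudA$resi, A$odir,
                 B$xyz, cloudB$kind, cloudB$radius, cloudB$density,
                 cloudB$resi, B$odir,
                 kernel_cfg(cfg, energy), clash_only)
}

identity_transform <- function() list(R = diag(3), t = c(0, 0, 0))

#' Count interchain clashes of a cloud against partner copies
#'
#' Partners are rigid copies of the cloud generated by the given transforms;
#' each (main, partner) pair is counted once. A clash is a pair closer than
#' `(1 - overlap_fraction) * (r_i + r_j)`, except N-O pairs which clash
#' below the hydrogen-bond distance of 1.2 A.
#'
#' @param cloud a `point_cloud` (the main subunit, untransformed).
#' @param partner_transforms list of `list(R, t)` rigid transforms.
#' @param cfg a [ccs_config()].
#' @return integer clash count.
#' @export
count_clashes <- function(cloud, partner_transforms, cfg = ccs_config()) {
  total <- 0
  for (tr in partner_transforms) {
    v <- pair_terms_clouds(cloud, identity_transform(), cloud, tr, cfg,
                           energy_config())
    total <- total + v[1]
  }
  as.integer(total)
}

#' Surrogate backbone hydrogen-bond terms
#'
#' A smooth distance window on the N...O separation (sine-squared bump over
#' `hb_window`) attenuated by the squared cosine of the angle between the
#' carbonyl direction and the O -> N vector; negative is favourable. Pairs
#' with residue separation below `sr_separation` count as short range.
#'
#' @inheritParams count_clashes
#' @param transforms list of partner transforms as in [count_clashes()].
#' @return named vector `c(hb_sr, hb_lr)`.
#' @export
hbond_bb <- function(cloud, transforms, cfg = ccs_config()) {
  sr <- lr <- 0
  for (tr in transforms) {
    v <- pair_terms_clouds(cloud, identity_transform(), cloud, tr, cfg,
                           energy_config())
    sr <- sr + v[2]; lr <- lr + v[3]
  }
  c(hb_sr = sr, hb_lr = lr)
}

ccs_breakdown <- function(terms, cfg) {
  w <- cfg$term_weights
  total <- w[["clash"]] * cfg$clash_penalty * terms[1] +
    w[["hb_sr"]] * terms[2] + w[["hb_lr"]] * terms[3] -
    w[["cb"]] * terms[4]
  list(n_clashes = as.integer(terms[1]),
       hbond_sr_bb = terms[2],
       hbond_lr_bb = terms[3],
       n_cb_cb_interactions = terms[4],
       total = unname(total))
}

#' CloudContactScore of a cloud against partner copies
#'
#' Total score = `w_clash * penalty * n_clashes + w_hb * (hb_sr + hb_lr)
#' - w_cb * n_cb_cb_interactions`; lower is better. The CB contact term is
#' the connection-density weighted count of interchain CB-CB pairs within
#' the contact cutoff.
#'
#' @inheritParams hbond_bb
#' @return list with `n_clashes`, `hbond_sr_bb`, `hbond_lr_bb`,
#'   `n_cb_cb_interactions` and `total`.
#' @export
ccs_score <- function(cloud, transforms, cfg = ccs_config()) {
  terms <- c(0, 0, 0, 0, 0, 0)
  for (tr in transforms) {
    v <- pair_terms_clouds(cloud, identity_transform(), cloud, tr, cfg,
                           energy_config())
    terms <- terms + v
  }
  ccs_breakdown(terms, cfg)
}
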