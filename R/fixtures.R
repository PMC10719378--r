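# Synthetic-data generation: toy subunits with ideal backbone geometry,
# ideal cubic assemblies, fake predictor ensembles and run tables. These
# stand in for predictor outputs and deposited assemblies so that every
# other module can be exercised without downloads.

# Standard backbone internal coordinates (Angstrom / degrees)
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                cb = 1.53,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8, ang_n_ca_cb = 110.5)

# NeRF: place atom D given A-B-C, the B-C-D bond length/angle and the
# A-B-C-D dihedral (degrees).
nerf_place <- function(A, B, C, bond, angle, dihedral) {
  ang <- deg2rad(angle); dih <- -deg2rad(dihedral) # IUPAC torsion sign
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- pracma_cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an ideal toy subunit
#'
#' Constructs a poly-alanine chain with ideal backbone geometry from
#' phi/psi dihedrals: an alpha helix (phi = -57, psi = -47; 1.5 A rise per
#' residue) or a two-strand hairpin. Atoms N, CA, C, O and CB are present
#' for every residue (glycines, if requested, lack CB). Per-residue pLDDT
#' is written to the B-factor column. The subunit is returned centered on
#' its center of mass with its principal helix axis along z-ish (raw build
#' frame); placement orientation is the docking engine's job.
#'
#' @param n_res number of residues (>= 8).
#' @param motif `"helix"` or `"hairpin"`.
#' @param seed RNG seed for the optional coordinate noise.
#' @param noise Gaussian coordinate noise sd in Angstrom.
#' @param plddt scalar or per-residue vector written to the B-factors.
#' @param gly integer positions mutated to glycine (CB removed).
#' @param chain_id chain label.
#' @return a `chain_model`.
#' @export
make_toy_subunit <- function(n_res = 16, motif = c("helix", "hairpin"),
                             seed = 1, noise = 0, plddt = 95,
                             gly = integer(0), chain_id = "A") {
  if (n_res < 8) stop("toy subunit needs at least 8 residues")
  motif <- match.arg(motif)
  if (motif == "helix") {
    phi <- rep(-57, n_res); psi <- rep(-47, n_res)
  } else {
    # antiparallel hairpin: two strands joined by a type II'-like turn
    # (dihedrals chosen so the strands pair within contact distance along
    # their whole length without steric overlap)
    phi <- rep(-100, n_res); psi <- rep(125, n_res)
    mid <- floor(n_res / 2)
    phi[mid] <- 50; psi[mid] <- -105
    phi[mid + 1] <- -93; psi[mid + 1] <- 10
  }
  omega <- 180
  g <- BB_GEOM
  N <- CA <- C <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  C[1, ] <- CA[1, ] + g$ca_c *
    c(cos(deg2rad(180 - g$ang_n_ca_c)), sin(deg2rad(180 - g$ang_n_ca_c)), 0)
  for (i in seq_len(n_res - 1)) {
    N[i + 1, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], g$c_n, g$ang_ca_c_n,
                             psi[i])
    CA[i + 1, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1, ], g$n_ca,
                              g$ang_c_n_ca, omega)
    C[i + 1, ] <- nerf_place(C[i, ], N[i + 1, ], CA[i + 1, ], g$ca_c,
                             g$ang_n_ca_c, phi[i + 1])
  }
  O <- matrix(NA_real_, n_res, 3)
  for (i in seq_len(n_res)) {
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], g$c_o, g$ang_ca_c_o,
                         psi[i] + 180)
  }
  CB <- matrix(NA_real_, n_res, 3)
  for (i in seq_len(n_res)) {
    CB[i, ] <- nerf_place(C[i, ], N[i, ], CA[i, ], g$cb, g$ang_n_ca_cb,
                          -122.5)
  }
  if (length(plddt) == 1) plddt <- rep(plddt, n_res)
  stopifnot(length(plddt) == n_res)
  rows <- list()
  for (i in seq_len(n_res)) {
    is_gly <- i %in% gly
    resname <- if (is_gly) "GLY" else "ALA"
    atoms <- rbind(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ])
    if (!is_gly) atoms <- rbind(atoms, CB = CB[i, ])
    elems <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")
    for (nm in rownames(atoms)) {
      rows[[length(rows) + 1]] <- data.frame(
        atom = nm, element = elems[[nm]], resno = i, resname = resname,
        x = atoms[nm, 1], y = atoms[nm, 2], z = atoms[nm, 3],
        bfactor = plddt[i], occupancy = 1, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  if (noise > 0) {
    withr_seed <- function(expr) {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      expr
    }
    df[, c("x", "y", "z")] <- withr_seed(
      df[, c("x", "y", "z")] + matrix(stats::rnorm(nrow(df) * 3, 0, noise),
                                      ncol = 3))
  }
  ch <- chain_model(chain_id, df)
  # center on the COM so the build frame is reproducible
  transform_chain(ch, diag(3), -chain_com(ch))
}

# Engineered starting orientations per (kind, setup_fold): chosen once so
# that sliding the helix bundle to contact gives 10-50 interchain CB
# contacts per fold and a genuine energy funnel around the minimum.
TOY_START_PARAMS <- list(
  T_2 = c(psi = 10, theta = 15, phi = 30, x = 5.5, lam = 5),
  T_3 = c(psi = 10, theta = 15, phi = 20, x = 6.5, lam = 8),
  O_2 = c(psi = 12, theta = 15, phi = -20, x = 5.5, lam = 5),
  O_3 = c(psi = 10, theta = 18, phi = 25, x = 6.5, lam = 8),
  O_4 = c(psi = 12, theta = 15, phi = 30, x = 7.0, lam = 6),
  I_2 = c(psi = 12, theta = 18, phi = -25, x = 5.5, lam = 5),
  I_3 = c(psi = 10, theta = 15, phi = 20, x = 6.5, lam = 8),
  I_5 = c(psi = 12, theta = 12, phi = 25, x = 8.0, lam = 5))

# Deterministic toy native parameters: start from the engineered
# orientation far out on the setup axis, slide into contact and minimize
# the surrogate interface energy to the nearest local optimum.
toy_native_params <- function(kind, setup_fold, subunit,
                              ccs_cfg = ccs_config(),
                              energy_cfg = energy_config()) {
  key <- paste("native", kind, setup_fold, n_residues(subunit),
               nrow(subunit$atoms), sep = "_")
  if (!is.null(.cubedock_env[[key]])) return(.cubedock_env[[key]])
  sd <- symmetry_def(kind, setup_fold)
  ctx <- dock_context(subunit, sd, ccs_cfg, energy_cfg)
  sp <- TOY_START_PARAMS[[paste(kind, setup_fold, sep = "_")]]
  p <- rigid_body_params(psi = sp[["psi"]], theta = sp[["theta"]],
                         phi = sp[["phi"]], z = 60, x = sp[["x"]],
                         lam = sp[["lam"]])
  step <- 0.3
  # inflate the setup-axis ring until it is clash-free (ring geometry is
  # independent of z at large z)
  tries <- 0
  while (ctx_has_clash(ctx, p) && tries < 100) {
    p[["x"]] <- p[["x"]] + step
    tries <- tries + 1
  }
  if (ctx_has_clash(ctx, p))
    stop("could not find a clash-free ring for ", kind, " ", setup_fold)
  # slide in along the setup axis until first clash, then step back
  while (p[["z"]] > 0) {
    trial <- p; trial[["z"]] <- p[["z"]] - step
    if (ctx_has_clash(ctx, trial)) break
    p <- trial
  }
  # bounded local minimization of the interface score
  polish <- function(p, half) {
    lo <- p[PARAM_NAMES] - half
    hi <- p[PARAM_NAMES] + half
    lo[["x"]] <- max(lo[["x"]], 0.5); lo[["z"]] <- max(lo[["z"]], 0.5)
    opt <- stats::optim(p[PARAM_NAMES],
                        function(v) ctx_iscore(ctx,
                                               stats::setNames(v, PARAM_NAMES)),
                        method = "L-BFGS-B", lower = lo, upper = hi,
                        control = list(maxit = 200))
    out <- rigid_body_params()
    out[PARAM_NAMES] <- opt$par
    out
  }
  p <- polish(p, c(15, 15, 15, 4, 3, 15))
  # settle into the reproducible deep optimum of the surrogate energy:
  # repeat deterministic memetic runs, re-centered on the best basin found,
  # until the basin is stable, then polish locally
  lam_half <- (360 / setup_fold) / 4
  best_iscore <- ctx_iscore(ctx, p)
  for (it in 1:4) {
    run_cfg <- de_config(population_size = 20, generations = 15,
                         seed = 917 + it,
                         recap_ranges = c(psi = 10, theta = 10, phi = 10,
                                          z = 3, x = 3, lam = lam_half))
    sdp <- symmetry_def(kind, setup_fold, params = p)
    res <- run_docking(subunit, sdp, "recapitulate", run_cfg)
    cand <- polish(res$best$params, c(3, 3, 3, 1, 1, 3))
    cand_iscore <- ctx_iscore(ctx, cand)
    if (cand_iscore < best_iscore - 0.5) {
      p <- cand; best_iscore <- cand_iscore
    } else break
  }
  # lambda is periodic in 360/n up to a group element: store the canonical
  # representative (the expanded assembly is unchanged)
  p[["lam"]] <- wrap_angle(p[["lam"]], 360 / setup_fold)
  .cubedock_env[[key]] <- p
  p
}

#' Build an ideal toy cubic assembly
#'
#' Expands a toy subunit into a full clash-free cubic assembly that serves
#' as a synthetic native structure. With `params = NULL` the generator
#' derives deterministic parameters by sliding an engineered orientation
#' into contact along the setup axis and relaxing it to the nearest
#' surrogate-energy optimum, so the returned parameters are a genuine local
#' minimum of the docking objective.
#'
#' @param kind `"T"`, `"O"` or `"I"`.
#' @param fold setup fold order.
#' @param subunit a `chain_model`; default 16-residue helix.
#' @param params optional [rigid_body_params()]; validated to be clash-free.
#' @return list with `assembly`, `sd` (symmetry definition with parameters
#'   and subsystem indices) and `params`.
#' @export
make_ideal_assembly <- function(kind, fold, subunit = NULL, params = NULL) {
  if (is.null(subunit)) subunit <- make_toy_subunit()
  if (is.null(params)) params <- toy_native_params(kind, fold, subunit)
  sd <- symmetry_def(kind, fold, params = params)
  ctx <- dock_context(subunit, sd)
  terms <- placement_terms(ctx, params, ccs = TRUE)
  if (terms[1] > 0)
    stop("assembly parameters produce ", terms[1], " interchain clashes")
  asm <- place_and_expand(subunit, params, sd)
  sub <- build_subsystem(asm, sd)
  sd$subsystem <- attr(sub, "subsystem")
  list(assembly = asm, sd = sd, params = params, subunit = subunit)
}

#' Build an ideal Cn oligomer
#'
#' Places a subunit with the usual six parameters and expands it through
#' the cyclic group about z only - the shape of a single oligomeric
#' subcomponent prediction.
#'
#' @param subunit a `chain_model`.
#' @param n cyclic order.
#' @param params [rigid_body_params()].
#' @return an [assembly()] with `n` chains.
#' @export
make_cn_oligomer <- function(subunit, n, params) {
  pt <- placement_transform(params)
  com <- chain_com(subunit)
  xyz0 <- sweep(chain_coords(subunit), 2, com)
  chains <- vector("list", n)
  for (k in seq_len(n)) {
    G <- rot_z((k - 1) * 360 / n)
    R <- G %*% pt$R
    t <- as.vector(G %*% pt$t)
    ch <- subunit
    moved <- sweep(xyz0 %*% t(R), 2, -t)
    ch$atoms$x <- moved[, 1]; ch$atoms$y <- moved[, 2]; ch$atoms$z <- moved[, 3]
    ch$chain_id <- CHAIN_ID_POOL[k]
    chains[[k]] <- ch
  }
  assembly(chains)
}

#' Generate a fake predictor ensemble
#'
#' Emulates a set of structure predictions of one subunit: each model is the
#' subunit plus small Gaussian noise, with optionally disordered (randomly
#' displaced, low-confidence) terminal residues, per-residue pLDDT written
#' to the B-factors, and a score manifest with per-model mean pLDDT and
#' pTM/ipTM values.
#'
#' @param subunit a `chain_model`.
#' @param n_models number of models.
#' @param plddt_profile per-residue pLDDT vector (length = subunit length).
#' @param disorder_n_term,disorder_c_term number of terminal residues to
#'   randomize.
#' @param seed RNG seed.
#' @param noise core coordinate noise sd (A).
#' @param ptm,iptm scalars or per-model vectors for the manifest; set
#'   `iptm = NA` for monomer-style records.
#' @return list with `models` (list of `chain_model`) and `manifest`.
#' @export
make_synthetic_ensemble <- function(subunit, n_models = 10,
                                    plddt_profile = NULL,
                                    disorder_n_term = 0, disorder_c_term = 0,
                                    seed = 1, noise = 0.15,
                                    ptm = 0.92, iptm = 0.95) {
  nres <- n_residues(subunit)
  if (is.null(plddt_profile)) plddt_profile <- rep(95, nres)
  stopifnot(length(plddt_profile) == nres)
  if (length(ptm) == 1) ptm <- rep(ptm, n_models)
  if (length(iptm) == 1) iptm <- rep(iptm, n_models)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  resnos <- unique(subunit$atoms$resno)
  dis_res <- c(utils::head(resnos, disorder_n_term),
               utils::tail(resnos, disorder_c_term))
  models <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    ch <- subunit
    a <- ch$atoms
    jitter <- matrix(stats::rnorm(nrow(a) * 3, 0, noise), ncol = 3)
    a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] + jitter
    # disordered termini: displace whole residues by a random walk
    for (r in dis_res) {
      k <- which(resnos == r)
      amp <- 1.5 * min(k, length(resnos) - k + 1)
      shift <- stats::rnorm(3, 0, amp)
      sel <- a$resno == r
      a[sel, c("x", "y", "z")] <- a[sel, c("x", "y", "z")] +
        rep(shift, each = sum(sel))
    }
    a$bfactor <- plddt_profile[match(a$resno, resnos)]
    ch$atoms <- a
    models[[m]] <- ch
  }
  manifest <- data.frame(
    model_id = sprintf("model_%03d.pdb", seq_len(n_models)),
    mean_plddt = rep(mean(plddt_profile), n_models),
    ptm = ptm, iptm = iptm, stringsAsFactors = FALSE)
  list(models = models, manifest = manifest)
}

#' Generate a synthetic docking-run table
#'
#' A table of final lowest-energy RMSD values for `n_runs` independent runs,
#' of which `n_success` land at `rmsd_low` (below the success threshold) and
#' the rest at `rmsd_high`, in shuffled order. Feeds the success-probability
#' resampling estimator.
#'
#' @param n_runs,n_success counts with `n_success <= n_runs`.
#' @param rmsd_low,rmsd_high representative RMSD values (A).
#' @param seed RNG seed for the shuffle.
#' @return data frame with columns `run` and `rmsd`.
#' @export
make_runs_table <- function(n_runs, n_success, rmsd_low = 1, rmsd_high = 20,
                            seed = 1) {
  stopifnot(n_success <= n_runs)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  rmsd <- sample(c(rep(rmsd_low, n_success),
                   rep(rmsd_high, n_runs - n_success)))
  data.frame(run = seq_len(n_runs), rmsd = rmsd)
}
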