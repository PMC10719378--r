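# Ensemble preparation: turn raw predictor outputs into docking-ready,
# equal-length, non-redundant subunit ensembles, and extract starting
# rigid-body estimates from oligomer predictions.

#' Ensemble-preparation configuration
#'
#' Thresholds follow the published protocol: models kept at mean pLDDT >= 90
#' (and model confidence >= 0.9 for multimer predictions); termini trimmed
#' until average pLDDT >= 90, connectivity >= 70 percent and secondary
#' structure propensity >= 70 percent; redundancy pruned at 0.1 A pairwise
#' CA RMSD, relaxed in 0.005 A steps (up to 18) if fewer than 50 models
#' survive.
#'
#' @param plddt_min minimum mean pLDDT.
#' @param confidence_min minimum multimer model confidence
#'   (`0.8 ipTM + 0.2 pTM`).
#' @param avg_plddt_threshold per-residue average pLDDT trim threshold.
#' @param connectivity_threshold,ss_threshold trim thresholds in percent.
#' @param contact_distance residue-contact distance for connectivity (A).
#' @param sequence_separation minimum residue separation for connectivity.
#' @param redundancy_rmsd initial pruning threshold (A).
#' @param redundancy_step,redundancy_max_steps threshold relaxation.
#' @param min_ensemble target minimum ensemble size.
#' @return list of class `ensemble_config`.
#' @export
ensemble_config <- function(plddt_min = 90, confidence_min = 0.9,
                            avg_plddt_threshold = 90,
                            connectivity_threshold = 70, ss_threshold = 70,
                            contact_distance = 8, sequence_separation = 10,
                            redundancy_rmsd = 0.1, redundancy_step = 0.005,
                            redundancy_max_steps = 18, min_ensemble = 50) {
  structure(list(plddt_min = plddt_min, confidence_min = confidence_min,
                 avg_plddt_threshold = avg_plddt_threshold,
                 connectivity_threshold = connectivity_threshold,
                 ss_threshold = ss_threshold,
                 contact_distance = contact_distance,
                 sequence_separation = sequence_separation,
                 redundancy_rmsd = redundancy_rmsd,
                 redundancy_step = redundancy_step,
                 redundancy_max_steps = redundancy_max_steps,
                 min_ensemble = min_ensemble),
            class = "ensemble_config")
}

#' Multimer model confidence score
#'
#' `0.8 * ipTM + 0.2 * pTM`, the composite confidence reported by multimer
#' structure predictors.
#'
#' @param ptm,iptm confidence scores in `[0, 1]`.
#' @return the model confidence in `[0, 1]`.
#' @export
model_confidence <- function(ptm, iptm) {
  if (any(ptm < 0 | ptm > 1) || any(iptm < 0 | iptm > 1))
    stop("ptm and iptm must be in [0, 1]")
  0.8 * iptm + 0.2 * ptm
}

#' Filter predictor models by confidence
#'
#' Monomer predictions (no ipTM) are kept at mean pLDDT >= `plddt_min`;
#' multimer predictions additionally require a model confidence of at least
#' `confidence_min`.
#'
#' @param models named list of `chain_model` objects; names must appear in
#'   the manifest.
#' @param manifest data frame as from [read_manifest()].
#' @param cfg an [ensemble_config()].
#' @return the kept subset of `models` (possibly empty, with a warning).
#' @export
filter_by_confidence <- function(models, manifest, cfg = ensemble_config()) {
  ids <- names(models)
  if (is.null(ids)) stop("models must be a named list")
  keep <- logical(length(models))
  for (i in seq_along(models)) {
    rec <- manifest[manifest$model_id == ids[i], ]
    if (nrow(rec) == 0) stop("no manifest record for model ", ids[i])
    ok <- rec$mean_plddt[1] >= cfg$plddt_min
    if (!is.na(rec$iptm[1]))
      ok <- ok && model_confidence(rec$ptm[1], rec$iptm[1]) >= cfg$confidence_min
    keep[i] <- ok
  }
  if (!any(keep)) warning("no models pass the confidence filters")
  models[keep]
}

# phi/psi backbone dihedrals of a chain (degrees; NA at the termini)
backbone_dihedrals <- function(chain) {
  a <- chain$atoms
  resnos <- unique(a$resno)
  get <- function(r, nm) unlist(a[a$resno == r & a$atom == nm,
                                  c("x", "y", "z")][1, ])
  dihedral <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
    m <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
    rad2deg(atan2(sum(m * n2), sum(n1 * n2)))
  }
  n <- length(resnos)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1)
      phi[i] <- dihedral(get(resnos[i - 1], "C"), get(resnos[i], "N"),
                         get(resnos[i], "CA"), get(resnos[i], "C"))
    if (i < n)
      psi[i] <- dihedral(get(resnos[i], "N"), get(resnos[i], "CA"),
                         get(resnos[i], "C"), get(resnos[i + 1], "N"))
  }
  data.frame(resno = resnos, phi = phi, psi = psi)
}

# Dihedral-window secondary-structure assignment with 3-residue majority
# smoothing; returns TRUE where the residue is helix or strand.
assign_ss <- function(chain) {
  d <- backbone_dihedrals(chain)
  helix <- !is.na(d$phi) & !is.na(d$psi) &
    d$phi >= -100 & d$phi <= -30 & d$psi >= -80 & d$psi <= -5
  strand <- !is.na(d$phi) & !is.na(d$psi) &
    d$phi >= -180 & d$phi <= -80 &
    ((d$psi >= 80 & d$psi <= 180) | (d$psi >= -180 & d$psi <= -170))
  ss <- helix | strand
  # termini inherit their neighbor's state before smoothing
  if (length(ss) > 2) {
    ss[1] <- ss[2]; ss[length(ss)] <- ss[length(ss) - 1]
  }
  smoothed <- ss
  for (i in seq_along(ss)) {
    win <- ss[max(1, i - 1):min(length(ss), i + 1)]
    smoothed[i] <- mean(win) >= 0.5
  }
  smoothed
}

#' Per-residue ensemble metric profiles
#'
#' For an equal-length model ensemble: the average per-residue pLDDT (from
#' the B-factors), the percentage of models in which the residue is
#' "connected" (has a CA within the contact distance of some residue at
#' least `sequence_separation` positions away), and the percentage of
#' models in which it is assigned helix or strand.
#'
#' @param ensemble list of equal-length `chain_model` objects.
#' @param cfg an [ensemble_config()].
#' @return data frame with columns `resno`, `avg_plddt`,
#'   `connectivity_pct`, `ss_pct`.
#' @export
residue_metric_profiles <- function(ensemble, cfg = ensemble_config()) {
  if (!length(ensemble)) stop("empty ensemble")
  nres <- vapply(ensemble, n_residues, 0L)
  if (length(unique(nres)) != 1) stop("models differ in length")
  n <- nres[1]
  plddt <- conn <- ss <- matrix(0, length(ensemble), n)
  for (m in seq_along(ensemble)) {
    ch <- ensemble[[m]]
    a <- ch$atoms
    resnos <- unique(a$resno)
    ca <- chain_coords(ch, "CA")
    plddt[m, ] <- vapply(resnos, function(r)
      mean(a$bfactor[a$resno == r]), 0)
    d2 <- cross_dist2(ca, ca)
    sep <- abs(outer(seq_len(n), seq_len(n), "-")) >= cfg$sequence_separation
    conn[m, ] <- apply(d2 <= cfg$contact_distance^2 & sep, 1, any)
    ss[m, ] <- assign_ss(ch)
  }
  data.frame(resno = unique(ensemble[[1]]$atoms$resno),
             avg_plddt = colMeans(plddt),
             connectivity_pct = 100 * colMeans(conn),
             ss_pct = 100 * colMeans(ss))
}

# first index (scanning the given direction) where all metrics have crossed
# their thresholds; implements the max-of-first-crossings rule
trim_cut <- function(metrics, cfg, from_start = TRUE) {
  idx <- if (from_start) seq_len(nrow(metrics)) else rev(seq_len(nrow(metrics)))
  pass <- cbind(metrics$avg_plddt[idx] >= cfg$avg_plddt_threshold,
                metrics$connectivity_pct[idx] >= cfg$connectivity_threshold,
                metrics$ss_pct[idx] >= cfg$ss_threshold)
  firsts <- apply(pass, 2, function(v) {
    w <- which(v)
    if (!length(w)) NA_integer_ else w[1]
  })
  if (any(is.na(firsts)))
    stop("a trimming metric never reaches its threshold")
  max(firsts)
}

#' Trim disordered termini from an ensemble
#'
#' Scanning inward from each terminus, finds for each metric the first
#' residue meeting its threshold; the cut position is the innermost of the
#' three (the last threshold to be crossed) and the identical cut is
#' applied to every model so all final lengths agree.
#'
#' @param ensemble list of equal-length `chain_model` objects.
#' @param metrics data frame from [residue_metric_profiles()].
#' @param cfg an [ensemble_config()].
#' @return list with `ensemble` (trimmed models), `n_cut`, `c_cut`.
#' @export
trim_termini <- function(ensemble, metrics = NULL,
                         cfg = ensemble_config()) {
  if (is.null(metrics)) metrics <- residue_metric_profiles(ensemble, cfg)
  n <- nrow(metrics)
  n_first <- trim_cut(metrics, cfg, TRUE)
  c_first <- trim_cut(metrics, cfg, FALSE)
  if (n_first > n - c_first + 1) stop("trimming removes every residue")
  keep <- metrics$resno[n_first:(n - c_first + 1)]
  out <- lapply(ensemble, function(ch) {
    ch$atoms <- ch$atoms[ch$atoms$resno %in% keep, ]
    ch
  })
  list(ensemble = out, n_cut = n_first - 1L, c_cut = c_first - 1L)
}

pairwise_ca_rmsd <- function(ensemble) {
  n <- length(ensemble)
  cas <- lapply(ensemble, chain_coords, atoms = "CA")
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    M[i, j] <- M[j, i] <- superpose(cas[[i]], cas[[j]])$rmsd
  M
}

#' Prune structurally redundant models
#'
#' Greedily removes, in ascending-RMSD order, the worse-scored member of
#' every model pair with CA RMSD (after optimal superposition) below the
#' threshold. If fewer than `min_ensemble` models survive, pruning restarts
#' with the threshold lowered by `redundancy_step`, up to
#' `redundancy_max_steps` times.
#'
#' @param ensemble list of `chain_model` objects (equal length).
#' @param scores numeric vector of per-model prediction scores (higher is
#'   better); defaults to equal scores.
#' @param cfg an [ensemble_config()].
#' @return list with `ensemble`, `kept` (indices) and `threshold` used.
#' @export
prune_redundant <- function(ensemble, scores = NULL,
                            cfg = ensemble_config()) {
  n <- length(ensemble)
  if (is.null(scores)) scores <- rep(0, n)
  stopifnot(length(scores) == n)
  if (n < 2)
    return(list(ensemble = ensemble, kept = seq_len(n),
                threshold = cfg$redundancy_rmsd))
  M <- pairwise_ca_rmsd(ensemble)
  run_prune <- function(thr) {
    alive <- rep(TRUE, n)
    pairs <- which(upper.tri(M) & M < thr, arr.ind = TRUE)
    if (nrow(pairs)) {
      ord <- order(M[pairs])
      for (k in ord) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        if (!alive[i] || !alive[j]) next
        drop <- if (scores[i] >= scores[j]) j else i
        alive[drop] <- FALSE
      }
    }
    alive
  }
  thr <- cfg$redundancy_rmsd
  alive <- run_prune(thr)
  steps <- 0
  while (sum(alive) < cfg$min_ensemble && steps < cfg$redundancy_max_steps) {
    thr <- thr - cfg$redundancy_step
    steps <- steps + 1
    if (thr <= 0) break
    alive <- run_prune(thr)
  }
  kept <- which(alive)
  list(ensemble = ensemble[kept], kept = kept, threshold = thr)
}

#' Extract starting rigid-body estimates from a Cn oligomer
#'
#' Computes the cyclic symmetry axis from the rotation relating consecutive
#' chains (which must be within 10 degrees of `360/n`), aligns it onto the
#' global fold axis and reads off the subunit orientation (`psi`, `theta`,
#' `phi`) and radial offset `x`; `z` and `lam` are left free. Of the two
#' antiparallel axis directions the one giving the smaller `theta` is
#' chosen (the inherent two-fold orientation ambiguity of an isolated
#' oligomer is resolved during global docking).
#'
#' @param oligomer an [assembly()] with `n` chains.
#' @param kind cubic symmetry kind the estimates will be used in (recorded).
#' @param n fold order of the oligomer.
#' @param subunit reference subunit defining the zero orientation; defaults
#'   to chain 1 of the oligomer (the per-model subunit the estimates are
#'   meant to be used with).
#' @return [rigid_body_params()] with `z = 0`, `lam = 0`; the inter-chain
#'   rotation angle is attached as `attr(, "cn_angle")` and the per-model
#'   subunit as `attr(, "subunit")`.
#' @export
extract_oligomer_params <- function(oligomer, kind, n, subunit = NULL) {
  if (length(oligomer$chains) < 2)
    stop("oligomer parameter extraction needs at least 2 chains")
  if (length(oligomer$chains) != n)
    stop("oligomer has ", length(oligomer$chains), " chains, expected ", n)
  ca1 <- chain_coords(oligomer$chains[[1]], "CA")
  ca2 <- chain_coords(oligomer$chains[[2]], "CA")
  sp <- superpose(ca1, ca2)
  aa <- axis_angle(sp$R)
  if (abs(aa$angle - 360 / n) > 10)
    stop("chains are not Cn-symmetric: inter-chain rotation ",
         round(aa$angle, 1), " degrees, expected ", round(360 / n, 1))
  axis <- aa$axis
  # a point on the rotation axis: solve (I - R) q = t in the plane normal
  # to the axis
  A <- diag(3) - sp$R
  q <- tryCatch(qr.solve(A + 1e-9 * (axis %o% axis), sp$t),
                error = function(e) c(0, 0, 0))
  q <- q - sum(q * axis) * axis + sum(chain_com(oligomer$chains[[1]]) * axis) * axis
  best <- NULL
  for (sgn in c(1, -1)) {
    a <- sgn * axis
    z <- c(0, 0, 1)
    R <- if (sum(a * z) > 1 - 1e-12) diag(3)
         else if (sum(a * z) < -1 + 1e-12) rot_x(180)
         else rot_axis(pracma_cross(a, z),
                       rad2deg(acos(max(-1, min(1, sum(a * z))))))
    com <- as.vector(R %*% (chain_com(oligomer$chains[[1]]) - q))
    xv <- sqrt(com[1]^2 + com[2]^2)
    azim <- if (xv > 1e-9) rad2deg(atan2(com[2], com[1])) else 0
    ref_ca <- if (is.null(subunit)) ca1 else chain_coords(subunit, "CA")
    refc <- sweep(ref_ca, 2, colMeans(ref_ca))
    moved <- chain_coords(transform_chain(oligomer$chains[[1]], R,
                                          -as.vector(R %*% q)), "CA")
    M0 <- kabsch(refc, sweep(moved, 2, colMeans(moved)))
    E <- rot_z(-azim) %*% M0
    ang <- matrix_to_euler_zyz(E)
    cand <- rigid_body_params(psi = ang[["psi"]], theta = ang[["theta"]],
                              phi = ang[["phi"]], z = 0, x = xv, lam = 0)
    if (is.null(best) || abs(cand[["theta"]]) < abs(best[["theta"]]))
      best <- cand
  }
  attr(best, "cn_angle") <- aa$angle
  attr(best, "subunit") <- oligomer$chains[[1]]
  best
}

#' Prepare a docking ensemble from predictor models
#'
#' The full preparation pipeline: confidence filtering, terminal trimming
#' and redundancy pruning, with a provenance table recording what was kept.
#'
#' @param models named list of `chain_model` objects.
#' @param manifest data frame as from [read_manifest()].
#' @param cfg an [ensemble_config()].
#' @return list with `ensemble`, `provenance` (data frame), `n_cut`,
#'   `c_cut` and the pruning `threshold`.
#' @export
prepare_ensemble <- function(models, manifest, cfg = ensemble_config()) {
  kept <- filter_by_confidence(models, manifest, cfg)
  if (!length(kept))
    return(list(ensemble = list(),
                provenance = data.frame(model_id = names(models),
                                        stage = "confidence",
                                        kept = FALSE)))
  trimmed <- trim_termini(kept, cfg = cfg)
  scores <- manifest$mean_plddt[match(names(kept), manifest$model_id)]
  pruned <- prune_redundant(trimmed$ensemble, scores, cfg)
  final_ids <- names(kept)[pruned$kept]
  prov <- data.frame(model_id = names(models),
                     passed_confidence = names(models) %in% names(kept),
                     kept_final = names(models) %in% final_ids)
  list(ensemble = pruned$ensemble, provenance = prov,
       n_cut = trimmed$n_cut, c_cut = trimmed$c_cut,
       threshold = pruned$threshold)
}
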