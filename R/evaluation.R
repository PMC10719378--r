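# Symmetry-aware model quality metrics: symmetric RMSD, DockQ per
# interface, buried-surface-weighted pairwise DockQ, a simplified assembly
# TM-score, quality classification, and the run-resampling success
# estimator.

# DockQ internal constants (from the DockQ literature, declared here)
DOCKQ_FNAT_CUTOFF <- 5      # native-contact heavy-atom distance (A)
DOCKQ_IFACE_CUTOFF <- 10    # interface-residue definition (A)
DOCKQ_IRMS_SCALE <- 1.5
DOCKQ_LRMS_SCALE <- 8.5
DOCKQ_ACCEPTABLE <- 0.23
DOCKQ_MEDIUM <- 0.49
DOCKQ_HIGH <- 0.80

# chain permutations induced by the k-th power of the setup-fold rotation:
# perm[j] = m such that G_m = Rz(k 360/n) G_j
setup_fold_permutations <- function(kind, setup_fold) {
  g <- oriented_group(kind, setup_fold)
  n <- setup_fold
  K <- g$order
  find_elem <- function(M) {
    for (m in seq_len(K))
      if (sqrt(sum((g$rotations[[m]] - M)^2)) < 1e-6) return(m)
    stop("rotation not found in group")
  }
  lapply(seq_len(n) - 1, function(k) {
    Rk <- rot_z(k * 360 / n)
    vapply(seq_len(K), function(j) find_elem(Rk %*% g$rotations[[j]]), 0L)
  })
}

# permutations induced by every group element (used for TM-score mappings)
group_permutations <- function(kind, setup_fold) {
  g <- oriented_group(kind, setup_fold)
  K <- g$order
  keys <- vapply(g$rotations, num_key, "", digits = 5)
  lookup <- stats::setNames(seq_len(K), keys)
  lapply(seq_len(K), function(i) {
    vapply(seq_len(K), function(j) {
      M <- g$rotations[[i]] %*% g$rotations[[j]]
      m <- lookup[[num_key(M, 5)]]
      if (is.null(m)) stop("group not closed under composition")
      m
    }, 0L)
  })
}

#' Symmetric RMSD between two assemblies
#'
#' CA RMSD after optimal superposition, minimized over the `n` symmetry
#' equivalent chain assignments obtained by rotating around the setup fold
#' (for an icosahedral structure with a 5-fold setup: 0, 72, 144, 216 and
#' 288 degrees). Chains are assumed to correspond index-wise up to that
#' rotation, as they do for assemblies generated by [place_and_expand()].
#'
#' @param model,native [assembly()] objects with equal chain/residue counts.
#' @param kind `"T"`, `"O"` or `"I"`.
#' @param setup_fold fold order used for the equivalent configurations.
#' @param chains optional chain indices to compare (e.g. a subsystem);
#'   default all chains.
#' @return minimum RMSD in Angstrom.
#' @export
symmetric_rmsd <- function(model, native, kind, setup_fold, chains = NULL) {
  if (length(model$chains) != length(native$chains))
    stop("model and native differ in chain count")
  if (is.null(chains)) chains <- seq_along(model$chains)
  perms <- setup_fold_permutations(kind, setup_fold)
  nat <- do.call(rbind, lapply(native$chains[chains], chain_coords,
                               atoms = "CA"))
  mod_cas <- lapply(model$chains, chain_coords, atoms = "CA")
  if (nrow(nat) != sum(vapply(mod_cas[chains], nrow, 0L)))
    stop("model and native differ in residue count")
  best <- Inf
  for (perm in perms) {
    mod <- do.call(rbind, mod_cas[perm[chains]])
    r <- superpose(mod, nat)$rmsd
    if (r < best) best <- r
  }
  best
}

chain_heavy <- function(chain) {
  a <- chain$atoms[chain$atoms$element != "H", ]
  list(xyz = as.matrix(a[, c("x", "y", "z")]), resno = a$resno)
}

chain_backbone <- function(chain) {
  a <- chain$atoms[chain$atoms$atom %in% c("N", "CA", "C", "O"), ]
  list(xyz = as.matrix(a[, c("x", "y", "z")]), resno = a$resno)
}

# residue pairs (chain A, chain B) with any heavy-atom contact below cutoff
contact_pairs <- function(chA, chB, cutoff) {
  ha <- chain_heavy(chA); hb <- chain_heavy(chB)
  d2 <- cross_dist2(ha$xyz, hb$xyz)
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  unique(data.frame(ra = ha$resno[hit[, 1]], rb = hb$resno[hit[, 2]]))
}

#' DockQ score of a chain-pair interface
#'
#' The mean of the native-contact fraction Fnat, `1 / (1 + (iRMS/1.5)^2)`
#' and `1 / (1 + (LRMS/8.5)^2)`, with native contacts at 5 A heavy-atom
#' distance, interface residues within 10 A, iRMS on interface backbone
#' atoms and LRMS on the ligand backbone after receptor superposition.
#' Chains are aligned by residue number.
#'
#' @param model_pair,native_pair lists of two `chain_model` objects
#'   (receptor, ligand).
#' @return DockQ in `[0, 1]`.
#' @export
dockq <- function(model_pair, native_pair) {
  natc <- contact_pairs(native_pair[[1]], native_pair[[2]],
                        DOCKQ_FNAT_CUTOFF)
  if (nrow(natc) == 0) stop("native chain pair has no interface contacts")
  modc <- contact_pairs(model_pair[[1]], model_pair[[2]], DOCKQ_FNAT_CUTOFF)
  key <- function(df) paste(df$ra, df$rb)
  fnat <- mean(key(natc) %in% key(modc))
  # interface residues of the native pair (10 A heavy-atom)
  ifc <- contact_pairs(native_pair[[1]], native_pair[[2]],
                       DOCKQ_IFACE_CUTOFF)
  ira <- unique(ifc$ra); irb <- unique(ifc$rb)
  bb_sel <- function(chain, res) {
    b <- chain_backbone(chain)
    b$xyz[b$resno %in% res, , drop = FALSE]
  }
  nat_if <- rbind(bb_sel(native_pair[[1]], ira), bb_sel(native_pair[[2]], irb))
  mod_if <- rbind(bb_sel(model_pair[[1]], ira), bb_sel(model_pair[[2]], irb))
  irms <- superpose(mod_if, nat_if)$rmsd
  # LRMS: superpose receptors, measure the ligand backbone deviation
  nat_r <- chain_backbone(native_pair[[1]])$xyz
  mod_r <- chain_backbone(model_pair[[1]])$xyz
  sp <- superpose(mod_r, nat_r)
  nat_l <- chain_backbone(native_pair[[2]])$xyz
  mod_l <- chain_backbone(model_pair[[2]])$xyz
  mod_l_sup <- sweep(mod_l %*% t(sp$R), 2, -sp$t)
  lrms <- coord_rmsd(mod_l_sup, nat_l)
  (fnat + 1 / (1 + (irms / DOCKQ_IRMS_SCALE)^2) +
      1 / (1 + (lrms / DOCKQ_LRMS_SCALE)^2)) / 3
}

#' Buried surface area of a chain pair
#'
#' The solvent-accessible surface area gained when the two chains are moved
#' infinitely far apart: `SASA(A) + SASA(B) - SASA(AB)`.
#'
#' @param x an [assembly()].
#' @param i,j chain indices.
#' @param cfg a [ccs_config()] (SASA settings).
#' @return buried area in A^2 (non-negative up to numeric tolerance).
#' @export
delta_sasa <- function(x, i, j, cfg = ccs_config()) {
  sasa_of <- function(atoms) {
    sum(cpp_sasa(as.matrix(atoms[, c("x", "y", "z")]),
                 atom_radius_for_sasa(atoms),
                 cfg$probe_radius, as.integer(cfg$sphere_points)))
  }
  ai <- x$chains[[i]]$atoms; aj <- x$chains[[j]]$atoms
  sasa_of(ai) + sasa_of(aj) - sasa_of(rbind(ai, aj))
}

# the chain index whose relation to chain 1 is an n-fold rotation and whose
# COM is nearest chain 1 (the unique n-fold interface partner)
fold_partner <- function(x, kind, setup_fold, n) {
  g <- oriented_group(kind, setup_fold)
  coms <- t(vapply(x$chains, chain_com, numeric(3)))
  target <- 360 / n
  cands <- integer(0)
  for (k in seq_along(g$rotations)[-1]) {
    aa <- axis_angle(g$rotations[[k]])
    if (abs(aa$angle - target) < 1e-3) cands <- c(cands, k)
  }
  if (!length(cands)) return(NA_integer_)
  d <- sqrt(rowSums(sweep(coms[cands, , drop = FALSE], 2, coms[1, ])^2))
  cands[which.min(d)]
}

#' Pairwise DockQ of a symmetric assembly
#'
#' For each unique fold interface of the cubic symmetry (2- and 3-fold for
#' T; 2-, 3-, 4-fold for O; 2-, 3-, 5-fold for I) the model chain pair best
#' matching the native pair by RMSD is scored with [dockq()], and the
#' per-fold scores are averaged weighted by the native interface buried
#' surface area (weights sum to 1). Folds without native contacts are
#' skipped with a warning and the weights renormalized.
#'
#' @param model,native [assembly()] objects from the same symmetry.
#' @param kind `"T"`, `"O"` or `"I"`.
#' @param setup_fold fold order of the generating setup axis.
#' @return list with `pairwise_dockq` and a data frame `interfaces`
#'   (fold, partner chain, dockq, delta_sasa, weight).
#' @export
pairwise_dockq <- function(model, native, kind, setup_fold) {
  folds <- GROUP_FOLDS[[kind]]
  g <- oriented_group(kind, setup_fold)
  rows <- list()
  for (n in folds) {
    j <- fold_partner(native, kind, setup_fold, n)
    if (is.na(j)) next
    ds <- delta_sasa(native, 1, j)
    natc <- tryCatch(contact_pairs(native$chains[[1]], native$chains[[j]],
                                   DOCKQ_FNAT_CUTOFF),
                     error = function(e) NULL)
    if (is.null(natc) || nrow(natc) == 0 || ds <= 0) {
      warning("no native contacts at the ", n, "-fold interface; skipped")
      next
    }
    # model pair best matching the native pair by RMSD among n-fold pairs
    target <- 360 / n
    cands <- integer(0)
    for (k in seq_along(g$rotations)[-1]) {
      aa <- axis_angle(g$rotations[[k]])
      if (abs(aa$angle - target) < 1e-3) cands <- c(cands, k)
    }
    nat_cat <- rbind(chain_backbone(native$chains[[1]])$xyz,
                     chain_backbone(native$chains[[j]])$xyz)
    best <- NULL
    for (k in cands) {
      mod_cat <- rbind(chain_backbone(model$chains[[1]])$xyz,
                       chain_backbone(model$chains[[k]])$xyz)
      if (nrow(mod_cat) != nrow(nat_cat)) next
      r <- superpose(mod_cat, nat_cat)$rmsd
      if (is.null(best) || r < best$r) best <- list(k = k, r = r)
    }
    dq <- dockq(list(model$chains[[1]], model$chains[[best$k]]),
                list(native$chains[[1]], native$chains[[j]]))
    rows[[length(rows) + 1]] <- data.frame(fold = n, partner = j,
                                           model_partner = best$k,
                                           dockq = dq, delta_sasa = ds)
  }
  if (!length(rows)) stop("no scoreable fold interfaces")
  tab <- do.call(rbind, rows)
  tab$weight <- tab$delta_sasa / sum(tab$delta_sasa)
  list(pairwise_dockq = sum(tab$dockq * tab$weight), interfaces = tab)
}

tm_d0 <- function(L) max(0.5, 1.24 * (L - 15)^(1 / 3) - 1.8)

tm_iterative <- function(mod, nat, d0) {
  L <- nrow(nat)
  subset <- seq_len(L)
  best <- 0
  for (it in 1:20) {
    sp <- superpose(mod[subset, , drop = FALSE], nat[subset, , drop = FALSE])
    moved <- sweep(mod %*% t(sp$R), 2, -sp$t)
    d <- sqrt(rowSums((moved - nat)^2))
    tm <- sum(1 / (1 + (d / d0)^2)) / L
    if (tm > best) best <- tm
    new_subset <- which(d < max(d0, 3))
    if (length(new_subset) < 4 || identical(new_subset, subset)) break
    subset <- new_subset
  }
  best
}

#' Simplified assembly TM-score
#'
#' Length-normalized TM-score of the full assembly CA trace with
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, maximized over iterative-subset
#' superposition and over the symmetry-consistent chain re-mappings induced
#' by the point group (for assemblies without symmetry information only the
#' identity mapping is used). A simplified internal stand-in for a full
#' structural alignment of the assembly.
#'
#' @param model,native [assembly()] objects of equal total length.
#' @param kind,setup_fold optional symmetry for chain re-mappings.
#' @return TM-score in `(0, 1]`.
#' @export
tm_score_assembly <- function(model, native, kind = NULL, setup_fold = NULL) {
  mod_cas <- lapply(model$chains, chain_coords, atoms = "CA")
  nat_cas <- lapply(native$chains, chain_coords, atoms = "CA")
  nat <- do.call(rbind, nat_cas)
  if (sum(vapply(mod_cas, nrow, 0L)) != nrow(nat))
    stop("model and native differ in total residue count")
  perms <- if (!is.null(kind)) group_permutations(kind, setup_fold)
           else list(seq_along(model$chains))
  d0 <- tm_d0(nrow(nat))
  best <- 0
  for (perm in perms) {
    mod <- do.call(rbind, mod_cas[perm])
    tm <- tm_iterative(mod, nat, d0)
    if (tm > best) best <- tm
  }
  best
}

#' Classify model quality
#'
#' A model is successful when its pairwise DockQ is at least acceptable
#' (0.23) and its TM-score at least 0.9; highly accurate when the pairwise
#' DockQ is high (0.80) with the same TM-score requirement. A model with
#' acceptable DockQ but TM-score below 0.9 is merely "acceptable".
#'
#' @param tm TM-score in `[0, 1]`.
#' @param pairwise_dockq pairwise DockQ in `[0, 1]`.
#' @return one of `"none"`, `"acceptable"`, `"successful"`,
#'   `"highly-accurate"`.
#' @export
classify_quality <- function(tm, pairwise_dockq) {
  stopifnot(tm >= 0, tm <= 1, pairwise_dockq >= 0, pairwise_dockq <= 1)
  if (pairwise_dockq >= DOCKQ_HIGH && tm >= 0.9) return("highly-accurate")
  if (pairwise_dockq >= DOCKQ_ACCEPTABLE && tm >= 0.9) return("successful")
  if (pairwise_dockq >= DOCKQ_ACCEPTABLE) return("acceptable")
  "none"
}

#' Success probability by run resampling
#'
#' For each candidate number of runs, resamples that many runs with
#' replacement from the observed run table and counts the fraction of
#' resampled sets whose best (lowest) RMSD beats the success threshold;
#' repeated `reps` times per candidate. Also reports the number of runs
#' needed to reach 80, 90 and 99 percent success.
#'
#' @param runs data frame with an `rmsd` column (final lowest-energy RMSD
#'   per run) as from [make_runs_table()].
#' @param num_runs_range integer vector of run counts to evaluate.
#' @param reps resamples per run count.
#' @param threshold success RMSD threshold (A).
#' @param seed optional RNG seed.
#' @return list with `table` (num_runs, success probability) and
#'   `runs_needed` (named vector for 80/90/99 percent).
#' @export
success_bootstrap <- function(runs, num_runs_range = 1:20, reps = 100,
                              threshold = 4, seed = NULL) {
  if (!nrow(runs)) stop("empty run table")
  if (!is.null(seed)) set.seed(seed)
  probs <- vapply(num_runs_range, function(k) {
    mean(vapply(seq_len(reps), function(r)
      min(sample(runs$rmsd, k, replace = TRUE)) < threshold, TRUE))
  }, 0)
  tab <- data.frame(num_runs = num_runs_range, success = probs)
  needed <- vapply(c(`80` = 0.8, `90` = 0.9, `99` = 0.99), function(p) {
    w <- which(probs >= p)
    if (length(w)) num_runs_range[w[1]] else NA_integer_
  }, 0L)
  list(table = tab, runs_needed = needed)
}

#' Evaluate a model assembly against a native assembly
#'
#' Convenience wrapper computing the TM-score, pairwise DockQ, symmetric
#' RMSD and the quality class.
#'
#' @param model,native [assembly()] objects.
#' @param kind,setup_fold symmetry specification.
#' @return list of class `eval_result`.
#' @export
evaluate_model <- function(model, native, kind, setup_fold) {
  tm <- tm_score_assembly(model, native, kind, setup_fold)
  pd <- pairwise_dockq(model, native, kind, setup_fold)
  rmsd <- symmetric_rmsd(model, native, kind, setup_fold)
  structure(list(tm_score = tm, pairwise_dockq = pd$pairwise_dockq,
                 interfaces = pd$interfaces, rmsd = rmsd,
                 quality_class = classify_quality(tm, pd$pairwise_dockq)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> TM %.3f | pairwise DockQ %.3f | RMSD %.2f A | %s\n",
              x$tm_score, x$pairwise_dockq, x$rmsd, x$quality_class))
  invisible(x)
}
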