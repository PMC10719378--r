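# The memetic docking optimizer: differential evolution over the six
# rigid-body parameters hybridized with symmetry-aware sliding moves and a
# Metropolis local search, with occasional backbone replacement from the
# ensemble (BB trials). Selection uses the interface score (Iscore).

#' Differential-evolution configuration
#'
#' Defaults follow the published protocol: population of 100 run for 50
#' generations with mutation rate 0.1 and recombination rate 0.7; the local
#' search executes 10 CCS-scored rigid-body Metropolis moves. The BB-trial
#' probability and the Metropolis temperature are package choices (the
#' protocol says "occasionally" and names no temperature).
#'
#' @param population_size number of individuals.
#' @param generations number of DE generations.
#' @param mutation_rate DE differential weight F.
#' @param recombination_rate binomial crossover probability CR.
#' @param bb_trial_probability per-individual, per-generation probability of
#'   a backbone swap trial.
#' @param mc_moves rigid-body Metropolis moves inside the local search.
#' @param temperature Metropolis temperature (surrogate energy units).
#' @param slide_step sliding-move step size (A).
#' @param slide_max maximum clash-free sliding steps per fold axis.
#' @param recap_ranges perturbation half-widths
#'   `(psi, theta, phi, z, x, lam)` used to initialize recapitulation runs
#'   around the native parameters.
#' @param seed RNG seed (`NULL` leaves the RNG state alone).
#' @return list of class `de_config`.
#' @export
de_config <- function(population_size = 100, generations = 50,
                      mutation_rate = 0.1, recombination_rate = 0.7,
                      bb_trial_probability = 0.3, mc_moves = 10,
                      temperature = 1.0, slide_step = 0.3, slide_max = 100,
                      recap_ranges = c(psi = 8, theta = 8, phi = 8,
                                       z = 2, x = 2, lam = 8),
                      seed = NULL) {
  stopifnot(mutation_rate >= 0, recombination_rate >= 0,
            recombination_rate <= 1, bb_trial_probability >= 0,
            bb_trial_probability <= 1)
  structure(list(population_size = population_size,
                 generations = generations,
                 mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate,
                 bb_trial_probability = bb_trial_probability,
                 mc_moves = mc_moves, temperature = temperature,
                 slide_step = slide_step, slide_max = slide_max,
                 recap_ranges = recap_ranges, seed = seed),
            class = "de_config")
}

new_individual <- function(bb, params, flip = 0L, iscore = NA_real_,
                           ccs = NA_real_) {
  list(bb = bb, params = params, flip = flip, iscore = iscore, ccs = ccs)
}

eval_with_ctx <- function(ctx, ind, bounds) {
  pen <- square_well_penalty(ind$params, bounds)
  ind$iscore <- ctx_iscore(ctx, ind$params, ind$flip) + pen
  ind
}

eval_individual <- function(ctxs, ind, bounds) {
  eval_with_ctx(ctxs[[ind$bb]], ind, bounds)
}

#' Uniform perturbation around a parameter center
#'
#' Draws each parameter uniformly in `center +- range`, optionally clipped
#' to bounds. Used to start recapitulation runs from a broad range around
#' the native parameters.
#'
#' @param center [rigid_body_params()].
#' @param ranges named half-widths for the six parameters.
#' @param bounds optional [make_bounds()] object to clip against.
#' @return perturbed [rigid_body_params()].
#' @export
perturb_params <- function(center, ranges, bounds = NULL) {
  p <- center
  for (nm in PARAM_NAMES)
    p[[nm]] <- center[[nm]] + stats::runif(1, -ranges[[nm]], ranges[[nm]])
  if (!is.null(bounds)) {
    b <- bounds$bounds
    p[PARAM_NAMES] <- pmin(pmax(p[PARAM_NAMES], b[, "lo"]), b[, "hi"])
  }
  p
}

# COM position vector of the placed main subunit
placement_com <- function(params, ...) {
  as.vector(rot_z(params[["lam"]]) %*% c(params[["x"]], 0, params[["z"]]))
}

# Re-express the placement after translating the main subunit by `delta`
# without rotating it; the global orientation Rz(lam) Rf E is preserved.
params_after_translation <- function(params, flip, delta, setup_fold) {
  p <- placement_com(params) + delta
  zv <- p[3]
  xv <- sqrt(p[1]^2 + p[2]^2)
  lam_new <- if (xv > 1e-9) rad2deg(atan2(p[2], p[1])) else params[["lam"]]
  dlam <- params[["lam"]] - lam_new
  if (flip) dlam <- -dlam
  E <- rot_z(dlam) %*% euler_zyz(params[["psi"]], params[["theta"]],
                                 params[["phi"]])
  # stay on the same branch of the Euler double cover so the bounded
  # parameter values change continuously
  ang <- euler_zyz_near(E, params[c("psi", "theta", "phi")])
  rigid_body_params(psi = ang[["psi"]], theta = ang[["theta"]],
                    phi = ang[["phi"]], z = zv, x = xv,
                    lam = wrap_angle(lam_new, 360 / setup_fold))
}

ctx_fold_axes <- function(ctx, n) {
  key <- paste0("axes_", n)
  if (is.null(ctx$cache)) ctx$cache <- new.env(parent = emptyenv())
  fold_axes(ctx$group, n)
}

#' Symmetric sliding move
#'
#' Slides the subunits along the symmetry fold axes from the highest to the
#' lowest fold. For each fold, the whole ring of chains around the axis
#' nearest the main subunit translates toward the assembly center in fixed
#' steps (keeping that fold's own interface fixed) until a CCS clash is
#' detected or the step budget is spent; a clashing trial step is reverted.
#' A fold's slide whose parameters leave the bounds is reverted.
#'
#' @param ctx a docking context (internal) for the individual's backbone.
#' @param ind an individual (`bb`, `params`, `flip`).
#' @param bounds a [make_bounds()] object.
#' @param cfg a [de_config()].
#' @return the individual with updated parameters (scores unset).
#' @keywords internal
slide_individual <- function(ctx, ind, bounds, cfg) {
  n_setup <- ctx$sd$setup_fold
  folds <- sort(ctx$group$folds, decreasing = TRUE)
  for (n in folds) {
    if (ctx_has_clash(ctx, ind$params, ind$flip)) next # 0 steps on this axis
    fold_start <- ind
    axes <- fold_axes(ctx$group, n)
    p <- placement_com(ind$params)
    ph <- p / sqrt(sum(p^2))
    dots <- as.vector(axes %*% ph)
    k <- which.max(abs(dots))
    a <- axes[k, ] * sign(dots[k])
    for (s in seq_len(cfg$slide_max)) {
      trial <- ind
      trial$params <- params_after_translation(ind$params, ind$flip,
                                               -cfg$slide_step * a, n_setup)
      if (ctx_has_clash(ctx, trial$params, trial$flip)) break
      ind <- trial
    }
    # a slide that leaves the bounds is reverted (per fold, so in-bounds
    # progress along the other axes is kept)
    if (square_well_penalty(ind$params, bounds) > 0) ind <- fold_start
  }
  ind$iscore <- NA_real_; ind$ccs <- NA_real_
  ind
}

# one greedy coordinate-descent pass over the six parameters
pack_min_pass <- function(ctx, ind, bounds, steps) {
  e <- function(par) {
    ctx_iscore(ctx, par, ind$flip) + square_well_penalty(par, bounds)
  }
  cur <- ind$params
  ecur <- if (is.na(ind$iscore)) e(cur) else ind$iscore
  for (nm in PARAM_NAMES) {
    d <- steps[[nm]]
    for (sgn in c(-1, 1)) {
      trial <- cur; trial[[nm]] <- cur[[nm]] + sgn * d
      et <- e(trial)
      if (et < ecur - 1e-12) { cur <- trial; ecur <- et }
    }
  }
  ind$params <- cur; ind$iscore <- ecur
  ind
}

metropolis_accept <- function(de, temperature) {
  de < 0 || stats::runif(1) < exp(-de / max(temperature, 1e-9))
}

#' Memetic local search
#'
#' The surrogate of the packing-minimization / rigid-body subroutine: a
#' greedy coordinate minimization of the Iscore (Metropolis-accepted;
#' repeated once more if the first pass improved by at least the
#' improvement threshold), followed by `mc_moves` random rigid-body
#' perturbations accepted by a Metropolis criterion on the
#' CloudContactScore, followed by a final minimization pass. Returns the
#' best Iscore state encountered.
#'
#' @inheritParams slide_individual
#' @keywords internal
local_search_individual <- function(ctx, ind, bounds, cfg) {
  steps <- c(psi = 2, theta = 2, phi = 2, z = 0.3, x = 0.3, lam = 2)
  ind <- eval_with_ctx(ctx, ind, bounds)
  best <- ind
  # packing-minimization (greedy => always Metropolis-accepted)
  e0 <- ind$iscore
  ind <- pack_min_pass(ctx, ind, bounds, steps)
  if (e0 - ind$iscore >= ctx$energy_cfg$improvement_threshold)
    ind <- pack_min_pass(ctx, ind, bounds, steps)
  if (ind$iscore < best$iscore) best <- ind
  # CCS-scored rigid-body Metropolis subroutine
  mc <- ind
  mc_ccs <- ctx_ccs_total(ctx, mc$params, mc$flip) +
    square_well_penalty(mc$params, bounds)
  sds <- c(psi = 2, theta = 2, phi = 2, z = 0.5, x = 0.5, lam = 2)
  for (m in seq_len(cfg$mc_moves)) {
    trial <- mc
    trial$params[PARAM_NAMES] <- mc$params[PARAM_NAMES] +
      stats::rnorm(6, 0, sds)
    tccs <- ctx_ccs_total(ctx, trial$params, trial$flip) +
      square_well_penalty(trial$params, bounds)
    if (metropolis_accept(tccs - mc_ccs, cfg$temperature)) {
      mc <- trial; mc_ccs <- tccs
    }
  }
  mc <- eval_with_ctx(ctx, mc, bounds)
  if (mc$iscore < best$iscore) best <- mc
  # final packing-minimization from the MC end state
  fin <- pack_min_pass(ctx, mc, bounds, steps)
  if (fin$iscore < best$iscore) best <- fin
  best$ccs <- NA_real_
  best
}

#' One differential-evolution step
#'
#' Builds a DE/rand/1/bin trial for every individual: donor
#' `a + F (b - c)` over the six parameters with binomial crossover at rate
#' CR and one forced crossover position; the backbone index is inherited
#' from the target and the orientation flag crosses over from the donor
#' base with probability CR.
#'
#' @param population list of individuals.
#' @param cfg a [de_config()].
#' @return list of unevaluated trial individuals.
#' @export
de_step <- function(population, cfg) {
  np <- length(population)
  if (np < 4) stop("differential evolution needs a population of at least 4")
  Fw <- cfg$mutation_rate; CR <- cfg$recombination_rate
  trials <- vector("list", np)
  for (i in seq_len(np)) {
    abc <- sample(setdiff(seq_len(np), i), 3)
    pa <- population[[abc[1]]]$params
    pb <- population[[abc[2]]]$params
    pc <- population[[abc[3]]]$params
    donor <- pa[PARAM_NAMES] + Fw * (pb[PARAM_NAMES] - pc[PARAM_NAMES])
    target <- population[[i]]$params
    cross <- stats::runif(6) < CR
    cross[sample.int(6, 1)] <- TRUE
    trial <- target
    trial[PARAM_NAMES][cross] <- donor[cross]
    flip <- if (stats::runif(1) < CR) population[[abc[1]]]$flip
            else population[[i]]$flip
    trials[[i]] <- new_individual(population[[i]]$bb, trial, flip)
  }
  trials
}

#' Survivor selection
#'
#' The individual with the lower Iscore survives; ties keep the parent.
#'
#' @param parent,trial evaluated individuals.
#' @return the surviving individual.
#' @export
select_individual <- function(parent, trial) {
  if (is.na(trial$iscore)) return(parent)
  if (trial$iscore < parent$iscore) trial else parent
}

#' Backbone replacement trial
#'
#' With the configured probability, swaps in a different random ensemble
#' backbone, re-runs slide + local search, and keeps the swap only if the
#' Iscore improves.
#'
#' @param ind an evaluated individual.
#' @param ctxs list of per-backbone docking contexts.
#' @param bounds a [make_bounds()] object.
#' @param cfg a [de_config()].
#' @return the (possibly updated) individual.
#' @keywords internal
bb_trial_individual <- function(ind, ctxs, bounds, cfg) {
  if (length(ctxs) < 2) return(ind)
  if (stats::runif(1) >= cfg$bb_trial_probability) return(ind)
  newbb <- sample(setdiff(seq_along(ctxs), ind$bb), 1)
  cand <- ind; cand$bb <- newbb
  cand <- slide_individual(ctxs[[newbb]], cand, bounds, cfg)
  cand <- local_search_individual(ctxs[[newbb]], cand, bounds, cfg)
  if (cand$iscore < ind$iscore) cand else ind
}

# initial z for a global-mode individual: slide away then back onto contact
slide_in_z <- function(ctx, params, flip, cfg) {
  p <- params
  rb <- max(sqrt(rowSums(ctx$cloud_ccs$coords^2)))
  p[["z"]] <- 4 * rb + 24
  coarse <- 8 * cfg$slide_step
  for (step in c(coarse, cfg$slide_step)) {
    repeat {
      trial <- p; trial[["z"]] <- p[["z"]] - step
      if (trial[["z"]] < 0 || ctx_has_clash(ctx, trial, flip)) break
      p <- trial
    }
    p[["z"]] <- p[["z"]] + step # back off before refining / finishing
  }
  p[["z"]] - cfg$slide_step
}

#' Initialize a docking population
#'
#' Parameters are drawn uniformly within their bounds (local/global modes)
#' or uniformly in the configured perturbation ranges around the bounds
#' center (recapitulation). In global mode the initial `z` of each
#' individual is determined by sliding the subunits away and back onto each
#' other until the CloudContactScore detects a clash, and half the
#' population starts in each of the two flip orientations.
#'
#' @param ensemble list of `chain_model` backbones (or a single one).
#' @param sd a [symmetry_def()].
#' @param bounds a [make_bounds()] object (its center defines the template).
#' @param mode `"recapitulate"`, `"local"` or `"global"`.
#' @param cfg a [de_config()].
#' @return list of unevaluated individuals.
#' @export
initialize_population <- function(ensemble, sd, bounds,
                                  mode = c("recapitulate", "local", "global"),
                                  cfg = de_config()) {
  mode <- match.arg(mode)
  if (inherits(ensemble, "chain_model")) ensemble <- list(ensemble)
  if (!length(ensemble)) stop("empty ensemble")
  ctxs <- lapply(ensemble, dock_context, sd = sd)
  b <- bounds$bounds
  pop <- vector("list", cfg$population_size)
  for (i in seq_len(cfg$population_size)) {
    bb <- sample.int(length(ensemble), 1)
    flip <- if (mode == "global") as.integer(i > cfg$population_size / 2)
            else 0L
    if (mode == "recapitulate") {
      params <- perturb_params(bounds$center, cfg$recap_ranges, bounds)
    } else {
      params <- rigid_body_params()
      for (nm in PARAM_NAMES)
        params[[nm]] <- stats::runif(1, b[nm, "lo"], b[nm, "hi"])
    }
    if (mode == "global")
      params[["z"]] <- slide_in_z(ctxs[[bb]], params, flip, cfg)
    pop[[i]] <- new_individual(bb, params, flip)
  }
  pop
}

archive_row <- function(ind, gen) {
  data.frame(gen = gen, bb = ind$bb, t(ind$params[PARAM_NAMES]),
             flip = ind$flip, iscore = ind$iscore)
}

#' Run a symmetric docking simulation
#'
#' Executes the memetic loop: DE trial generation, symmetric sliding,
#' Metropolis local search, Iscore selection and backbone trials, for the
#' configured number of generations. Fully reproducible for a fixed
#' `cfg$seed`.
#'
#' @param ensemble list of `chain_model` backbones (or one).
#' @param sd a [symmetry_def()]; must carry `params` (the template center)
#'   for recapitulation/local modes.
#' @param mode `"recapitulate"`, `"local"` or `"global"`.
#' @param cfg a [de_config()].
#' @param reference optional native [assembly()]; when given, the best
#'   individual's symmetric RMSD is logged each generation.
#' @param estimates optional [rigid_body_params()] with starting
#'   `psi/theta/phi/x` for global mode (e.g. from
#'   [extract_oligomer_params()]).
#' @return list with `population` (final individuals), `archive` (data
#'   frame of all selected individuals per generation), `log` (per
#'   generation best/mean Iscore, acceptance rate, best RMSD) and `best`.
#' @export
run_docking <- function(ensemble, sd,
                        mode = c("recapitulate", "local", "global"),
                        cfg = de_config(), reference = NULL,
                        estimates = NULL) {
  mode <- match.arg(mode)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (inherits(ensemble, "chain_model")) ensemble <- list(ensemble)
  if (mode %in% c("recapitulate", "local")) {
    if (is.null(sd$params))
      stop(mode, " mode requires template parameters in the symmetry definition")
    center <- sd$params
    bounds <- make_bounds(sd, "local", center)
  } else {
    center <- if (!is.null(estimates)) estimates else rigid_body_params()
    center[["z"]] <- 0; center[["lam"]] <- 0
    bounds <- make_bounds(sd, "global", center)
  }
  ctxs <- lapply(ensemble, dock_context, sd = sd)
  pop <- initialize_population(ensemble, sd, bounds, mode, cfg)
  pop <- lapply(pop, function(ind) eval_individual(ctxs, ind, bounds))
  log <- NULL
  archive <- list()
  for (g in seq_len(cfg$generations)) {
    trials <- de_step(pop, cfg)
    accepted <- 0
    for (i in seq_along(pop)) {
      tr <- trials[[i]]
      tr <- slide_individual(ctxs[[tr$bb]], tr, bounds, cfg)
      tr <- local_search_individual(ctxs[[tr$bb]], tr, bounds, cfg)
      survivor <- select_individual(pop[[i]], tr)
      if (!identical(survivor, pop[[i]])) accepted <- accepted + 1
      survivor <- bb_trial_individual(survivor, ctxs, bounds, cfg)
      pop[[i]] <- survivor
    }
    iscores <- vapply(pop, `[[`, 0, "iscore")
    best_i <- which.min(iscores)
    rmsd <- NA_real_
    if (!is.null(reference)) {
      model <- place_and_expand(ensemble[[pop[[best_i]]$bb]],
                                pop[[best_i]]$params, sd,
                                pop[[best_i]]$flip)
      rmsd <- symmetric_rmsd(model, reference, sd$kind, sd$setup_fold)
    }
    log <- rbind(log, data.frame(gen = g, best_iscore = min(iscores),
                                 mean_iscore = mean(iscores),
                                 accept_rate = accepted / length(pop),
                                 best_rmsd = rmsd))
    archive[[g]] <- do.call(rbind, lapply(pop, archive_row, gen = g))
  }
  for (i in seq_along(pop))
    pop[[i]]$ccs <- ctx_ccs_total(ctxs[[pop[[i]]$bb]], pop[[i]]$params,
                                  pop[[i]]$flip)
  iscores <- vapply(pop, `[[`, 0, "iscore")
  list(population = pop, archive = do.call(rbind, archive), log = log,
       best = pop[[which.min(iscores)]])
}
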