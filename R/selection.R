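# The post-docking selection funnel: harvest the best individuals by
# Iscore, cluster on the six rigid-body parameters, refine each cluster
# representative with a surrogate relax, and emit five ranked final models.

#' Selection-funnel configuration
#'
#' Defaults follow the published funnel: the 1000 best structures by Iscore
#' are clustered into 100 sets whose representatives are refined, then
#' re-clustered into 5 final models.
#'
#' @param harvest_n individuals harvested by Iscore.
#' @param refine_clusters clusters before refinement.
#' @param final_clusters final model count.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(harvest_n = 1000, refine_clusters = 100,
                             final_clusters = 5) {
  stopifnot(harvest_n >= refine_clusters,
            refine_clusters >= final_clusters)
  structure(list(harvest_n = harvest_n, refine_clusters = refine_clusters,
                 final_clusters = final_clusters),
            class = "selection_config")
}

#' Harvest the best individuals by Iscore
#'
#' Takes the `harvest_n` lowest-Iscore rows of a docking archive; ties are
#' broken by the stable order of the archive (run, then generation). Fewer
#' rows than requested are returned with a warning.
#'
#' @param archive data frame with at least an `iscore` column (e.g. the
#'   concatenated `archive` tables of several [run_docking()] results).
#' @param cfg a [selection_config()].
#' @return the harvested rows, best first.
#' @export
harvest <- function(archive, cfg = selection_config()) {
  if (!nrow(archive)) stop("empty archive")
  if (nrow(archive) < cfg$harvest_n)
    warning("archive has only ", nrow(archive), " individuals (requested ",
            cfg$harvest_n, ")")
  ord <- order(archive$iscore) # stable: ties keep archive order
  archive[utils::head(ord, cfg$harvest_n), , drop = FALSE]
}

#' Cluster models on their rigid-body parameters
#'
#' k-means over the raw six-parameter vectors (10 restarts, seeded);
#' the representative of each cluster is its best-Iscore member.
#'
#' @param models data frame with the six parameter columns and `iscore`.
#' @param k number of clusters (reduced with a warning if there are fewer
#'   models).
#' @param seed RNG seed for the k-means restarts.
#' @return list with `labels`, `representatives` (row indices into
#'   `models`) and the fitted `kmeans` object.
#' @export
cluster_params <- function(models, k, seed = 1) {
  X <- as.matrix(models[, PARAM_NAMES])
  if (nrow(X) < k) {
    warning("only ", nrow(X), " models; reducing k from ", k)
    k <- nrow(X)
  }
  set.seed(seed)
  X_unique <- nrow(unique(round(X, 9)))
  k_eff <- min(k, X_unique)
  if (k_eff >= nrow(X)) {
    km <- NULL
    labels <- seq_len(nrow(X))
    k_eff <- nrow(X)
  } else {
    km <- stats::kmeans(X, centers = k_eff, nstart = 10, iter.max = 50)
    labels <- km$cluster
  }
  reps <- vapply(seq_len(k_eff), function(cl) {
    idx <- which(labels == cl)
    idx[which.min(models$iscore[idx])]
  }, 0L)
  if (k_eff < k) {
    # degenerate input: duplicate representatives to keep the contract
    warning("parameter vectors support only ", k_eff, " distinct clusters")
    reps <- rep(reps, length.out = k)
  }
  list(labels = labels, representatives = reps, kmeans = km)
}

#' Surrogate refinement of selected models
#'
#' The stand-in for all-atom relax: bounded local minimization of the
#' Iscore over the six parameters (L-BFGS-B within the docking bounds)
#' followed by re-selection of the best backbone from the ensemble at the
#' refined parameters. The Iscore never worsens.
#'
#' @param models data frame of selected models (six parameter columns,
#'   `bb`, `flip`, `iscore`).
#' @param ensemble list of `chain_model` backbones.
#' @param sd a [symmetry_def()].
#' @param bounds a [make_bounds()] object.
#' @return `models` with refined parameters, backbone ids and Iscores.
#' @export
refine <- function(models, ensemble, sd, bounds) {
  if (inherits(ensemble, "chain_model")) ensemble <- list(ensemble)
  ctxs <- lapply(ensemble, dock_context, sd = sd)
  b <- bounds$bounds
  for (i in seq_len(nrow(models))) {
    p0 <- stats::setNames(as.numeric(models[i, PARAM_NAMES]), PARAM_NAMES)
    flip <- models$flip[i]
    ctx <- ctxs[[models$bb[i]]]
    obj <- function(v) ctx_iscore(ctx, stats::setNames(v, PARAM_NAMES), flip)
    opt <- stats::optim(p0, obj, method = "L-BFGS-B",
                        lower = pmax(b[, "lo"], p0 - c(10, 10, 10, 3, 3, 10)),
                        upper = pmin(b[, "hi"], p0 + c(10, 10, 10, 3, 3, 10)),
                        control = list(maxit = 100))
    par <- opt$par; val <- opt$value
    # backbone re-selection at the refined parameters
    if (length(ctxs) > 1) {
      vals <- vapply(seq_along(ctxs), function(bb)
        ctx_iscore(ctxs[[bb]], stats::setNames(par, PARAM_NAMES), flip), 0)
      bbbest <- which.min(vals)
      if (vals[bbbest] < val) { val <- vals[bbbest]; models$bb[i] <- bbbest }
    }
    if (val <= models$iscore[i]) {
      models[i, PARAM_NAMES] <- as.list(par)
      models$iscore[i] <- val
    }
  }
  models
}

#' Final five ranked models
#'
#' Clusters the refined models into `final_clusters` sets, takes the best
#' Iscore member of each and ranks the representatives by Iscore (rank 1 =
#' Best Ranked).
#'
#' @param models refined model data frame.
#' @param cfg a [selection_config()].
#' @param seed k-means seed.
#' @return the representative rows, ranked by Iscore, with a `rank` column.
#' @export
final_five <- function(models, cfg = selection_config(), seed = 1) {
  k <- cfg$final_clusters
  if (nrow(models) < k) {
    warning("only ", nrow(models), " models for ", k, " clusters")
    k <- nrow(models)
  }
  cl <- cluster_params(models, k, seed = seed)
  out <- models[cl$representatives, , drop = FALSE]
  out <- out[order(out$iscore), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' Run the full selection funnel
#'
#' harvest -> k-means into `refine_clusters` -> surrogate refinement of the
#' representatives -> final clustering into `final_clusters` ranked models.
#' The best Iscore present never increases through the funnel.
#'
#' @param archive docking archive data frame.
#' @param ensemble list of `chain_model` backbones.
#' @param sd a [symmetry_def()].
#' @param bounds a [make_bounds()] object.
#' @param cfg a [selection_config()].
#' @param seed k-means seed.
#' @return list with `harvested`, `refined` and `final` data frames.
#' @export
select_models <- function(archive, ensemble, sd, bounds,
                          cfg = selection_config(), seed = 1) {
  top <- harvest(archive, cfg)
  cl <- cluster_params(top, min(cfg$refine_clusters, nrow(top)), seed = seed)
  reps <- top[cl$representatives, , drop = FALSE]
  refined <- refine(reps, ensemble, sd, bounds)
  fin <- final_five(refined, cfg, seed = seed)
  list(harvested = top, refined = refined, final = fin)
}
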