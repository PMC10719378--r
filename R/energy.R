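# Surrogate interface energy standing in for an all-atom force field.
#
# The interface score (Iscore) of a symmetric placement is the sum, over
# main-subunit/neighbor atom pairs, of a truncated-and-shifted soft
# Lennard-Jones term, the surrogate backbone hydrogen bond, and a smooth
# connection-density weighted CB-CB contact reward. Intra-subunit energy is
# deliberately excluded: it would bias selection without improving the
# assembly.

#' Surrogate energy configuration
#'
#' @param lj_eps Lennard-Jones well depth per pair (surrogate units).
#' @param lj_cap repulsion cap per pair.
#' @param lj_cutoff truncation distance (A); the potential is shifted to
#'   zero there.
#' @param hb_weight weight of the hydrogen-bond terms.
#' @param contact_weight weight of the smooth CB contact reward.
#' @param contact_switch distances (A) over which the contact reward
#'   switches smoothly from full to zero.
#' @param clash_weight energy added per interchain clash (CCS clash
#'   definition); keeps the surrogate minima clash-free, since the capped
#'   soft LJ alone underpenalizes deep overlap.
#' @param improvement_threshold energy improvement (surrogate units) after
#'   which the local-search minimization pass is repeated.
#' @return list of class `energy_config`.
#' @export
energy_config <- function(lj_eps = 0.2, lj_cap = 10, lj_cutoff = 12,
                          hb_weight = 1, contact_weight = 0.5,
                          contact_switch = c(8, 12), clash_weight = 25,
                          improvement_threshold = 15) {
  structure(list(lj_eps = lj_eps, lj_cap = lj_cap, lj_cutoff = lj_cutoff,
                 hb_weight = hb_weight, contact_weight = contact_weight,
                 contact_switch = contact_switch,
                 clash_weight = clash_weight,
                 improvement_threshold = improvement_threshold),
            class = "energy_config")
}

# Precomputed scoring context for one backbone under one symmetry: the two
# point sets (full backbone for the energy, surface cloud for the CCS), the
# stacked group rotations and the kernel configuration vector.
dock_context <- function(subunit, sd, ccs_cfg = ccs_config(),
                         energy_cfg = energy_config()) {
  g <- oriented_group(sd$kind, sd$setup_fold)
  structure(list(subunit = subunit,
                 cloud_energy = build_point_cloud(subunit, ccs_cfg,
                                                  surface_only = FALSE),
                 cloud_ccs = build_point_cloud(subunit, ccs_cfg,
                                               surface_only = TRUE),
                 rots = stack_rotations(g),
                 group = g,
                 sd = sd,
                 ccs_cfg = ccs_cfg,
                 energy_cfg = energy_cfg,
                 kcfg = kernel_cfg(ccs_cfg, energy_cfg)),
            class = "dock_context")
}

# raw kernel terms for a placement; set ccs=TRUE to use the surface cloud
placement_terms <- function(ctx, params, flip = 0, ccs = FALSE,
                            clash_only = FALSE) {
  cl <- if (ccs) ctx$cloud_ccs else ctx$cloud_energy
  cpp_score_placement(cl$coords, cl$kind, cl$radius, cl$density, cl$resi,
                      cl$odir, ctx$rots,
                      params[PARAM_NAMES], as.integer(flip), ctx$kcfg,
                      clash_only)
}

iscore_from_terms <- function(terms, ecfg) {
  unname(terms[5] + ecfg$clash_weight * terms[1] +
           ecfg$hb_weight * (terms[2] + terms[3]) -
           ecfg$contact_weight * terms[6])
}

# Iscore of a placement within a precomputed context
ctx_iscore <- function(ctx, params, flip = 0) {
  iscore_from_terms(placement_terms(ctx, params, flip), ctx$energy_cfg)
}

# CCS total of a placement within a precomputed context
ctx_ccs_total <- function(ctx, params, flip = 0) {
  ccs_breakdown(placement_terms(ctx, params, flip, ccs = TRUE),
                ctx$ccs_cfg)$total
}

ctx_has_clash <- function(ctx, params, flip = 0) {
  placement_terms(ctx, params, flip, ccs = TRUE, clash_only = TRUE)[1] > 0
}

#' Interface score of a symmetric placement
#'
#' Sums the surrogate pair energy over every (main subunit, neighbor) chain
#' pair of the expanded assembly; each pair is counted once and
#' intra-subunit interactions are excluded. Deterministic for fixed input;
#' lower is better.
#'
#' @param subunit a `chain_model`.
#' @param params [rigid_body_params()].
#' @param sd a [symmetry_def()].
#' @param ccs_cfg a [ccs_config()].
#' @param energy_cfg an [energy_config()].
#' @param flip evaluate the 180-degree flipped orientation.
#' @return the interface score (surrogate energy units).
#' @export
interface_score <- function(subunit, params, sd, ccs_cfg = ccs_config(),
                            energy_cfg = energy_config(), flip = 0) {
  ctx <- dock_context(subunit, sd, ccs_cfg, energy_cfg)
  ctx_iscore(ctx, params, flip)
}

#' Whole-assembly interface energy
#'
#' For a homomer every interface appears `order` times but is shared by two
#' chains, so the whole-structure interface energy is
#' `(group order / 2) * Iscore`.
#'
#' @param iscore interface score of the main subunit.
#' @param sd a [symmetry_def()].
#' @return whole-assembly energy.
#' @export
whole_energy <- function(iscore, sd) {
  GROUP_ORDER[[sd$kind]] / 2 * iscore
}

# Iscore between two explicit chains (used by oracle-style full-assembly
# summation in tests and by the subsystem completeness checks).
chain_pair_iscore <- function(chainA, chainB, ccs_cfg = ccs_config(),
                              energy_cfg = energy_config()) {
  ca <- build_point_cloud(chainA, ccs_cfg, surface_only = FALSE)
  cb <- build_point_cloud(chainB, ccs_cfg, surface_only = FALSE)
  v <- cpp_pair_terms(cloud_absolute(ca)$xyz, ca$kind, ca$radius, ca$density,
                      ca$resi, cloud_absolute(ca)$odir,
                      cloud_absolute(cb)$xyz, cb$kind, cb$radius, cb$density,
                      cb$resi, cloud_absolute(cb)$odir,
                      kernel_cfg(ccs_cfg, energy_cfg), FALSE)
  iscore_from_terms(v, energy_cfg)
}
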