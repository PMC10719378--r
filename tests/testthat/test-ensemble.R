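test_that("model confidence is 0.8 ipTM + 0.2 pTM with range checks", {
  expect_equal(model_confidence(1, 1), 1.0)
  expect_equal(model_confidence(0, 1), 0.8)
  expect_equal(model_confidence(0.5, 0.9), 0.82)
  expect_error(model_confidence(1.2, 0.5), "\\[0, 1\\]")
  expect_error(model_confidence(0.5, -0.1), "\\[0, 1\\]")
})

test_that("confidence filtering applies the monomer and multimer rules", {
  s <- toy_helix()
  models <- list(mono_lo = s, mono_hi = s, multi_conf_lo = s,
                 multi_ok = s)
  manifest <- data.frame(
    model_id = names(models),
    mean_plddt = c(89.9, 92, 95, 95),
    ptm = c(0.9, 0.9, 0.85, 0.9),
    iptm = c(NA, NA, 0.9, 0.95))
  # multi_conf_lo: 0.8*0.9 + 0.2*0.85 = 0.89 < 0.9 -> dropped
  kept <- filter_by_confidence(models, manifest)
  expect_equal(names(kept), c("mono_hi", "multi_ok"))
  # empty result warns
  strict <- ensemble_config(plddt_min = 99)
  expect_warning(none <- filter_by_confidence(models, manifest, strict))
  expect_length(none, 0)
  expect_error(filter_by_confidence(list(unknown = s), manifest),
               "unknown")
})

test_that("residue metric profiles measure pLDDT, connectivity and SS", {
  h <- toy_hairpin(24)
  ens <- list(h, h)
  m <- residue_metric_profiles(ens)
  expect_equal(nrow(m), 24)
  expect_equal(m$avg_plddt, rep(95, 24))
  # hairpin strands contact across the turn at sequence separation >= 10
  expect_gt(mean(m$connectivity_pct > 99), 0.5)
  expect_gt(mean(m$ss_pct), 70)
  # a displaced terminal residue loses its connectivity
  far <- h
  sel <- far$atoms$resno == 24
  far$atoms[sel, c("x", "y", "z")] <- far$atoms[sel, c("x", "y", "z")] + 50
  m2 <- residue_metric_profiles(list(far))
  expect_equal(m2$connectivity_pct[24], 0)
  # per-residue pLDDT comes from the B-factors
  hb <- make_toy_subunit(24, "hairpin", plddt = c(rep(50, 4), rep(90, 20)))
  m3 <- residue_metric_profiles(list(hb))
  expect_equal(m3$avg_plddt[1:4], rep(50, 4))
  # an ideal helix is assigned 100% helical in its interior
  m4 <- residue_metric_profiles(list(toy_helix()))
  expect_equal(m4$ss_pct[5:12], rep(100, 8))
  expect_error(residue_metric_profiles(list(toy_helix(), toy_hairpin())),
               "length")
})

test_that("terminal trimming cuts at the last threshold crossing", {
  h <- toy_hairpin(24)
  # constructed pLDDT profile failing on residues 1-5 only
  prof <- c(rep(50, 5), rep(95, 19))
  lo <- make_toy_subunit(24, "hairpin", plddt = prof)
  ens <- list(lo, lo)
  tr <- trim_termini(ens)
  expect_equal(tr$n_cut, 5L)
  expect_equal(tr$c_cut, 0L)
  lens <- vapply(tr$ensemble, n_residues, 0L)
  expect_equal(lens, rep(19L, 2))
  expect_equal(tr$ensemble[[1]]$atoms$resno[1], 6)
  # all metrics passing: no trimming; trimming is idempotent
  ok <- trim_termini(list(h, h))
  expect_equal(ok$n_cut, 0L)
  again <- trim_termini(ok$ensemble)
  expect_equal(vapply(again$ensemble, n_residues, 0L),
               vapply(ok$ensemble, n_residues, 0L))
  # constructed metric table: first crossings at 3, 5 and 4 -> cut at 5
  metrics <- data.frame(resno = 1:24,
                        avg_plddt = c(rep(0, 4), rep(95, 20)),
                        connectivity_pct = c(rep(0, 2), rep(90, 22)),
                        ss_pct = c(rep(0, 3), rep(90, 21)))
  tr2 <- trim_termini(ens, metrics)
  expect_equal(tr2$n_cut, 4L)
  # every residue failing is an error
  bad <- make_toy_subunit(24, "hairpin", plddt = 10)
  expect_error(trim_termini(list(bad)), "threshold")
})

test_that("redundancy pruning keeps the better-scored survivor", {
  base <- toy_hairpin(24)
  jiggle <- function(seed, sdv) {
    set.seed(seed)
    ch <- base
    ch$atoms[, c("x", "y", "z")] <- ch$atoms[, c("x", "y", "z")] +
      matrix(rnorm(nrow(ch$atoms) * 3, 0, sdv), ncol = 3)
    ch
  }
  diverse <- lapply(1:8, jiggle, sdv = 1.0)
  # two identical members: only the better-scored one survives
  ens <- c(diverse, list(diverse[[3]]))
  scores <- c(95, 91, 90, 93, 92, 94, 96, 97, 98) # duplicate (9th) scores 98
  cfg <- ensemble_config(min_ensemble = 2)
  out <- prune_redundant(ens, scores, cfg)
  expect_equal(length(out$ensemble), 8)
  expect_false(3 %in% out$kept)  # the lower-scored copy was removed
  expect_true(9 %in% out$kept)
  # diverse set with a near-duplicate pair: one member pruned
  near <- c(diverse, list(jiggle(3, 1.0))) # seed 3 duplicates member 3
  near[[9]]$atoms$x <- near[[9]]$atoms$x + 1e-4
  out2 <- prune_redundant(near, scores, cfg)
  expect_equal(length(out2$ensemble), 8)
  # threshold relaxation: mutually similar models get relaxed thresholds
  sims <- lapply(1:6, jiggle, sdv = 0.02)
  out3 <- prune_redundant(sims, seq(90, 95), ensemble_config(min_ensemble = 4))
  expect_lt(out3$threshold, 0.1)
  expect_gte(length(out3$ensemble), 1)
})

test_that("oligomer parameter extraction recovers the generating values", {
  s <- toy_helix()
  p <- rigid_body_params(psi = 10, theta = 15, phi = 20, z = 0, x = 9,
                         lam = 0)
  oli <- make_cn_oligomer(s, 3, p)
  est <- extract_oligomer_params(oli, "T", 3, subunit = s)
  expect_lt(max(abs(est[c("psi", "theta", "phi")] -
                      p[c("psi", "theta", "phi")])), 0.5)
  expect_lt(abs(est[["x"]] - p[["x"]]), 0.1)
  expect_equal(attr(est, "cn_angle"), 120, tolerance = 0.1)
  # dimers within the 10-degree angular tolerance are accepted
  d <- make_cn_oligomer(s, 2, p)
  est2 <- extract_oligomer_params(d, "T", 2)
  expect_equal(attr(est2, "cn_angle"), 180, tolerance = 0.1)
  # monomers are rejected
  expect_error(extract_oligomer_params(assembly(list(s)), "T", 3),
               "at least 2")
  # chain-count mismatch is rejected
  expect_error(extract_oligomer_params(oli, "T", 2), "expected")
})

test_that("oligomer extraction round trips all folds of the three groups", {
  s <- toy_helix()
  for (n in c(2, 3, 4, 5)) {
    p <- rigid_body_params(psi = 7, theta = 12, phi = -9, z = 0,
                           x = 6 + n, lam = 0)
    oli <- make_cn_oligomer(s, n, p)
    kind <- switch(as.character(n), "2" = "T", "3" = "T", "4" = "O",
                   "5" = "I")
    est <- extract_oligomer_params(oli, kind, n, subunit = s)
    expect_lt(max(abs(est[c("psi", "theta", "phi")] -
                        p[c("psi", "theta", "phi")])), 0.5)
    expect_lt(abs(est[["x"]] - p[["x"]]), 0.1)
  }
})

test_that("the full preparation pipeline produces a docking-ready ensemble", {
  h <- toy_hairpin(24)
  prof <- c(rep(60, 2), rep(97, 20), rep(60, 2))
  syn <- make_synthetic_ensemble(h, n_models = 6, plddt_profile = prof,
                                 disorder_n_term = 2, disorder_c_term = 2,
                                 seed = 5)
  models <- syn$models
  names(models) <- syn$manifest$model_id
  res <- prepare_ensemble(models, syn$manifest)
  expect_gt(length(res$ensemble), 0)
  lens <- vapply(res$ensemble, n_residues, 0L)
  expect_equal(length(unique(lens)), 1L)
  # both disordered tails are removed; the corrupted junction dihedral and
  # the 3-residue SS smoothing may cost up to two extra residues per side
  expect_gte(res$n_cut, 2L); expect_lte(res$n_cut, 4L)
  expect_gte(res$c_cut, 2L); expect_lte(res$c_cut, 4L)
  expect_equal(unique(lens), 24L - res$n_cut - res$c_cut)
  expect_true(all(c("model_id", "passed_confidence", "kept_final") %in%
                    names(res$provenance)))
})
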