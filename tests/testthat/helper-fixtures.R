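# Shared fixtures, cached per test session. The toy native parameters are
# additionally cached inside the package environment, so repeated
# make_ideal_assembly() calls are cheap after the first.

.fx_cache <- new.env(parent = emptyenv())

toy_helix <- function(n_res = 16) {
  key <- paste0("helix_", n_res)
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- make_toy_subunit(n_res, "helix", seed = 1)
  .fx_cache[[key]]
}

toy_hairpin <- function(n_res = 24) {
  key <- paste0("hairpin_", n_res)
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- make_toy_subunit(n_res, "hairpin", seed = 1)
  .fx_cache[[key]]
}

toy_fixture <- function(kind, fold) {
  key <- paste0("fx_", kind, "_", fold)
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- make_ideal_assembly(kind, fold, toy_helix())
  .fx_cache[[key]]
}

# hand-built point cloud for kernel-level scoring tests
manual_cloud <- function(coords, kinds, density = NULL, resi = NULL,
                         odir = NULL) {
  coords <- matrix(coords, ncol = 3, byrow = TRUE)
  n <- nrow(coords)
  kind_code <- c(N = 0L, CA = 1L, C = 2L, O = 3L, CB = 4L)
  radii <- c(N = 1.75, CA = 2.0, C = 2.0, O = 1.55, CB = 1.5)
  if (is.null(density)) density <- rep(1, n)
  if (is.null(resi)) resi <- seq_len(n)
  if (is.null(odir)) {
    odir <- matrix(0, n, 3)
    odir[kinds == "O", 1] <- 1 # carbonyl direction +x by default
  }
  structure(list(coords = coords, kind = unname(kind_code[kinds]),
                 radius = unname(radii[kinds]), density = density,
                 resi = as.integer(resi), odir = odir, com = c(0, 0, 0),
                 n_res = n),
            class = "point_cloud")
}

translation <- function(t) list(R = diag(3), t = t)

# brute-force interface score of chain 1 against every other chain
brute_force_iscore <- function(asm) {
  total <- 0
  for (k in seq_along(asm$chains)[-1])
    total <- total + cubedock:::chain_pair_iscore(asm$chains[[1]],
                                                  asm$chains[[k]])
  total
}

# brute-force clash count of chain 1 against every other chain
brute_force_clashes <- function(asm, cfg = ccs_config()) {
  total <- 0
  c1 <- build_point_cloud(asm$chains[[1]], cfg)
  for (k in seq_along(asm$chains)[-1]) {
    ck <- build_point_cloud(asm$chains[[k]], cfg)
    v <- cubedock:::cpp_pair_terms(
      cubedock:::cloud_absolute(c1)$xyz, c1$kind, c1$radius, c1$density,
      c1$resi, cubedock:::cloud_absolute(c1)$odir,
      cubedock:::cloud_absolute(ck)$xyz, ck$kind, ck$radius, ck$density,
      ck$resi, cubedock:::cloud_absolute(ck)$odir,
      cubedock:::kernel_cfg(cfg), FALSE)
    total <- total + v[1]
  }
  total
}

rigid_move_assembly <- function(asm, R, t) {
  for (i in seq_along(asm$chains))
    asm$chains[[i]] <- transform_chain(asm$chains[[i]], R, t)
  asm
}
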