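# Atomic data model and PDB / score-manifest I/O.
#
# A chain_model holds one polypeptide chain as a data frame of atoms; an
# assembly is an ordered list of chains plus an optional cubic symmetry tag.
# Coordinates are Angstrom in a right-handed frame; the B-factor column
# carries per-residue pLDDT when structures come from a predictor.

ATOM_COLUMNS <- c("atom", "element", "resno", "resname",
                  "x", "y", "z", "bfactor", "occupancy")

# chain identifier pool for writing assemblies with more than 26 chains
CHAIN_ID_POOL <- c(LETTERS, letters, as.character(0:9))

#' Construct a single-chain structure model
#'
#' @param chain_id single-character chain label.
#' @param atoms data frame with columns `atom`, `element`, `resno`,
#'   `resname`, `x`, `y`, `z`, `bfactor`, `occupancy`.
#' @param validate check backbone completeness (every residue must have
#'   N, CA, C, O and a CB unless it is glycine) and monotone residue numbers.
#' @return an object of class `chain_model`.
#' @export
chain_model <- function(chain_id, atoms, validate = TRUE) {
  stopifnot(is.character(chain_id), nchar(chain_id) == 1)
  missing_cols <- setdiff(ATOM_COLUMNS, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, ATOM_COLUMNS]
  obj <- structure(list(chain_id = chain_id, atoms = atoms),
                   class = "chain_model")
  if (validate) validate_chain(obj)
  obj
}

validate_chain <- function(chain) {
  a <- chain$atoms
  if (nrow(a) == 0) stop("chain ", chain$chain_id, " has no atoms")
  if (!all(is.finite(c(a$x, a$y, a$z))))
    stop("chain ", chain$chain_id, " has non-finite coordinates")
  resnos <- unique(a$resno)
  if (any(diff(resnos) <= 0))
    stop("chain ", chain$chain_id, ": residue numbers not strictly increasing")
  for (r in resnos) {
    sel <- a$resno == r
    nm <- a$atom[sel]
    need <- c("N", "CA", "C", "O")
    if (!all(need %in% nm))
      stop("chain ", chain$chain_id, " residue ", r, " (", a$resname[sel][1],
           "): missing backbone atom ",
           paste(setdiff(need, nm), collapse = ","))
    if (a$resname[sel][1] != "GLY" && !("CB" %in% nm))
      stop("chain ", chain$chain_id, " residue ", r,
           ": non-glycine residue missing CB")
  }
  invisible(chain)
}

#' @export
print.chain_model <- function(x, ...) {
  cat("<chain_model> chain", x$chain_id, "-", n_residues(x), "residues,",
      nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' Number of residues in a chain
#' @param chain a `chain_model`.
#' @export
n_residues <- function(chain) length(unique(chain$atoms$resno))

#' Coordinate matrix of a chain
#'
#' @param chain a `chain_model`.
#' @param atoms optional atom-name filter (e.g. `"CA"`).
#' @return an n x 3 matrix.
#' @export
chain_coords <- function(chain, atoms = NULL) {
  a <- chain$atoms
  if (!is.null(atoms)) a <- a[a$atom %in% atoms, ]
  as.matrix(a[, c("x", "y", "z")])
}

#' Center of mass of a chain (unweighted atom centroid)
#' @param chain a `chain_model`.
#' @export
chain_com <- function(chain) colMeans(chain_coords(chain))

#' Apply a rigid transform to a chain
#'
#' @param chain a `chain_model`.
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation applied after the rotation.
#' @export
transform_chain <- function(chain, R = diag(3), t = c(0, 0, 0)) {
  xyz <- chain_coords(chain) %*% t(R)
  xyz <- sweep(xyz, 2, -t)
  chain$atoms$x <- xyz[, 1]; chain$atoms$y <- xyz[, 2]; chain$atoms$z <- xyz[, 3]
  chain
}

#' Construct a multi-chain assembly
#'
#' @param chains list of `chain_model` objects with unique chain ids.
#' @param symmetry optional cubic symmetry tag, one of "T", "O", "I".
#' @param center assembly center, defaults to the origin.
#' @return an object of class `assembly`.
#' @export
assembly <- function(chains, symmetry = NULL, center = c(0, 0, 0)) {
  if (length(chains) == 0) stop("assembly must contain at least one chain")
  ids <- vapply(chains, function(ch) ch$chain_id, "")
  if (anyDuplicated(ids)) stop("duplicate chain ids in assembly")
  if (!is.null(symmetry)) symmetry <- match.arg(symmetry, c("T", "O", "I"))
  structure(list(chains = chains, symmetry = symmetry, center = center),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat("<assembly>", length(x$chains), "chains",
      if (!is.null(x$symmetry)) paste0("(", x$symmetry, " symmetry)") else "",
      "\n")
  invisible(x)
}

#' Number of chains in an assembly
#' @param x an `assembly`.
#' @export
n_chains <- function(x) length(x$chains)

#' Read a structure from a PDB file
#'
#' Parses ATOM records (fixed-width PDB columns). Chains are split on chain
#' identifier changes and TER records and returned in file order. B-factors
#' are preserved to the 0.01 precision of the format.
#'
#' @param path path to a PDB file.
#' @param dialect only `"pdb"` is supported.
#' @param validate run backbone-completeness validation on every chain.
#' @return an [assembly()].
#' @export
read_structure <- function(path, dialect = "pdb", validate = TRUE) {
  dialect <- match.arg(dialect, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- which(startsWith(rec, "ATOM"))
  if (!length(keep)) stop("no ATOM records in ", path)
  parse_field <- function(ln, from, to) trimws(substr(ln, from, to))
  chains <- list(); cur <- NULL; cur_id <- NULL
  flush_chain <- function() {
    if (!is.null(cur) && length(cur)) {
      df <- do.call(rbind, cur)
      chains[[length(chains) + 1]] <<- chain_model(cur_id, df,
                                                  validate = validate)
    }
    cur <<- NULL
  }
  prev_line_was_ter <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "TER")) { flush_chain(); prev_line_was_ter <- TRUE; next }
    if (!startsWith(ln, "ATOM")) next
    ch <- substr(ln, 22, 22)
    if (is.null(cur) || !identical(ch, cur_id)) {
      flush_chain()
      cur_id <- ch
      cur <- list()
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    resno <- suppressWarnings(as.integer(parse_field(ln, 23, 26)))
    if (any(!is.finite(xyz)) || is.na(resno))
      stop("malformed ATOM record at line ", i, " of ", path)
    elem <- parse_field(ln, 77, 78)
    nm <- parse_field(ln, 13, 16)
    if (elem == "") elem <- substr(nm, 1, 1)
    occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
    bf <- suppressWarnings(as.numeric(substr(ln, 61, 66)))
    cur[[length(cur) + 1]] <- data.frame(
      atom = nm, element = elem, resno = resno,
      resname = parse_field(ln, 18, 20),
      x = xyz[1], y = xyz[2], z = xyz[3],
      bfactor = if (is.finite(bf)) bf else 0,
      occupancy = if (is.finite(occ)) occ else 1,
      stringsAsFactors = FALSE)
  }
  flush_chain()
  ids <- vapply(chains, function(ch) ch$chain_id, "")
  if (anyDuplicated(ids)) {
    # re-label duplicates from the pool, preserving file order
    pool <- setdiff(CHAIN_ID_POOL, ids)
    for (k in which(duplicated(ids))) {
      chains[[k]]$chain_id <- pool[1]
      pool <- pool[-1]
    }
  }
  assembly(chains)
}

#' Write an assembly to a PDB file
#'
#' Chains with ids longer than one character, or assemblies whose ids
#' collide, are relabelled from the pool `A-Z`, `a-z`, `0-9` (62 ids; cubic
#' assemblies need at most 60). Emits standard ATOM/TER/END records.
#'
#' @param x an [assembly()].
#' @param path output file path.
#' @export
write_assembly <- function(x, path) {
  if (!inherits(x, "assembly")) stop("x must be an assembly")
  if (length(x$chains) > length(CHAIN_ID_POOL))
    stop("cannot write more than ", length(CHAIN_ID_POOL), " chains")
  ids <- vapply(x$chains, function(ch) ch$chain_id, "")
  if (any(nchar(ids) != 1) || anyDuplicated(ids))
    ids <- CHAIN_ID_POOL[seq_along(x$chains)]
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (ci in seq_along(x$chains)) {
    a <- x$chains[[ci]]$atoms
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      nm <- a$atom[i]
      nm_field <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      writeLines(sprintf(
        "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, nm_field, a$resname[i], ids[ci], a$resno[i],
        a$x[i], a$y[i], a$z[i], a$occupancy[i], a$bfactor[i],
        a$element[i]), con)
    }
    writeLines(sprintf("TER   %5d      %-3s %1s%4d",
                       (serial + 1L) %% 100000L,
                       a$resname[nrow(a)], ids[ci], a$resno[nrow(a)]), con)
    serial <- serial + 1L
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a predictor score manifest
#'
#' The manifest is a JSON object mapping model file name to
#' `{plddt, ptm, iptm}`; `iptm` may be absent for monomer predictions.
#'
#' @param path path to a JSON manifest.
#' @return data frame with columns `model_id`, `mean_plddt`, `ptm`, `iptm`
#'   (NA when absent).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(raw)) stop("empty manifest: ", path)
  rows <- lapply(names(raw), function(id) {
    rec <- raw[[id]]
    plddt <- rec$plddt
    ptm <- rec$ptm
    iptm <- if (is.null(rec$iptm)) NA_real_ else rec$iptm
    if (is.null(plddt) || is.null(ptm))
      stop("manifest record ", id, " is missing plddt or ptm")
    if (plddt < 0 || plddt > 100)
      stop("manifest record ", id, ": plddt outside [0, 100]")
    if (ptm < 0 || ptm > 1)
      stop("manifest record ", id, ": ptm outside [0, 1]")
    if (!is.na(iptm) && (iptm < 0 || iptm > 1))
      stop("manifest record ", id, ": iptm outside [0, 1]")
    data.frame(model_id = id, mean_plddt = plddt, ptm = ptm, iptm = iptm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a predictor score manifest
#'
#' @param manifest data frame as returned by [read_manifest()].
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- list(plddt = manifest$mean_plddt[i], ptm = manifest$ptm[i])
    if (!is.na(manifest$iptm[i])) r$iptm <- manifest$iptm[i]
    r
  })
  names(recs) <- manifest$model_id
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
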