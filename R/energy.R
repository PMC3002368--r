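# Non-bonded energy model: a united-atom Lennard-Jones term capped at
# 2 kcal/mol per pair, plus an unscreened Coulomb term, with interatomic
# distances floored at 2 A. Residue pairs interact only when their CA atoms
# are less than 20 A apart, and interactions with solvent-exposed residues
# (>50% of reference accessible area) are scaled by 1/2. A geometric
# disulfide bonus applies when a patch contains two cysteines in bridge
# geometry.

KE_COULOMB <- 332.0637  # kcal * A / (mol * e^2)

default_energy_config <- function() {
  list(epsilon_r = 1, lj_cap = 2, r_floor = 2, pair_cutoff = 20,
       exposure_threshold = 0.5, exposure_scale = 0.5, e_ss = -10,
       kT = 0.593, damping = 0.9, tol = 1e-4, max_iter = 500L)
}

new_forcefield <- function(table, config = list()) {
  stopifnot(all(c("resid", "elety", "q", "a", "b", "eps") %in% names(table)))
  cfg <- utils::modifyList(default_energy_config(), config)
  structure(list(table = table,
                 index = paste(table$resid, table$elety),
                 config = cfg),
            class = "forcefield")
}

#' Load a non-bonded parameter table
#'
#' Whitespace-delimited text with columns RES ATOM q A_half B_half eps and
#' `#` comments. Pairwise coefficients use geometric combination:
#' A_ij = A_i * A_j, B_ij = B_i * B_j, eps_ij = sqrt(eps_i * eps_j). Rows
#' with RES `*` act as fallbacks for any residue type.
#'
#' @param path parameter file path.
#' @param config named list overriding energy-model settings (epsilon_r,
#'   lj_cap, r_floor, pair_cutoff, exposure_threshold, exposure_scale,
#'   e_ss, kT, damping, tol, max_iter).
#' @return object of class `forcefield`.
#' @export
load_forcefield <- function(path, config = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(sub("#.*$", "", readLines(path)))
  lines <- lines[nzchar(lines)]
  tok <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(tok) != 6)
  if (length(bad)) stop("malformed parameter row: ", lines[bad[1]])
  tab <- data.frame(
    resid = toupper(vapply(tok, `[`, "", 1)),
    elety = toupper(vapply(tok, `[`, "", 2)),
    q = as.numeric(vapply(tok, `[`, "", 3)),
    a = as.numeric(vapply(tok, `[`, "", 4)),
    b = as.numeric(vapply(tok, `[`, "", 5)),
    eps = as.numeric(vapply(tok, `[`, "", 6)),
    stringsAsFactors = FALSE)
  if (anyNA(tab[, 3:6])) stop("non-numeric parameter value in ", path)
  new_forcefield(tab, config)
}

#' The shipped synthetic united-atom parameter table
#'
#' Element-based Lennard-Jones parameters with simplified partial charges:
#' a synthetic stand-in for a statistical force field, sufficient to drive
#' the pipeline and fully reproducible from the package sources.
#'
#' @inheritParams load_forcefield
#' @return a `forcefield`.
#' @export
default_forcefield <- function(config = list()) {
  load_forcefield(system.file("extdata", "nb_params_synthetic.txt",
                              package = "patchsampler"), config)
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf("forcefield: %d typed atoms; eps_r=%g, lj_cap=%g, r_floor=%g, cutoff=%g\n",
              nrow(x$table), x$config$epsilon_r, x$config$lj_cap,
              x$config$r_floor, x$config$pair_cutoff))
  invisible(x)
}

# per-atom parameter lookup (exact residue+atom, then wildcard residue)
lookup_params <- function(ff, resid, elety) {
  i <- match(paste(resid, elety), ff$index)
  miss <- is.na(i)
  if (any(miss)) {
    i[miss] <- match(paste("*", elety[miss]), ff$index)
    if (anyNA(i))
      stop("no non-bonded parameters for: ",
           paste(unique(paste(resid, elety)[is.na(i)]), collapse = ", "))
  }
  ff$table[i, c("q", "a", "b", "eps")]
}

#' Solvent accessibility of every residue
#'
#' Rolling-probe (1.4 A) numerical accessible surface area per residue
#' (Shrake-Rupley sphere sampling), compared against the reference
#' extended-tripeptide totals; a residue is accessible when its ASA exceeds
#' 50% (`threshold`) of its reference area. Computed once on the unbound
#' protein.
#'
#' @param s a `pdb_structure`.
#' @param probe probe radius in Angstrom.
#' @param n_points sphere sample points per atom.
#' @param threshold accessibility ratio threshold.
#' @return data.frame (`exposure_map`): `reskey`, `resid`, `asa`,
#'   `reference`, `ratio`, `accessible`.
#' @export
compute_exposure <- function(s, probe = 1.4, n_points = 240,
                             threshold = 0.5) {
  a <- s$atoms
  n <- nrow(a)
  radii <- VDW_RADII[a$elem]
  radii[is.na(radii)] <- 1.8
  ext <- radii + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  # golden-spiral unit sphere points
  k <- seq_len(n_points)
  phi <- acos(1 - 2 * (k - 0.5) / n_points)
  theta <- pi * (1 + sqrt(5)) * (k - 0.5)
  pts <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  asa_atom <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (ext[i] + ext)^2 & seq_len(n) != i)
    sp <- sweep(pts * ext[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dj <- rowSums(sweep(sp[free, , drop = FALSE], 2, xyz[j, ])^2)
        free[free] <- dj >= ext[j]^2
      }
      frac <- sum(free) / n_points
    } else frac <- 1
    asa_atom[i] <- frac * 4 * pi * ext[i]^2
  }
  asa <- tapply(asa_atom, factor(a$reskey, levels = unique(a$reskey)), sum)
  rt <- residue_table(s)
  ref <- REFERENCE_ASA[rt$resid]
  ref[is.na(ref)] <- mean(REFERENCE_ASA)
  out <- data.frame(reskey = rt$reskey, resid = rt$resid,
                    asa = as.numeric(asa[rt$reskey]),
                    reference = as.numeric(ref), stringsAsFactors = FALSE)
  out$ratio <- out$asa / out$reference
  out$accessible <- out$ratio > threshold
  class(out) <- c("exposure_map", "data.frame")
  out
}

# an "atom set": coordinates + parameters + per-atom accessibility scale,
# with excluded (default-torsion) atoms dropped
atom_set <- function(atoms, ff, exposure = NULL) {
  if (is.null(atoms$reskey))
    atoms$reskey <- paste(atoms$chain, atoms$resno, atoms$icode,
                          sep = ".")
  drop <- rep(FALSE, nrow(atoms))
  for (rt in names(EXCLUDED_ENERGY_ATOMS))
    drop <- drop | (atoms$resid == rt &
                      atoms$elety %in% EXCLUDED_ENERGY_ATOMS[[rt]])
  atoms <- atoms[!drop, , drop = FALSE]
  p <- lookup_params(ff, atoms$resid, atoms$elety)
  sc <- rep(1, nrow(atoms))
  if (!is.null(exposure)) {
    acc <- exposure$accessible[match(atoms$reskey, exposure$reskey)]
    sc[which(acc)] <- ff$config$exposure_scale
  }
  list(xyz = as.matrix(atoms[, c("x", "y", "z")]), q = p$q, a = p$a,
       b = p$b, eps = p$eps, s = sc, reskey = atoms$reskey,
       resid = atoms$resid, elety = atoms$elety)
}

# raw per-pair energy matrix between two atom sets (no cutoff, no scaling)
energy_matrix <- function(A, B, config) {
  d2 <- outer(rowSums(A$xyz^2), rowSums(B$xyz^2), "+") -
    2 * A$xyz %*% t(B$xyz)
  r <- sqrt(pmax(d2, 0))
  r <- pmax(r, config$r_floor)
  lj <- pmin(sqrt(outer(A$eps, B$eps)) *
               (outer(A$a, B$a) / r^12 - outer(A$b, B$b) / r^6),
             config$lj_cap)
  coul <- KE_COULOMB * outer(A$q, B$q) / (config$epsilon_r * r)
  lj + coul
}

#' Non-bonded energy of a single atom pair
#'
#' The unit term of the energy model: distance floored at `r_floor`,
#' Lennard-Jones capped at `lj_cap`, plus Coulomb; the whole term is scaled
#' by `exposure_scale` when atom `j`'s residue is solvent-accessible.
#'
#' @param i,j one-row atom data.frames (columns `resid`, `elety`, `x`, `y`,
#'   `z`).
#' @param params a `forcefield`.
#' @param j_accessible is the residue of `j` solvent-accessible?
#' @return energy in kcal/mol.
#' @export
pair_energy <- function(i, j, params, j_accessible = FALSE) {
  A <- atom_set(i, params)
  B <- atom_set(j, params)
  if (!length(A$q) || !length(B$q)) return(0)  # excluded atom
  e <- energy_matrix(A, B, params$config)[1, 1]
  if (j_accessible) e <- e * params$config$exposure_scale
  e
}

#' Geometric disulfide-bridge bonus between two cysteines
#'
#' Returns `e_ss` (default -10 kcal/mol) when the SG-SG distance lies in
#' [1.8, 2.3] A and both CB-SG-SG angles lie in [90, 120] degrees, else 0.
#'
#' @param cys_a,cys_b atom data.frames of two CYS residues (SG and CB
#'   present).
#' @param e_ss bonus energy in kcal/mol.
#' @return kcal/mol.
#' @export
disulfide_term <- function(cys_a, cys_b, e_ss = -10) {
  stopifnot(cys_a$resid[1] == "CYS", cys_b$resid[1] == "CYS")
  sg_a <- as.numeric(cys_a[cys_a$elety == "SG", c("x", "y", "z")])
  sg_b <- as.numeric(cys_b[cys_b$elety == "SG", c("x", "y", "z")])
  cb_a <- as.numeric(cys_a[cys_a$elety == "CB", c("x", "y", "z")])
  cb_b <- as.numeric(cys_b[cys_b$elety == "CB", c("x", "y", "z")])
  if (!length(sg_a) || !length(sg_b)) return(0)
  d <- vnorm(sg_a - sg_b)
  if (d < 1.8 || d > 2.3) return(0)
  ang_a <- bond_angle(cb_a, sg_a, sg_b)
  ang_b <- bond_angle(cb_b, sg_b, sg_a)
  if (ang_a >= 90 && ang_a <= 120 && ang_b >= 90 && ang_b <= 120) e_ss
  else 0
}

# residue-level CA table for the 20 A interaction cutoff
residue_ca <- function(atoms) {
  ca <- atoms[atoms$elety == "CA", ]
  keys <- unique(atoms$reskey)
  if (!all(keys %in% ca$reskey)) stop("missing CA in residue(s): ",
      paste(setdiff(keys, ca$reskey), collapse = ","))
  m <- as.matrix(ca[match(keys, ca$reskey), c("x", "y", "z")])
  rownames(m) <- keys
  m
}

#' Total non-bonded energy of a patch conformation
#'
#' Sums the pair energy over all atoms of the patch against all atoms of
#' the protein carrying it, subject to the CA-CA `pair_cutoff`, with
#' patch-internal pairs counted once (their accessibility factors
#' averaged), intra-residue pairs closer than 4 bonds excluded, and the
#' defaulted-torsion atoms (LYS NZ; ARG CZ/NH1/NH2) omitted entirely. Any
#' disulfide bonus between two patch cysteines is added.
#'
#' @param conf_struct a `pdb_structure` of the whole protein with the
#'   conformation's side chains in place.
#' @param patch_reskeys residue keys of the patch members.
#' @param params a `forcefield`.
#' @param exposure an `exposure_map` computed on the unbound protein.
#' @return energy in kcal/mol.
#' @export
conformation_energy <- function(conf_struct, patch_reskeys, params,
                                exposure = NULL) {
  atoms <- conf_struct$atoms
  in_patch <- atoms$reskey %in% patch_reskeys
  ca_all <- residue_ca(atoms)
  P <- atom_set(atoms[in_patch, ], params, exposure)
  E <- atom_set(atoms[!in_patch, ], params, exposure)
  e <- nb_sum2(P, P, params$config, ca_all, dedup = TRUE, scale = "avg")
  if (length(E$q))
    e <- e + nb_sum2(P, E, params$config, ca_all, dedup = FALSE,
                     scale = "j")
  # disulfide check between patch cysteines
  cys <- unique(P$reskey[P$resid == "CYS"])
  if (length(cys) >= 2) {
    for (a in seq_len(length(cys) - 1)) for (b in seq(a + 1, length(cys)))
      e <- e + disulfide_term(atoms[atoms$reskey == cys[a], ],
                              atoms[atoms$reskey == cys[b], ],
                              params$config$e_ss)
  }
  e
}
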