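# Self-consistent mean field (SCMF) machinery. A patch becomes a
# "multi-copy" system: every effective residue simultaneously carries all
# its admissible rotamers, each weighted by a probability. Energies against
# the fixed surroundings (E_bb), within a rotamer (E_self) and between
# rotamers of different residues (E_pair) are precomputed once per patch;
# the mean-field iteration then reweights probabilities by Boltzmann
# factors of the effective energies until self-consistency. The filtering
# driver runs one SCMF per chi1 configuration and keeps that
# configuration's most probable (lowest effective energy) conformation.

# generalized pair sum modes used by the table builder:
#   dedup  - count unordered pairs once (A and B the same set)
#   scale  - "j": multiply by the j-side accessibility factor (patch vs
#            rest of protein); "avg": average both factors (both in patch)
nb_sum2 <- function(A, B, config, ca_all, dedup = FALSE, scale = "j") {
  if (!length(A$q) || !length(B$q)) return(0)
  e <- energy_matrix(A, B, config)
  ca_a <- ca_all[A$reskey, , drop = FALSE]
  ca_b <- ca_all[B$reskey, , drop = FALSE]
  d2 <- outer(rowSums(ca_a^2), rowSums(ca_b^2), "+") - 2 * ca_a %*% t(ca_b)
  mask <- d2 < config$pair_cutoff^2
  same_res <- outer(A$reskey, B$reskey, "==")
  if (any(same_res)) {
    for (k in which(colSums(same_res) > 0)) {
      rows <- which(same_res[, k])
      sep <- get_bond_separation(B$resid[k])
      pres <- rownames(sep)
      ii <- match(A$elety[rows], pres)
      jj <- match(B$elety[k], pres)
      if (is.na(jj)) next
      ok <- !is.na(ii)
      excl <- rep(FALSE, length(rows))
      excl[ok] <- sep[cbind(ii[ok], jj)] < 4
      mask[rows[excl], k] <- FALSE
    }
  }
  if (dedup) {
    key_a <- paste(A$reskey, A$elety)
    key_b <- paste(B$reskey, B$elety)
    u <- unique(c(key_a, key_b))
    mask <- mask & outer(match(key_a, u), match(key_b, u), "<")
  }
  sc <- if (scale == "avg")
    (outer(A$s, rep(1, length(B$s))) + outer(rep(1, length(A$s)), B$s)) / 2
  else outer(rep(1, length(A$s)), B$s)
  sum(e * sc * mask)
}

# atom set for one built rotamer of one residue
rotamer_atom_set <- function(reskey, res_type, coords, ff, exposure) {
  df <- data.frame(chain = "", resno = 0L, icode = "", resid = res_type,
                   elety = rownames(coords), x = coords[, 1],
                   y = coords[, 2], z = coords[, 3],
                   reskey = reskey, stringsAsFactors = FALSE)
  s <- atom_set(df, ff, exposure)
  # accessibility factor follows the residue's exposure classification
  if (!is.null(exposure)) {
    acc <- exposure$accessible[match(reskey, exposure$reskey)]
    if (isTRUE(acc)) s$s[] <- ff$config$exposure_scale
  }
  s
}

#' Build the multi-copy SCMF system of a patch
#'
#' Strips the side chains of the patch's effective residues from the
#' (unbound) protein, builds every admissible rotamer (library plus the
#' 0.6 A unbound supplement) on each residue's backbone, and precomputes
#' the energy tables: `e_bb` (rotamer vs all fixed atoms), `e_self`
#' (intra-rotamer), `e_pair` (rotamer-rotamer between residues), and
#' `e_fixed` (the conformation-independent part of the patch energy).
#'
#' @param patch a `patch` whose `members`/`effective` keys refer to
#'   `unbound`.
#' @param unbound the unbound `pdb_structure`.
#' @param lib a `rotamer_library`.
#' @param params a `forcefield`.
#' @param exposure an `exposure_map` of `unbound` (optional).
#' @param supplement_threshold RMSD threshold of the unbound supplement.
#' @return object of class `multicopy_system` with uniform probabilities.
#' @export
build_multicopy_system <- function(patch, unbound, lib, params,
                                   exposure = NULL,
                                   supplement_threshold = 0.6) {
  eff <- patch$effective
  atoms <- unbound$atoms
  ca_all <- residue_ca(atoms)
  rot_sets <- lapply(eff, function(k)
    residue_rotamers(get_residue(unbound, k), lib, supplement_threshold))
  names(rot_sets) <- eff
  # fixed frame: whole protein minus the effective side chains
  sc_of <- function(k, rt) atoms$reskey == k &
    !(atoms$elety %in% BACKBONE_ATOMS)
  drop <- rep(FALSE, nrow(atoms))
  for (k in eff) drop <- drop | sc_of(k)
  fixed <- atoms[!drop, ]
  in_patch <- fixed$reskey %in% patch$members
  FP <- atom_set(fixed[in_patch, ], params, exposure)
  FE <- atom_set(fixed[!in_patch, ], params, exposure)
  cfg <- params$config
  rot_atoms <- lapply(eff, function(k) {
    rs <- rot_sets[[k]]
    lapply(rs$coords, function(co)
      rotamer_atom_set(k, rs$res_type, co, params, exposure))
  })
  names(rot_atoms) <- eff
  n <- length(eff)
  e_bb <- vector("list", n)
  e_self <- vector("list", n)
  for (i in seq_len(n)) {
    e_bb[[i]] <- vapply(rot_atoms[[i]], function(R)
      nb_sum2(R, FP, cfg, ca_all, dedup = FALSE, scale = "avg") +
        nb_sum2(R, FE, cfg, ca_all, dedup = FALSE, scale = "j"),
      numeric(1))
    e_self[[i]] <- vapply(rot_atoms[[i]], function(R)
      nb_sum2(R, R, cfg, ca_all, dedup = TRUE, scale = "avg"), numeric(1))
  }
  e_pair <- vector("list", n)
  for (i in seq_len(n)) e_pair[[i]] <- vector("list", n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    Ri <- rot_atoms[[i]]
    Rj <- rot_atoms[[j]]
    m <- matrix(0, length(Ri), length(Rj))
    both_cys <- rot_sets[[i]]$res_type == "CYS" &&
      rot_sets[[j]]$res_type == "CYS"
    for (r in seq_along(Ri)) for (s in seq_along(Rj)) {
      v <- nb_sum2(Ri[[r]], Rj[[s]], cfg, ca_all, dedup = FALSE,
                   scale = "avg")
      if (both_cys) {
        ai <- data.frame(resid = "CYS", elety = Ri[[r]]$elety,
                         x = Ri[[r]]$xyz[, 1], y = Ri[[r]]$xyz[, 2],
                         z = Ri[[r]]$xyz[, 3])
        aj <- data.frame(resid = "CYS", elety = Rj[[s]]$elety,
                         x = Rj[[s]]$xyz[, 1], y = Rj[[s]]$xyz[, 2],
                         z = Rj[[s]]$xyz[, 3])
        v <- v + disulfide_term(ai, aj, cfg$e_ss)
      }
      m[r, s] <- v
    }
    e_pair[[i]][[j]] <- m
    e_pair[[j]][[i]] <- t(m)
  }
  e_fixed <- nb_sum2(FP, FP, cfg, ca_all, dedup = TRUE, scale = "avg") +
    nb_sum2(FP, FE, cfg, ca_all, dedup = FALSE, scale = "j")
  p <- lapply(rot_sets, function(rs)
    rep(1 / length(rs$chis), length(rs$chis)))
  structure(list(reskeys = eff,
                 res_types = vapply(rot_sets, `[[`, "", "res_type"),
                 rotamer_sets = rot_sets, e_bb = e_bb, e_self = e_self,
                 e_pair = e_pair, p = unname(p), e_fixed = e_fixed,
                 config = cfg, converged = FALSE),
            class = "multicopy_system")
}

#' Construct a multi-copy system directly from energy tables
#'
#' Mainly for testing and for abstract mean-field experiments detached from
#' any geometry.
#'
#' @param e_bb,e_self lists (one numeric vector per residue).
#' @param e_pair list-of-lists of matrices, `e_pair[[i]][[j]][r, s]`.
#' @param config energy configuration (kT, damping, tol, max_iter).
#' @return a `multicopy_system`.
#' @export
multicopy_from_tables <- function(e_bb, e_self = NULL, e_pair = NULL,
                                  config = default_energy_config()) {
  n <- length(e_bb)
  if (is.null(e_self)) e_self <- lapply(e_bb, function(v) numeric(length(v)))
  if (is.null(e_pair)) {
    e_pair <- vector("list", n)
    for (i in seq_len(n)) {
      e_pair[[i]] <- vector("list", n)
      for (j in seq_len(n)) if (j != i)
        e_pair[[i]][[j]] <- matrix(0, length(e_bb[[i]]), length(e_bb[[j]]))
    }
  }
  p <- lapply(e_bb, function(v) rep(1 / length(v), length(v)))
  structure(list(reskeys = paste0("R", seq_len(n)),
                 res_types = rep("UNK", n), rotamer_sets = NULL,
                 e_bb = e_bb, e_self = e_self, e_pair = e_pair, p = p,
                 e_fixed = 0, config = config, converged = FALSE),
            class = "multicopy_system")
}

#' Mean-field effective energy of one rotamer
#'
#' E_bb + E_self plus half the probability-weighted interaction with every
#' other residue's rotamer ensemble.
#'
#' @param sys a `multicopy_system`.
#' @param i residue index; @param r rotamer index.
#' @return kcal/mol.
#' @export
effective_energy <- function(sys, i, r) {
  if (i > length(sys$e_bb) || r > length(sys$e_bb[[i]]))
    stop("index out of range")
  e <- sys$e_bb[[i]][r] + sys$e_self[[i]][r]
  for (j in seq_along(sys$e_bb)) {
    if (j == i) next
    e <- e + 0.5 * sum(sys$p[[j]] * sys$e_pair[[i]][[j]][r, ])
  }
  unname(e)
}

# all effective energies of residue i as a vector
effective_energies <- function(sys, i) {
  e <- sys$e_bb[[i]] + sys$e_self[[i]]
  for (j in seq_along(sys$e_bb)) {
    if (j == i) next
    e <- e + 0.5 * as.numeric(sys$e_pair[[i]][[j]] %*% sys$p[[j]])
  }
  unname(e)
}

#' Mean energy of the multi-copy system
#'
#' Probability-weighted sum of the effective energies; with one-hot
#' probabilities this equals the rotamer-dependent part of the single
#' conformation's energy (the half factor in the effective energy
#' compensates double counting). Add `e_fixed` for the full patch energy.
#'
#' @param sys a `multicopy_system`.
#' @return kcal/mol.
#' @export
mean_energy <- function(sys) {
  sum(vapply(seq_along(sys$e_bb), function(i)
    sum(sys$p[[i]] * effective_energies(sys, i)), numeric(1)))
}

#' Effective free energy of the multi-copy system
#'
#' Mean energy plus `kT` times the negative rotamer entropy,
#' sum of p log p (0 log 0 = 0). Its minimizer over a single residue's
#' probabilities is the Boltzmann distribution at temperature kT.
#'
#' @param sys a `multicopy_system`.
#' @param kT thermal energy in kcal/mol.
#' @return kcal/mol.
#' @export
free_energy <- function(sys, kT = sys$config$kT) {
  ent <- sum(vapply(sys$p, function(p) {
    nz <- p > 0
    sum(p[nz] * log(p[nz]))
  }, numeric(1)))
  mean_energy(sys) + kT * ent
}

#' Run the SCMF iteration to convergence
#'
#' Synchronously reweights every residue's rotamer probabilities by the
#' Boltzmann factor of its current effective energies, mixes with the
#' previous probabilities (`p <- damping * p + (1 - damping) * p_new`), and
#' stops when the largest probability change drops below `tol`.
#'
#' @param sys a `multicopy_system`.
#' @param kT thermal energy (kcal/mol).
#' @param damping memory coefficient lambda in [0, 1); 0 is undamped.
#' @param tol convergence threshold on max |delta p|.
#' @param max_iter iteration cap.
#' @return the converged system (`converged`, `n_iter` set).
#' @export
scmf_iterate <- function(sys, kT = sys$config$kT,
                         damping = sys$config$damping,
                         tol = sys$config$tol,
                         max_iter = sys$config$max_iter) {
  n <- length(sys$e_bb)
  sizes <- lengths(sys$e_bb)
  active <- which(sizes > 1)
  if (!length(active)) {  # every residue one-hot already: a fixed point
    sys$converged <- TRUE
    sys$n_iter <- 0L
    return(sys)
  }
  # residues with a single admissible rotamer never move; fold their field
  # into a static base energy for each active residue
  base <- vector("list", n)
  for (i in active) {
    b <- sys$e_bb[[i]] + sys$e_self[[i]]
    for (j in seq_len(n)) {
      if (j == i || sizes[j] > 1) next
      b <- b + 0.5 * as.numeric(sys$e_pair[[i]][[j]] %*% sys$p[[j]])
    }
    base[[i]] <- b
  }
  for (it in seq_len(max_iter)) {
    delta <- 0
    p_new <- vector("list", n)
    for (i in active) {
      e <- base[[i]]
      for (j in active) if (j != i)
        e <- e + 0.5 * as.numeric(sys$e_pair[[i]][[j]] %*% sys$p[[j]])
      w <- exp(-(e - min(e)) / kT)
      p_new[[i]] <- w / sum(w)
    }
    for (i in active) {
      p_mix <- damping * sys$p[[i]] + (1 - damping) * p_new[[i]]
      p_mix <- p_mix / sum(p_mix)
      delta <- max(delta, max(abs(p_mix - sys$p[[i]])))
      sys$p[[i]] <- p_mix
    }
    if (delta < tol) {
      sys$converged <- TRUE
      sys$n_iter <- it
      return(sys)
    }
  }
  sys$converged <- FALSE
  sys$n_iter <- max_iter
  sys
}

#' @export
print.multicopy_system <- function(x, ...) {
  cat(sprintf("multicopy_system: %d residues, rotamers [%s], converged=%s\n",
              length(x$e_bb),
              paste(lengths(x$e_bb), collapse = ","),
              x$converged))
  invisible(x)
}

# restrict a system to per-residue rotamer index subsets (chi1 slots)
subset_system <- function(sys, idx) {
  n <- length(sys$e_bb)
  out <- sys
  for (i in seq_len(n)) {
    ii <- idx[[i]]
    out$e_bb[[i]] <- sys$e_bb[[i]][ii]
    out$e_self[[i]] <- sys$e_self[[i]][ii]
    out$p[[i]] <- rep(1 / length(ii), length(ii))
    if (!is.null(out$rotamer_sets)) {
      rs <- sys$rotamer_sets[[i]]
      out$rotamer_sets[[i]] <- list(
        res_type = rs$res_type, chis = rs$chis[ii],
        source = rs$source[ii], bins = rs$bins[ii],
        coords = rs$coords[ii], orig_index = ii)
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    out$e_pair[[i]][[j]] <-
      sys$e_pair[[i]][[j]][idx[[i]], idx[[j]], drop = FALSE]
  }
  out$converged <- FALSE
  out
}

#' Pick the most probable conformation of a converged system
#'
#' Per residue the rotamer of maximal probability (ties to the lowest
#' index); the conformation's energy is assembled from the precomputed
#' tables (equal to [conformation_energy()] on the built structure).
#'
#' @param sys a converged `multicopy_system` built from a patch.
#' @return object of class `patch_conformation`: chosen rotamer indices,
#'   side-chain coordinates per residue, chi1 bins, source tags, `energy`.
#' @export
select_conformation <- function(sys) {
  n <- length(sys$e_bb)
  pick <- vapply(seq_len(n), function(i) which.max(sys$p[[i]]), integer(1))
  conformation_from_indices(sys, pick)
}

# assemble a conformation (and its table energy) from explicit indices
conformation_from_indices <- function(sys, pick) {
  n <- length(sys$e_bb)
  e <- sys$e_fixed
  for (i in seq_len(n)) e <- e + sys$e_bb[[i]][pick[i]] +
      sys$e_self[[i]][pick[i]]
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i)
    e <- e + sys$e_pair[[i]][[j]][pick[i], pick[j]]
  coords <- NULL
  bins <- source <- chis <- NULL
  if (!is.null(sys$rotamer_sets)) {
    coords <- lapply(seq_len(n), function(i)
      sys$rotamer_sets[[i]]$coords[[pick[i]]])
    names(coords) <- sys$reskeys
    bins <- vapply(seq_len(n), function(i)
      sys$rotamer_sets[[i]]$bins[pick[i]], character(1))
    source <- vapply(seq_len(n), function(i)
      sys$rotamer_sets[[i]]$source[pick[i]], character(1))
    chis <- lapply(seq_len(n), function(i)
      sys$rotamer_sets[[i]]$chis[[pick[i]]])
  }
  structure(list(reskeys = sys$reskeys, res_types = sys$res_types,
                 rot_idx = pick, coords = coords, chis = chis,
                 bins = bins, source = source, energy = unname(e)),
            class = "patch_conformation")
}

#' @export
print.patch_conformation <- function(x, ...) {
  cat(sprintf("patch_conformation: %d residues, E = %.3f kcal/mol\n",
              length(x$reskeys), x$energy))
  invisible(x)
}

#' Enumerate the chi1 configurations of a patch
#'
#' The sampled conformational space is stratified by chi1: every standard
#' flexible residue contributes its non-empty chi1 bins (g+/t/g-),
#' histidine is sampled exhaustively (one slot per rotamer), and serine and
#' cysteine contribute a single free slot in which the SCMF sees all their
#' rotamers. The Cartesian product over residues defines the
#' configurations.
#'
#' @param rotamer_sets per-residue rotamer sets (supplemented), as stored
#'   in a `multicopy_system`.
#' @return list of configurations; each has `idx` (per-residue admissible
#'   rotamer indices) and `label`.
#' @export
enumerate_chi1_configurations <- function(rotamer_sets) {
  slots <- lapply(rotamer_sets, function(rs) {
    nr <- length(rs$chis)
    if (nr == 0) stop("residue with zero rotamers")
    if (rs$res_type == "HIS") {
      lapply(seq_len(nr), function(r)
        list(idx = r, label = sprintf("H%d", r)))
    } else if (rs$res_type %in% c("SER", "CYS")) {
      list(list(idx = seq_len(nr), label = "free"))
    } else {
      bins <- c("g+", "t", "g-")
      out <- list()
      for (b in bins) {
        ii <- which(rs$bins == b)
        if (length(ii)) out <- c(out, list(list(idx = ii, label = b)))
      }
      out
    }
  })
  configs <- list(list(idx = list(), label = character(0)))
  for (s in slots) {
    configs <- unlist(lapply(configs, function(cf)
      lapply(s, function(sl)
        list(idx = c(cf$idx, list(sl$idx)),
             label = c(cf$label, sl$label)))), recursive = FALSE)
  }
  lapply(configs, function(cf) {
    cf$label <- paste(cf$label, collapse = "/")
    cf
  })
}

#' SCMF-filter a patch: one conformation per chi1 configuration
#'
#' Builds the multi-copy system once, enumerates the chi1 configurations,
#' and for each runs the SCMF iteration over the restricted rotamer sets,
#' keeping the most probable conformation. Deterministic.
#'
#' @inheritParams build_multicopy_system
#' @param sys optionally a prebuilt `multicopy_system` (skips rebuilding).
#' @return list of `patch_conformation`s, one per configuration, each
#'   carrying `config_id` and `config_label`.
#' @export
filter_patch <- function(patch, unbound, lib, params, exposure = NULL,
                         supplement_threshold = 0.6, sys = NULL) {
  if (is.null(sys))
    sys <- build_multicopy_system(patch, unbound, lib, params, exposure,
                                  supplement_threshold)
  configs <- enumerate_chi1_configurations(sys$rotamer_sets)
  out <- vector("list", length(configs))
  for (k in seq_along(configs)) {
    sub <- subset_system(sys, configs[[k]]$idx)
    sub <- scmf_iterate(sub)
    conf <- select_conformation(sub)
    # map restricted indices back to the full sets
    conf$rot_idx <- vapply(seq_along(conf$rot_idx), function(i)
      configs[[k]]$idx[[i]][conf$rot_idx[i]], integer(1))
    conf$config_id <- k
    conf$config_label <- configs[[k]]$label
    out[[k]] <- conf
  }
  out
}
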