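# Evaluation constructs: measuring how well an ensemble approximates the
# bound conformation of a patch. Because bound and unbound backbones
# differ, two analysis-only grafts isolate the side-chain contribution:
# bound_UBB places the bound side chains on the unbound backbone
# (per-residue backbone superposition + exact CA translation), and
# rotamer_UBB places the library rotamer closest to bound_UBB. These use
# bound-state information and exist only to evaluate, never to predict.

# full-atom coordinate table of a patch: backbone (and fixed side chains)
# from the structure, effective side chains overridden by a conformation's
# or graft's coordinates when given
patch_coord_table <- function(structure, members, conf = NULL) {
  rows <- list()
  for (k in members) {
    res <- get_residue(structure, k)
    if (!is.null(conf) && k %in% names(conf$coords)) {
      bb <- res[res$elety %in% BACKBONE_ATOMS, c("reskey", "elety", "x",
                                                 "y", "z")]
      sc <- conf$coords[[k]]
      rows[[k]] <- rbind(bb, data.frame(
        reskey = k, elety = rownames(sc), x = sc[, 1], y = sc[, 2],
        z = sc[, 3], stringsAsFactors = FALSE))
    } else {
      rows[[k]] <- res[, c("reskey", "elety", "x", "y", "z")]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# match two patch atom tables into aligned coordinate matrices;
# key_map maps table-a residue keys to table-b keys (default identity)
match_atom_tables <- function(ta, tb, key_map = NULL) {
  keys_a <- if (is.null(key_map)) ta$reskey else unname(key_map[ta$reskey])
  ka <- paste(keys_a, ta$elety)
  kb <- paste(tb$reskey, tb$elety)
  i <- match(ka, kb)
  if (anyNA(i))
    stop("atom correspondence mismatch: ",
         paste(utils::head(ka[is.na(i)], 3), collapse = "; "))
  list(a = as.matrix(ta[, c("x", "y", "z")]),
       b = as.matrix(tb[i, c("x", "y", "z")]))
}

#' All-atom RMSD between two patch conformations
#'
#' In-place RMSD over all patch heavy atoms (backbone and side chains);
#' rows are matched by residue key and atom name.
#'
#' @param ta,tb patch atom tables (columns `reskey`, `elety`, `x`, `y`,
#'   `z`), e.g. from the internal table builders or subsets of
#'   `structure$atoms`.
#' @param key_map optional named vector mapping `ta` residue keys to `tb`
#'   keys.
#' @return RMSD in Angstrom.
#' @export
all_atom_patch_rmsd <- function(ta, tb, key_map = NULL) {
  m <- match_atom_tables(ta, tb, key_map)
  rmsd_coords(m$a, m$b)
}

#' Graft bound side chains onto the unbound backbone (bound_UBB)
#'
#' Per residue, the bound state is superposed onto the unbound state by a
#' least-squares fit of backbone atoms (N, CA, C, plus O when present in
#' both), the fitted transform is applied to the bound side chain, and the
#' residue is then translated so its CA coincides exactly with the unbound
#' CA.
#'
#' @param bound,unbound `pdb_structure`s.
#' @param members unbound residue keys of the patch.
#' @param key_map named vector mapping unbound keys to bound keys (default
#'   identity).
#' @return a `graft_conformation` (side-chain coordinates per residue on
#'   the unbound backbone, `construction = "bound_UBB"`).
#' @export
build_bound_ubb <- function(bound, unbound, members, key_map = NULL) {
  coords <- list()
  types <- character(0)
  for (k in members) {
    kb <- if (is.null(key_map)) k else unname(key_map[k])
    ru <- get_residue(unbound, k)
    rb <- get_residue(bound, kb)
    if (ru$resid[1] != rb$resid[1])
      stop("residue type mismatch at ", k, ": ", ru$resid[1], " vs ",
           rb$resid[1])
    sc_names <- intersect(sidechain_atoms(rb$resid[1]), rb$elety)
    if (!length(sc_names)) next
    bb_names <- intersect(intersect(BACKBONE_ATOMS, rb$elety), ru$elety)
    mb <- residue_coords(rb, bb_names)
    mu <- residue_coords(ru, bb_names)
    sb <- residue_coords(rb, sc_names)
    fit <- superpose_coords(mb, mu, apply_to = sb)
    sc <- fit$coords
    # exact CA coincidence
    shift <- residue_coords(ru, "CA") -
      superpose_coords(mb, mu, apply_to = residue_coords(rb, "CA"))$coords
    sc <- sweep(sc, 2, as.numeric(shift), "+")
    rownames(sc) <- sc_names
    coords[[k]] <- sc
    types <- c(types, rb$resid[1])
  }
  structure(list(reskeys = names(coords), res_types = types,
                 coords = coords, construction = "bound_UBB"),
            class = c("graft_conformation"))
}

#' Closest-rotamer graft on the unbound backbone (rotamer_UBB)
#'
#' For every effective patch residue, the supplemented rotamer set (library
#' plus the 0.6 A unbound supplement) is built on the unbound backbone and
#' the rotamer with minimal in-place side-chain RMSD to the bound_UBB side
#' chain is kept. Non-effective members keep their unbound side chain.
#'
#' @param bound_ubb a `graft_conformation` from [build_bound_ubb()].
#' @param unbound the unbound `pdb_structure`.
#' @param lib a `rotamer_library`.
#' @param supplement_threshold RMSD threshold of the unbound supplement.
#' @return a `graft_conformation` with `construction = "rotamer_UBB"` and
#'   per-residue `source` tags.
#' @export
build_rotamer_ubb <- function(bound_ubb, unbound, lib,
                              supplement_threshold = 0.6) {
  coords <- list()
  types <- character(0)
  source <- character(0)
  for (k in bound_ubb$reskeys) {
    ru <- get_residue(unbound, k)
    rt <- ru$resid[1]
    target <- bound_ubb$coords[[k]]
    if (!(rt %in% FLEXIBLE_TYPES)) {
      sc_names <- intersect(sidechain_atoms(rt), ru$elety)
      coords[[k]] <- residue_coords(ru, sc_names)
      types <- c(types, rt)
      source <- c(source, "native")
      next
    }
    rs <- residue_rotamers(ru, lib, supplement_threshold)
    nm <- intersect(rownames(rs$coords[[1]]), rownames(target))
    rmsds <- vapply(rs$coords, function(co)
      rmsd_coords(co[nm, , drop = FALSE], target[nm, , drop = FALSE]),
      numeric(1))
    best <- which.min(rmsds)
    coords[[k]] <- rs$coords[[best]]
    types <- c(types, rt)
    source <- c(source, rs$source[best])
  }
  structure(list(reskeys = names(coords), res_types = types,
                 coords = coords, source = source,
                 construction = "rotamer_UBB"),
            class = c("graft_conformation"))
}

#' Best pick of an ensemble against a reference
#'
#' The ensemble member with minimal all-atom patch RMSD to the (superposed)
#' bound reference; ties go to the lowest index.
#'
#' @param ens a `patch_ensemble`.
#' @param reference_table bound patch atom table, already in the unbound
#'   frame.
#' @param unbound the unbound `pdb_structure`.
#' @param members patch member keys (unbound).
#' @param key_map optional unbound-to-bound key map.
#' @return list `index`, `rmsd`, and the per-member `rmsds` vector.
#' @export
best_pick <- function(ens, reference_table, unbound, members,
                      key_map = NULL) {
  # atom matching is identical across members: resolve it once on the
  # first member, then swap side-chain coordinates in place
  first <- ens$members[[1]]
  t0 <- patch_coord_table(unbound, members, first)
  mm <- match_atom_tables(t0, reference_table, key_map)
  ref <- mm$b
  slots <- lapply(names(first$coords), function(k) {
    sc <- first$coords[[k]]
    rows <- which(t0$reskey == k & t0$elety %in% rownames(sc))
    list(rows = rows, ord = match(t0$elety[rows], rownames(sc)), key = k)
  })
  rmsds <- vapply(ens$members, function(m) {
    X <- mm$a
    for (s in slots)
      X[s$rows, ] <- m$coords[[s$key]][s$ord, , drop = FALSE]
    sqrt(mean(rowSums((X - ref)^2)))
  }, numeric(1))
  list(index = which.min(rmsds), rmsd = min(rmsds), rmsds = rmsds)
}

#' Evaluate one patch ensemble against the bound conformation
#'
#' Superposes the bound patch onto the unbound patch once (least-squares on
#' backbone atoms; this also yields the backbone-change RMSD), then scores
#' every ensemble member, the unbound conformation and the two grafts by
#' in-place all-atom RMSD against the superposed bound reference.
#'
#' @param ens a `patch_ensemble`.
#' @param patch the `patch` (member keys refer to `unbound`).
#' @param unbound,bound `pdb_structure`s.
#' @param lib the `rotamer_library` used for the rotamer_UBB graft.
#' @param key_map optional named vector mapping unbound keys to bound keys.
#' @return one-row data.frame (`patch_report`): backbone_rmsd,
#'   rmsd_unbound_to_bound, best_pick_rmsd, best_pick_index,
#'   rmsd_boundUBB_to_rotamerUBB, rmsd_bound_to_boundUBB,
#'   rmsd_bound_to_rotamerUBB, ensemble_size.
#' @export
evaluate_patch <- function(ens, patch, unbound, bound, lib,
                           key_map = NULL) {
  members <- patch$members
  tu <- patch_coord_table(unbound, members)
  keys_b <- if (is.null(key_map)) members else unname(key_map[members])
  tb <- bound$atoms[bound$atoms$reskey %in% keys_b,
                    c("reskey", "elety", "x", "y", "z")]
  # one global backbone superposition of bound onto unbound
  bb_u <- tu[tu$elety %in% BACKBONE_ATOMS, ]
  m <- match_atom_tables(bb_u, tb, key_map)
  fit <- superpose_coords(m$b, m$a, apply_to = as.matrix(tb[, c("x", "y",
                                                                "z")]))
  tb[, c("x", "y", "z")] <- fit$coords
  backbone_rmsd <- superpose_coords(m$b, m$a)$rmsd
  rmsd_ub <- all_atom_patch_rmsd(tu, tb, key_map)
  bp <- best_pick(ens, tb, unbound, members, key_map)
  bubb <- build_bound_ubb(structure_from_atoms(
    cbind(bound$atoms[bound$atoms$reskey %in% keys_b,
                      c("chain", "resno", "icode", "resid", "elety",
                        "occ")],
          tb[, c("x", "y", "z")])[, c("chain", "resno", "icode", "resid",
                                      "elety", "x", "y", "z", "occ")],
    id = "bound_fit"), unbound, members, key_map)
  rubb <- build_rotamer_ubb(bubb, unbound, lib)
  t_bubb <- patch_coord_table(unbound, members, bubb)
  t_rubb <- patch_coord_table(unbound, members, rubb)
  data.frame(
    backbone_rmsd = backbone_rmsd,
    rmsd_unbound_to_bound = rmsd_ub,
    best_pick_rmsd = bp$rmsd,
    best_pick_index = bp$index,
    rmsd_boundUBB_to_rotamerUBB = all_atom_patch_rmsd(t_bubb, t_rubb),
    rmsd_bound_to_boundUBB = all_atom_patch_rmsd(t_bubb, tb, key_map),
    rmsd_bound_to_rotamerUBB = all_atom_patch_rmsd(t_rubb, tb, key_map),
    ensemble_size = length(ens$members))
}

#' Summarize patch reports over thresholds
#'
#' @param reports data.frame of patch reports (rbind of
#'   [evaluate_patch()] rows).
#' @param thresholds RMSD thresholds in Angstrom.
#' @return list with `threshold_counts` (count and fraction of patches with
#'   best pick within each threshold), `n_improved` (best pick strictly
#'   better than unbound), `mean_improvement` (mean of unbound minus best
#'   pick RMSD), and `by_backbone_band` (same statistics within backbone
#'   change bands <=1, 1-2, >2 A).
#' @export
summarize_cases <- function(reports, thresholds = c(1, 1.4, 2)) {
  stopifnot(nrow(reports) >= 1)
  tc <- data.frame(threshold = thresholds,
                   count = vapply(thresholds, function(t)
                     sum(reports$best_pick_rmsd <= t), numeric(1)))
  tc$fraction <- tc$count / nrow(reports)
  impr <- reports$rmsd_unbound_to_bound - reports$best_pick_rmsd
  band <- cut(reports$backbone_rmsd, c(-Inf, 1, 2, Inf),
              labels = c("<=1A", "1-2A", ">2A"))
  by_band <- do.call(rbind, lapply(levels(band), function(b) {
    ii <- which(band == b)
    data.frame(band = b, n = length(ii),
               within_1A = sum(reports$best_pick_rmsd[ii] <= 1),
               mean_improvement = if (length(ii)) mean(impr[ii]) else NA)
  }))
  list(n = nrow(reports), threshold_counts = tc,
       n_improved = sum(impr > 0), mean_improvement = mean(impr),
       by_backbone_band = by_band)
}
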