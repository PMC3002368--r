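# End-to-end drivers: interface -> patches -> rotamer enumeration -> SCMF
# filtering -> clustering -> final ensemble, plus evaluation against the
# bound state.

#' The unbound conformation of a patch as an ensemble member
#'
#' Wraps the observed unbound side chains of the effective residues
#' (atoms reordered to topology order so the atom correspondence with
#' built conformations is exact) and computes their patch energy.
#'
#' @param patch a `patch` with unbound keys.
#' @param unbound the unbound `pdb_structure`.
#' @param params a `forcefield`; @param exposure optional `exposure_map`.
#' @return a `patch_conformation` with source "unbound".
#' @export
unbound_conformation <- function(patch, unbound, params, exposure = NULL) {
  eff <- patch$effective
  coords <- lapply(eff, function(k) {
    res <- get_residue(unbound, k)
    residue_coords(res, intersect(sidechain_atoms(res$resid[1]),
                                  res$elety))
  })
  names(coords) <- eff
  types <- vapply(eff, function(k)
    get_residue(unbound, k)$resid[1], character(1))
  e <- conformation_energy(unbound, patch$members, params, exposure)
  structure(list(reskeys = eff, res_types = unname(types),
                 rot_idx = rep(NA_integer_, length(eff)), coords = coords,
                 chis = NULL, bins = NULL,
                 source = rep("unbound", length(eff)), energy = e),
            class = "patch_conformation")
}

#' Materialize a conformation as a full structure
#'
#' Replaces the side chains of the conformation's residues inside the
#' unbound protein, yielding a structure suitable for
#' [conformation_energy()] or [write_pdb()].
#'
#' @param conf a `patch_conformation`.
#' @param unbound the unbound `pdb_structure`.
#' @return a `pdb_structure`.
#' @export
conformation_structure <- function(conf, unbound) {
  s <- unbound
  for (k in names(conf$coords)) {
    res <- get_residue(s, k)
    bb <- res[res$elety %in% BACKBONE_ATOMS, ]
    sc <- conf$coords[[k]]
    scdf <- bb[rep(1, nrow(sc)), ]
    scdf$elety <- rownames(sc)
    scdf$x <- sc[, 1]
    scdf$y <- sc[, 2]
    scdf$z <- sc[, 3]
    s <- replace_residue(s, k, rbind(bb, scdf))
  }
  s
}

#' Translate a patch's residue keys from bound to unbound numbering
#'
#' @param patch a `patch` built on the bound structure.
#' @param mapping a `case_mapping` (bound -> unbound pairs).
#' @return the patch with `members`/`effective` rewritten to unbound keys.
#' @export
map_patch_keys <- function(patch, mapping) {
  m <- stats::setNames(mapping$pairs$unbound, mapping$pairs$bound)
  if (anyNA(m[patch$members]))
    stop("patch member(s) unmapped in the unbound structure")
  patch$members <- unname(m[patch$members])
  patch$effective <- unname(m[patch$effective])
  patch
}

#' Generate the docking ensemble of one patch
#'
#' Runs the full per-patch procedure on the unbound protein: supplemented
#' rotamer sets, SCMF filtering stratified by chi1 configuration, k-means
#' reduction to at most `k` minimum-energy representatives, and the unbound
#' conformation appended.
#'
#' @param patch a `patch` whose keys refer to `unbound`.
#' @param unbound the unbound `pdb_structure`.
#' @param lib a `rotamer_library`; @param params a `forcefield`.
#' @param exposure optional `exposure_map` (computed on `unbound` if NULL).
#' @param k cluster count; @param seed clustering seed.
#' @param supplement_threshold unbound-supplement RMSD threshold (A).
#' @return a `patch_ensemble`; attributes carry the `space_size` counts
#'   and the filtered-set size.
#' @export
sample_patch <- function(patch, unbound, lib, params, exposure = NULL,
                         k = 50L, seed = 0L, supplement_threshold = 0.6) {
  if (is.null(exposure)) exposure <- compute_exposure(unbound)
  sys <- build_multicopy_system(patch, unbound, lib, params, exposure,
                                supplement_threshold)
  confs <- filter_patch(patch, unbound, lib, params, exposure,
                        supplement_threshold, sys = sys)
  clusters <- kmeans_cluster(confs, k, seed)
  reps <- select_representatives(confs, clusters)
  unb <- unbound_conformation(patch, unbound, params, exposure)
  ens <- finalize_ensemble(reps, unb)
  attr(ens, "space_size") <- count_spaces(sys$rotamer_sets)
  attr(ens, "n_filtered") <- length(confs)
  ens
}

#' Run the pipeline on one side of a docking case
#'
#' Detects the interface on the bound structures, constructs the patches
#' there, transfers them to the unbound protein, samples an ensemble per
#' patch and evaluates it against the bound conformation.
#'
#' @param bound,unbound `pdb_structure`s of the protein carrying the
#'   patches (bound and unbound states).
#' @param partner_bound `pdb_structure` of the bound docking partner (used
#'   only for interface detection).
#' @param lib a `rotamer_library`; @param params a `forcefield`.
#' @param k cluster count; @param seed clustering seed.
#' @param mapping optional `case_mapping` (bound -> unbound); identity
#'   keys assumed if NULL.
#' @param interface_cutoff interface distance cutoff (A).
#' @return list: `patches`, `ensembles`, `reports` (one evaluation row per
#'   patch), `interface` keys.
#' @export
run_case <- function(bound, unbound, partner_bound, lib, params,
                     k = 50L, seed = 0L, mapping = NULL,
                     interface_cutoff = 6) {
  iface <- interface_residues(bound, partner_bound, interface_cutoff)
  patches <- build_patches(bound, iface)
  key_map <- NULL
  if (!is.null(mapping)) {
    patches <- lapply(patches, map_patch_keys, mapping = mapping)
    key_map <- stats::setNames(mapping$pairs$bound, mapping$pairs$unbound)
  }
  exposure <- compute_exposure(unbound)
  ensembles <- lapply(patches, sample_patch, unbound = unbound, lib = lib,
                      params = params, exposure = exposure, k = k,
                      seed = seed)
  reports <- do.call(rbind, lapply(seq_along(patches), function(i)
    evaluate_patch(ensembles[[i]], patches[[i]], unbound, bound, lib,
                   key_map = key_map)))
  list(patches = patches, ensembles = ensembles, reports = reports,
       interface = iface)
}

#' Write an ensemble as a multi-MODEL PDB plus manifest
#'
#' One MODEL per ensemble member (patch atoms only), REMARK lines carrying
#' member index, source, cluster and energy; the manifest is written as TSV
#' next to it when `manifest_path` is given.
#'
#' @param ens a `patch_ensemble`; @param patch its `patch`.
#' @param unbound the unbound `pdb_structure`.
#' @param path output PDB path; @param manifest_path optional TSV path.
#' @return invisibly, `path`.
#' @export
write_ensemble_pdb <- function(ens, patch, unbound, path,
                               manifest_path = NULL) {
  meta <- unbound$atoms[, c("reskey", "chain", "resno", "icode", "resid")]
  meta <- meta[!duplicated(meta$reskey), ]
  models <- lapply(ens$members, function(m) {
    tab <- patch_coord_table(unbound, patch$members, m)
    i <- match(tab$reskey, meta$reskey)
    structure_from_atoms(data.frame(
      chain = meta$chain[i], resno = meta$resno[i], icode = meta$icode[i],
      resid = meta$resid[i], elety = tab$elety, x = tab$x, y = tab$y,
      z = tab$z, occ = 1, stringsAsFactors = FALSE), id = "member")
  })
  man <- ensemble_manifest(ens)
  remarks <- sprintf("member %d source=%s cluster=%s E=%.4f", man$member,
                     man$source, man$cluster, man$energy)
  write_pdb(models, path, remarks = remarks)
  if (!is.null(manifest_path))
    utils::write.table(man, manifest_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(path)
}
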