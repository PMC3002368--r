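# Ensemble reduction: the SCMF-filtered conformations (one per chi1
# configuration) are clustered by k-means on side-chain coordinates (the
# backbone is shared, so Euclidean distance in the flattened coordinate
# space is proportional to side-chain RMSD), the minimum-energy member of
# each cluster is kept, and the unbound conformation is appended.

# flatten the side-chain coordinates of a conformation into one vector;
# atom correspondence across conformations of a patch is exact by
# construction (same residues, same topology order)
conformation_features <- function(conf) {
  as.numeric(t(do.call(rbind, conf$coords)))
}

#' Side-chain RMSD between two conformations of the same patch
#'
#' In-place root-mean-square deviation over the side-chain heavy atoms
#' (backbone excluded: it is identical in all conformations of a patch).
#'
#' @param a,b `patch_conformation` objects of the same patch.
#' @return RMSD in Angstrom.
#' @export
sidechain_rmsd <- function(a, b) {
  ca <- do.call(rbind, a$coords)
  cb <- do.call(rbind, b$coords)
  if (nrow(ca) != nrow(cb) ||
      !identical(unlist(lapply(a$coords, rownames)),
                 unlist(lapply(b$coords, rownames))))
    stop("atom correspondence mismatch between conformations")
  rmsd_coords(ca, cb)
}

# deterministic k-means (Lloyd) with farthest-point seeding; convergence
# when assignments stabilize
lloyd_kmeans <- function(x, k, seed, max_iter = 100L) {
  n <- nrow(x)
  set.seed(seed)
  centers_idx <- sample.int(n, 1)
  d2min <- rowSums(sweep(x, 2, x[centers_idx, ])^2)
  while (length(centers_idx) < k) {
    nxt <- which.max(d2min)
    centers_idx <- c(centers_idx, nxt)
    d2min <- pmin(d2min, rowSums(sweep(x, 2, x[nxt, ])^2))
  }
  centers <- x[centers_idx, , drop = FALSE]
  assign_old <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
      2 * x %*% t(centers)
    assignment <- max.col(-d2, ties.method = "first")
    if (identical(assignment, assign_old)) break
    assign_old <- assignment
    for (c in unique(assignment))
      centers[c, ] <- colMeans(x[assignment == c, , drop = FALSE])
  }
  assignment
}

#' Cluster patch conformations by k-means on side-chain coordinates
#'
#' With `n <= k` every conformation is its own cluster. Otherwise Lloyd
#' k-means runs on the flattened side-chain coordinates (equivalent to
#' clustering under side-chain RMSD up to the constant sqrt(n_atoms)
#' factor), seeded deterministically: the first center drawn from `seed`,
#' the rest by farthest-point.
#'
#' @param confs list of `patch_conformation`s.
#' @param k target cluster count (50).
#' @param seed integer seed for the initial center.
#' @return integer vector of cluster labels (1..k).
#' @export
kmeans_cluster <- function(confs, k = 50L, seed = 0L) {
  if (!length(confs)) stop("no conformations to cluster")
  n <- length(confs)
  if (n <= k) return(seq_len(n))
  x <- do.call(rbind, lapply(confs, conformation_features))
  lloyd_kmeans(x, k, seed)
}

#' Minimum-energy representative of each cluster
#'
#' @param confs list of `patch_conformation`s.
#' @param clusters integer cluster labels from [kmeans_cluster()].
#' @return list of representatives (one per non-empty cluster, in cluster
#'   label order), each annotated with its `cluster` id.
#' @export
select_representatives <- function(confs, clusters) {
  stopifnot(length(confs) == length(clusters))
  reps <- list()
  for (c in sort(unique(clusters))) {
    ii <- which(clusters == c)
    en <- vapply(confs[ii], `[[`, numeric(1), "energy")
    best <- ii[which.min(en)]
    r <- confs[[best]]
    r$cluster <- c
    reps <- c(reps, list(r))
  }
  reps
}

#' Assemble the final docking ensemble of a patch
#'
#' Representatives plus the unbound conformation (always appended, never
#' deduplicated; a coincidence with a representative is flagged).
#'
#' @param reps list of representatives.
#' @param unbound_conf the unbound `patch_conformation`.
#' @return object of class `patch_ensemble` with `members` (unbound last)
#'   and `unbound_duplicated` flag.
#' @export
finalize_ensemble <- function(reps, unbound_conf) {
  dup <- any(vapply(reps, function(r)
    isTRUE(all.equal(conformation_features(r),
                     conformation_features(unbound_conf),
                     tolerance = 1e-9)), logical(1)))
  unbound_conf$cluster <- NA_integer_
  structure(list(members = c(reps, list(unbound_conf)),
                 n_representatives = length(reps),
                 unbound_duplicated = dup),
            class = "patch_ensemble")
}

#' @export
print.patch_ensemble <- function(x, ...) {
  cat(sprintf("patch_ensemble: %d members (%d representatives + unbound)%s\n",
              length(x$members), x$n_representatives,
              if (x$unbound_duplicated) " [unbound duplicates a representative]"
              else ""))
  invisible(x)
}

#' Tabular manifest of an ensemble
#'
#' @param ens a `patch_ensemble`.
#' @return data.frame: member index, source, chi1-configuration label,
#'   cluster id, energy (kcal/mol).
#' @export
ensemble_manifest <- function(ens) {
  data.frame(
    member = seq_along(ens$members),
    source = vapply(ens$members, function(m)
      if (is.na(m$cluster[1])) "unbound" else "representative", ""),
    config = vapply(ens$members, function(m)
      if (is.null(m$config_label)) "" else m$config_label, ""),
    cluster = vapply(ens$members, function(m)
      if (is.null(m$cluster)) NA_integer_ else m$cluster, NA_integer_),
    energy = vapply(ens$members, `[[`, numeric(1), "energy"),
    stringsAsFactors = FALSE)
}
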