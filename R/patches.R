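# Interface detection and surface-patch construction. Patches are spheres
# around interface atoms, grown until they hold 8 or 9 effective (non-ALA,
# non-GLY) interface residues; extra patches centered at CA atoms cover any
# interface residue the stride-64 centers missed.

#' Interface residues of one protein against its partner
#'
#' A residue of `a` is interfacial when at least one of its atoms lies
#' within `cutoff` (6 A) of any atom of `b`.
#'
#' @param a,b `pdb_structure` objects (the two bound partners).
#' @param cutoff distance cutoff in Angstrom.
#' @return character vector of residue keys of `a`, in file order.
#' @export
interface_residues <- function(a, b, cutoff = 6) {
  xa <- as.matrix(a$atoms[, c("x", "y", "z")])
  xb <- as.matrix(b$atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  near <- sqrt(pmax(d2, 0)) <= cutoff
  keys <- unique(a$atoms$reskey[apply(near, 1, any)])
  keys[order(match(keys, a$atoms$reskey))]
}

#' Stride-64 patch centers along the interface atom list
#'
#' One patch center is placed at every 64th position of the interface atom
#' list (in structure file order), starting at the first atom; an average
#' residue holds about 8 heavy atoms, so this spacing yields roughly one
#' center per 8 residues.
#'
#' @param interface_atoms data.frame of interface atoms in file order.
#' @param stride spacing in atoms.
#' @return the center atom rows (subset of `interface_atoms`).
#' @export
place_patch_centers <- function(interface_atoms, stride = 64L) {
  if (!nrow(interface_atoms)) stop("empty interface: no atoms")
  interface_atoms[seq(1, nrow(interface_atoms), by = stride), ,
                  drop = FALSE]
}

# minimum atom distance from a point to each listed residue
min_dist_to_residues <- function(center, structure, reskeys) {
  a <- structure$atoms[structure$atoms$reskey %in% reskeys, ]
  d <- sqrt(rowSums(sweep(as.matrix(a[, c("x", "y", "z")]), 2, center)^2))
  dmin <- tapply(d, factor(a$reskey, levels = unique(a$reskey)), min)
  dmin[order(match(names(dmin), structure$atoms$reskey))]
}

#' Grow a patch sphere around a center atom
#'
#' The radius is searched on a 0.25 A grid from `r_start` for the smallest
#' value at which the sphere holds 8 or 9 effective interface residues
#' (any-heavy-atom membership); if the count jumps from below 8 to above 9
#' between grid steps, the search bisects to 0.01 A. If no radius admits 8
#' or 9 residues, the radius with effective count nearest 8.5 is returned
#' with `degenerate = TRUE`. Members are all interface residues (ALA and
#' GLY included) with an atom inside the sphere.
#'
#' @param center numeric 3-vector (or one-row atom data.frame), the patch
#'   center.
#' @param interface residue keys of the interface.
#' @param structure the `pdb_structure` carrying the interface.
#' @param r_start,r_step radius grid origin and spacing in Angstrom.
#' @return object of class `patch`: center, radius, `members`,
#'   `effective`, `size` (A), `degenerate`.
#' @export
grow_patch <- function(center, interface, structure, r_start = 3,
                       r_step = 0.25) {
  if (is.data.frame(center)) {
    center_key <- paste(center$reskey[1], center$elety[1])
    center <- as.numeric(center[1, c("x", "y", "z")])
  } else center_key <- NA_character_
  rt <- residue_table(structure)
  eff_keys <- rt$reskey[rt$is_effective]
  dmin <- min_dist_to_residues(center, structure, interface)
  is_eff <- names(dmin) %in% eff_keys
  count_at <- function(r) sum(dmin[is_eff] <= r)
  d_eff <- sort(unname(dmin[is_eff]))
  if (length(d_eff) < 8) {
    r <- max(d_eff, r_start)
    degen <- TRUE
  } else {
    degen <- FALSE
    grid <- seq(r_start, max(d_eff) + r_step, by = r_step)
    counts <- vapply(grid, count_at, numeric(1))
    hit <- which(counts %in% c(8, 9))
    if (length(hit)) {
      r <- grid[hit[1]]
    } else {
      jump <- which(counts > 9)[1]
      r <- NA_real_
      if (!is.na(jump) && jump > 1) {
        fine <- seq(grid[jump - 1], grid[jump], by = 0.01)
        fc <- vapply(fine, count_at, numeric(1))
        fhit <- which(fc %in% c(8, 9))
        if (length(fhit)) r <- fine[fhit[1]]
      }
      if (is.na(r)) {  # still impossible: nearest count to 8.5
        allr <- sort(unique(c(grid, d_eff)))
        ac <- vapply(allr, count_at, numeric(1))
        r <- allr[which.min(abs(ac - 8.5))]
        degen <- TRUE
      }
    }
  }
  members <- names(dmin)[dmin <= r]
  effective <- members[members %in% eff_keys]
  p <- structure(list(center = center, center_key = center_key,
                      radius = r, members = members,
                      effective = effective, degenerate = degen),
                 class = "patch")
  p$size <- patch_size(p, structure)
  p
}

#' Maximal atom-atom distance within a patch
#' @param p a `patch`; @param structure its `pdb_structure`.
#' @return size in Angstrom.
#' @export
patch_size <- function(p, structure) {
  a <- structure$atoms[structure$atoms$reskey %in% p$members, ]
  if (nrow(a) < 2) return(0)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  max(stats::dist(xyz))
}

#' Add patches until every effective interface residue is covered
#'
#' For every effective interface residue contained in no patch, a new patch
#' is grown from that residue's CA; repeated until coverage is complete.
#'
#' @param patches list of `patch` objects.
#' @param interface interface residue keys.
#' @param structure the `pdb_structure`.
#' @return the extended patch list.
#' @export
cover_gaps <- function(patches, interface, structure) {
  rt <- residue_table(structure)
  eff <- interface[interface %in% rt$reskey[rt$is_effective]]
  repeat {
    covered <- unique(unlist(lapply(patches, `[[`, "effective")))
    missing <- setdiff(eff, covered)
    if (!length(missing)) break
    res <- get_residue(structure, missing[1])
    ca <- res[res$elety == "CA", ]
    if (!nrow(ca)) stop("no CA in residue ", missing[1])
    patches <- c(patches, list(grow_patch(ca, interface, structure)))
  }
  patches
}

#' Construct the full set of interface patches of one protein
#'
#' Convenience driver: stride-64 centers over the interface atom list,
#' sphere growth, then gap coverage.
#'
#' @param structure the (bound) `pdb_structure` carrying the interface.
#' @param interface interface residue keys (from [interface_residues()]).
#' @return list of `patch` objects.
#' @export
build_patches <- function(structure, interface) {
  ia <- structure$atoms[structure$atoms$reskey %in% interface, ]
  centers <- place_patch_centers(ia)
  patches <- lapply(seq_len(nrow(centers)), function(i)
    grow_patch(centers[i, ], interface, structure))
  cover_gaps(patches, interface, structure)
}

#' @export
print.patch <- function(x, ...) {
  cat(sprintf("patch @ %s: r=%.2f A, %d members (%d effective)%s, size %.2f A\n",
              ifelse(is.na(x$center_key), "point", x$center_key), x$radius,
              length(x$members), length(x$effective),
              if (x$degenerate) " [degenerate]" else "", x$size))
  invisible(x)
}
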