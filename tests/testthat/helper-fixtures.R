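# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately implemented differently from the package code paths they
# check.

# independent dihedral computation: project bond vectors onto the plane
# normal to the central bond and take the signed plane angle
oracle_dihedral <- function(p1, p2, p3, p4) {
  b <- p3 - p2
  b <- b / sqrt(sum(b^2))
  u <- (p1 - p2) - sum((p1 - p2) * b) * b
  w <- (p4 - p3) - sum((p4 - p3) * b) * b
  ang <- atan2(sum(cross3(u, w) * b), sum(u * w)) * 180 / pi
  -ang
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# quaternion-based rigid superposition (Horn 1987), independent of the
# package's SVD-based Kabsch implementation
oracle_superpose <- function(mobile, target) {
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(target, 2, ct)
  S <- t(P) %*% Q
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  fitc <- P %*% t(R)
  list(coords = sweep(fitc, 2, ct, "+"),
       rmsd = sqrt(mean(rowSums((fitc - Q)^2))))
}

# brute-force non-bonded energy: plain double loop over every atom pair,
# no spatial pruning, mirroring the stated model term by term
oracle_energy <- function(struct, patch_keys, ff, exposure = NULL) {
  a <- struct$atoms
  drop <- rep(FALSE, nrow(a))
  for (rt in names(patchsampler:::EXCLUDED_ENERGY_ATOMS))
    drop <- drop | (a$resid == rt &
                      a$elety %in% patchsampler:::EXCLUDED_ENERGY_ATOMS[[rt]])
  a <- a[!drop, ]
  p <- patchsampler:::lookup_params(ff, a$resid, a$elety)
  cfg <- ff$config
  acc <- function(key) {
    if (is.null(exposure)) return(FALSE)
    isTRUE(exposure$accessible[match(key, exposure$reskey)])
  }
  ca <- a[a$elety == "CA", ]
  ca_of <- function(key) as.numeric(ca[match(key, ca$reskey),
                                       c("x", "y", "z")])
  in_patch <- a$reskey %in% patch_keys
  total <- 0
  n <- nrow(a)
  for (i in seq_len(n)) {
    if (!in_patch[i]) next
    for (j in seq_len(n)) {
      if (j == i) next
      if (in_patch[j] && j < i) next   # patch-internal pairs once
      if (a$reskey[i] == a$reskey[j] && j < i) next
      same <- a$reskey[i] == a$reskey[j]
      if (same) {
        sep <- patchsampler:::get_bond_separation(a$resid[i])
        ii <- match(a$elety[i], rownames(sep))
        jj <- match(a$elety[j], rownames(sep))
        if (!is.na(ii) && !is.na(jj) && sep[ii, jj] < 4) next
      }
      if (sqrt(sum((ca_of(a$reskey[i]) - ca_of(a$reskey[j]))^2)) >=
            cfg$pair_cutoff) next
      r <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                       c(a$x[j], a$y[j], a$z[j]))^2))
      r <- max(r, cfg$r_floor)
      lj <- min(sqrt(p$eps[i] * p$eps[j]) *
                  (p$a[i] * p$a[j] / r^12 - p$b[i] * p$b[j] / r^6),
                cfg$lj_cap)
      coul <- 332.0637 * p$q[i] * p$q[j] / (cfg$epsilon_r * r)
      e <- lj + coul
      si <- if (acc(a$reskey[i])) cfg$exposure_scale else 1
      sj <- if (acc(a$reskey[j])) cfg$exposure_scale else 1
      s <- if (in_patch[i] && in_patch[j]) (si + sj) / 2 else sj
      total <- total + e * s
    }
  }
  total
}

# a minimal three-residue peptide (GLY-X-GLY style but all flexible) used
# by the small energy/SCMF oracles
tiny_patch_system <- function(types = c("SER", "CYS", "VAL"), seed = 0,
                              rotamers_per_type = 3, charge = 0) {
  toy <- make_toy_case(types = c("ALA", types, "ALA"), seed = seed,
                       rotamers_per_type = rotamers_per_type)
  params <- make_toy_params(unique(toy$bound$atoms$resid),
                            charge = charge)
  flex_keys <- toy$truth$flex_keys
  p <- structure(list(center = c(0, 0, 0), center_key = NA_character_,
                      radius = 99, members = unique(toy$unbound$atoms$reskey),
                      effective = flex_keys, degenerate = FALSE, size = 0),
                 class = "patch")
  list(toy = toy, params = params, patch = p)
}

# enumerate every rotamer combination of a multicopy system and return the
# energies (plus index matrix); exhaustive ground truth for the filter
oracle_exhaustive_energies <- function(sys) {
  counts <- lengths(sys$e_bb)
  grid <- do.call(expand.grid, lapply(counts, seq_len))
  e <- apply(grid, 1, function(ix) {
    ix <- as.integer(ix)
    v <- sys$e_fixed
    for (i in seq_along(ix)) v <- v + sys$e_bb[[i]][ix[i]] +
        sys$e_self[[i]][ix[i]]
    for (i in seq_along(ix)) for (j in seq_along(ix)) if (j > i)
      v <- v + sys$e_pair[[i]][[j]][ix[i], ix[j]]
    v
  })
  list(energies = e, grid = grid)
}

# write a minimal hand-rolled PDB text file; returns the path
write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, altloc = " ", icode = " ") {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name, altloc, resid, chain, resno, icode, x, y, z, occ,
          0)
}
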