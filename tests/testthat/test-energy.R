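mk_atom <- function(resid, elety, x, y = 0, z = 0, resno = 1L,
                    chain = "A") {
  data.frame(chain = chain, resno = resno, icode = "", resid = resid,
             elety = elety, x = x, y = y, z = z, occ = 1,
             stringsAsFactors = FALSE)
}

test_that("distance floor and LJ cap bound every pair term", {
  ff <- make_toy_params("ALA")
  a <- mk_atom("ALA", "CB", 0)
  # severe clash: floored at 2 A and capped at 2 kcal/mol
  for (d in c(0.3, 0.5, 1.0, 1.9)) {
    b <- mk_atom("ALA", "CB", d, resno = 2L)
    expect_equal(pair_energy(a, b, ff), 2)
  }
  # energies at r and max(r, 2) identical
  expect_equal(pair_energy(a, mk_atom("ALA", "CB", 1.2, resno = 2L), ff),
               pair_energy(a, mk_atom("ALA", "CB", 2.0, resno = 2L), ff))
  # beyond the well the LJ term is negative but still <= cap
  e <- pair_energy(a, mk_atom("ALA", "CB", 4.0, resno = 2L), ff)
  expect_lt(e, 0)
  # accessibility scaling halves the term
  expect_equal(pair_energy(a, mk_atom("ALA", "CB", 4.0, resno = 2L), ff,
                           j_accessible = TRUE), e / 2)
})

test_that("Coulomb spot value: unit opposite charges at 3.32064 A", {
  # neutral LJ: zero the LJ coefficients, keep unit charges
  tab <- data.frame(resid = "ALA", elety = c("P1", "M1"), q = c(1, -1),
                    a = 0, b = 0, eps = 0)
  ff <- patchsampler:::new_forcefield(tab)
  a <- mk_atom("ALA", "P1", 0)
  b <- mk_atom("ALA", "M1", 332.064 / 100, resno = 2L)
  expect_equal(pair_energy(a, b, ff), -100.0, tolerance = 1e-5)
})

test_that("conformation energy equals the unpruned brute-force double loop", {
  for (seed in 1:3) {
    ts <- tiny_patch_system(types = c("SER", "LEU", "ASP"), seed = seed,
                            charge = 0.05)
    toy <- ts$toy
    e_pkg <- conformation_energy(toy$unbound, ts$patch$members, ts$params)
    e_orc <- oracle_energy(toy$unbound, ts$patch$members, ts$params)
    expect_equal(e_pkg, e_orc, tolerance = 1e-10)
    # with exposure scaling
    expo <- compute_exposure(toy$unbound)
    e_pkg2 <- conformation_energy(toy$unbound, ts$patch$members, ts$params,
                                  expo)
    e_orc2 <- oracle_energy(toy$unbound, ts$patch$members, ts$params, expo)
    expect_equal(e_pkg2, e_orc2, tolerance = 1e-10)
  }
})

test_that("energy is invariant under rigid motion of the whole system", {
  ts <- tiny_patch_system(seed = 2, charge = 0.05)
  toy <- ts$toy
  e0 <- conformation_energy(toy$unbound, ts$patch$members, ts$params)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  s2 <- toy$unbound
  xyz <- as.matrix(s2$atoms[, c("x", "y", "z")]) %*% R
  s2$atoms$x <- xyz[, 1] + 11
  s2$atoms$y <- xyz[, 2] - 3
  s2$atoms$z <- xyz[, 3] + 0.5
  expect_equal(conformation_energy(s2, ts$patch$members, ts$params), e0,
               tolerance = 1e-8)
})

test_that("atoms beyond the 20 A CA-CA cutoff contribute nothing", {
  ff <- make_toy_params("GLY")
  # two 1-atom residues 50 A apart: conformation energy is zero
  atoms <- rbind(mk_atom("GLY", "CA", 0), mk_atom("GLY", "CA", 50,
                                                  resno = 2L))
  s <- structure_from_atoms(atoms, "far")
  expect_equal(conformation_energy(s, "A.1.", ff), 0)
  # at 15 A they interact
  atoms2 <- rbind(mk_atom("GLY", "CA", 0), mk_atom("GLY", "CA", 15,
                                                   resno = 2L))
  s2 <- structure_from_atoms(atoms2, "near")
  expect_true(conformation_energy(s2, "A.1.", ff) != 0)
})

test_that("solvent exposure: isolated residues accessible, caged ones not", {
  toy <- make_toy_case(seed = 1)
  k <- toy$truth$flex_keys[4]
  lone <- subset_structure(toy$unbound, k)
  expo <- compute_exposure(lone)
  expect_gt(expo$ratio, 0.9)
  expect_true(expo$accessible)
  # enclose the residue in a dense cage of atoms
  res <- get_residue(toy$unbound, k)
  ctr <- colMeans(res[, c("x", "y", "z")])
  sph <- expand.grid(th = seq(0, pi, length.out = 18),
                     ph = seq(0, 2 * pi, length.out = 36),
                     r = c(6.5, 8))
  cage <- data.frame(chain = "C", resno = 99L, icode = "", resid = "GLY",
                     elety = "CA",
                     x = ctr[1] + sph$r * sin(sph$th) * cos(sph$ph),
                     y = ctr[2] + sph$r * sin(sph$th) * sin(sph$ph),
                     z = ctr[3] + sph$r * cos(sph$th), occ = 1)
  caged <- structure_from_atoms(rbind(
    res[, c("chain", "resno", "icode", "resid", "elety", "x", "y", "z",
            "occ")], cage), "caged")
  expo2 <- compute_exposure(caged)
  expect_lt(expo2$ratio[1], 0.05)
  expect_false(expo2$accessible[1])
})

test_that("exposure ratios are stable under sphere-point refinement", {
  toy <- make_toy_case(types = c("ALA", "SER", "LEU", "ALA"), seed = 3)
  lo <- compute_exposure(toy$unbound, n_points = 240)
  hi <- compute_exposure(toy$unbound, n_points = 2400)
  expect_lt(max(abs(lo$ratio - hi$ratio)), 0.02)
})

test_that("disulfide bonus requires bridge geometry", {
  cys_pair <- function(d_ss, ang_deg) {
    a <- pi * ang_deg / 180
    sg1 <- c(0, 0, 0)
    sg2 <- c(d_ss, 0, 0)
    cb1 <- sg1 + 1.808 * c(cos(a), sin(a), 0)
    cb2 <- sg2 + 1.808 * c(-cos(a), sin(a), 0)
    list(
      a = data.frame(chain = "A", resno = 1L, icode = "", resid = "CYS",
                     elety = c("CB", "SG"), x = c(cb1[1], sg1[1]),
                     y = c(cb1[2], sg1[2]), z = 0, occ = 1),
      b = data.frame(chain = "A", resno = 5L, icode = "", resid = "CYS",
                     elety = c("CB", "SG"), x = c(cb2[1], sg2[1]),
                     y = c(cb2[2], sg2[2]), z = 0, occ = 1))
  }
  good <- cys_pair(2.05, 104)
  expect_equal(disulfide_term(good$a, good$b), -10)
  expect_equal(disulfide_term(good$a, good$b, e_ss = -5), -5)
  # too far, and bad approach angles, give zero
  far <- cys_pair(4, 104)
  expect_equal(disulfide_term(far$a, far$b), 0)
  straight <- cys_pair(2.05, 170)
  expect_equal(disulfide_term(straight$a, straight$b), 0)
})
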