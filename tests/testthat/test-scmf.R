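test_that("effective energy: hand-computable systems", {
  # zero pair energies -> E_bb + E_self
  sys <- multicopy_from_tables(e_bb = list(c(1, 2), c(0, 3)),
                               e_self = list(c(0.5, 0), c(0, 0)))
  expect_equal(effective_energy(sys, 1, 1), 1.5)
  expect_equal(effective_energy(sys, 2, 2), 3)
  # 2 residues, 1 rotamer each, pair energy 4 -> each gets half
  ep <- list(list(NULL, matrix(4, 1, 1)), list(matrix(4, 1, 1), NULL))
  sys2 <- multicopy_from_tables(e_bb = list(1, 1), e_pair = ep)
  expect_equal(effective_energy(sys2, 1, 1), 1 + 2)
  expect_error(effective_energy(sys2, 1, 5), "range")
})

test_that("effective energy matches a direct triple-loop evaluation", {
  set.seed(5)
  for (rep in 1:20) {
    counts <- sample(1:3, 3, replace = TRUE)
    e_bb <- lapply(counts, function(k) rnorm(k))
    e_self <- lapply(counts, function(k) rnorm(k))
    e_pair <- vector("list", 3)
    for (i in 1:3) e_pair[[i]] <- vector("list", 3)
    for (i in 1:3) for (j in 1:3) if (j > i) {
      m <- matrix(rnorm(counts[i] * counts[j]), counts[i], counts[j])
      e_pair[[i]][[j]] <- m
      e_pair[[j]][[i]] <- t(m)
    }
    sys <- multicopy_from_tables(e_bb, e_self, e_pair)
    # random valid probabilities
    sys$p <- lapply(counts, function(k) {
      w <- runif(k)
      w / sum(w)
    })
    i <- sample(1:3, 1)
    r <- sample(counts[i], 1)
    want <- e_bb[[i]][r] + e_self[[i]][r]
    for (j in 1:3) {
      if (j == i) next
      for (s in seq_len(counts[j]))
        want <- want + 0.5 * sys$p[[j]][s] * e_pair[[i]][[j]][r, s]
    }
    expect_equal(effective_energy(sys, i, r), want, tolerance = 1e-12)
  }
})

test_that("mean energy equals the exhaustive expectation over combinations", {
  set.seed(8)
  for (rep in 1:10) {
    counts <- sample(2:3, 3, replace = TRUE)
    e_bb <- lapply(counts, function(k) rnorm(k))
    e_self <- lapply(counts, function(k) rnorm(k))
    e_pair <- vector("list", 3)
    for (i in 1:3) e_pair[[i]] <- vector("list", 3)
    for (i in 1:3) for (j in 1:3) if (j > i) {
      m <- matrix(rnorm(counts[i] * counts[j]), counts[i], counts[j])
      e_pair[[i]][[j]] <- m
      e_pair[[j]][[i]] <- t(m)
    }
    sys <- multicopy_from_tables(e_bb, e_self, e_pair)
    sys$p <- lapply(counts, function(k) {
      w <- runif(k)
      w / sum(w)
    })
    # direct expectation: sum over all rotamer combinations weighted by
    # the product probability
    grid <- expand.grid(lapply(counts, seq_len))
    want <- 0
    for (g in seq_len(nrow(grid))) {
      ix <- as.integer(grid[g, ])
      pr <- prod(vapply(1:3, function(i) sys$p[[i]][ix[i]], numeric(1)))
      e <- sum(vapply(1:3, function(i)
        e_bb[[i]][ix[i]] + e_self[[i]][ix[i]], numeric(1)))
      for (i in 1:3) for (j in 1:3) if (j > i)
        e <- e + e_pair[[i]][[j]][ix[i], ix[j]]
      want <- want + pr * e
    }
    expect_equal(mean_energy(sys), want, tolerance = 1e-10)
  }
})

test_that("one-hot mean energy reproduces the built conformation's energy", {
  ts <- tiny_patch_system(types = c("SER", "LEU", "ASP"), seed = 4,
                          charge = 0.05)
  toy <- ts$toy
  expo <- compute_exposure(toy$unbound)
  sys <- build_multicopy_system(ts$patch, toy$unbound, toy$library,
                                ts$params, expo)
  counts <- lengths(sys$e_bb)
  set.seed(1)
  for (rep in 1:3) {
    pick <- vapply(counts, function(k) sample.int(k, 1), integer(1))
    sys$p <- lapply(seq_along(counts), function(i) {
      p <- numeric(counts[i])
      p[pick[i]] <- 1
      p
    })
    conf <- patchsampler:::conformation_from_indices(sys, pick)
    # pair terms counted once: mean energy + fixed part = full energy
    expect_equal(mean_energy(sys) + sys$e_fixed, conf$energy,
                 tolerance = 1e-9)
    full <- conformation_structure(conf, toy$unbound)
    expect_equal(conf$energy,
                 conformation_energy(full, ts$patch$members, ts$params,
                                     expo),
                 tolerance = 1e-8)
  }
})

test_that("free energy: one-hot, uniform, and Boltzmann closed forms", {
  sys <- multicopy_from_tables(e_bb = list(c(1, 2, 4), c(0, 1)))
  kT <- sys$config$kT
  # one-hot: entropy vanishes
  sys$p <- list(c(1, 0, 0), c(0, 1))
  expect_equal(free_energy(sys), mean_energy(sys))
  # zero energies, uniform p: F = -kT * sum log R_i
  sys0 <- multicopy_from_tables(e_bb = list(numeric(4), numeric(3)))
  expect_equal(free_energy(sys0), -kT * (log(4) + log(3)))
  # 1-residue minimizer over p is the Boltzmann distribution: compare the
  # converged F against the closed-form -kT log Z
  e <- c(0.3, -0.8, 1.1)
  sys1 <- multicopy_from_tables(e_bb = list(e))
  conv <- scmf_iterate(sys1, damping = 0, tol = 1e-12)
  z <- sum(exp(-e / kT))
  expect_equal(free_energy(conv), -kT * log(z), tolerance = 1e-9)
  # perturbing p away from Boltzmann can only raise F
  for (rep in 1:5) {
    set.seed(rep)
    w <- runif(3)
    sysp <- sys1
    sysp$p <- list(w / sum(w))
    expect_gte(free_energy(sysp), -kT * log(z) - 1e-12)
  }
})

test_that("SCMF converges to the exact Boltzmann distribution (1 residue)", {
  set.seed(3)
  for (rep in 1:10) {
    e <- rnorm(sample(2:6, 1), sd = 2)
    sys <- multicopy_from_tables(e_bb = list(e))
    conv <- scmf_iterate(sys, damping = 0, tol = 1e-12)
    expect_true(conv$converged)
    boltz <- exp(-(e - min(e)) / sys$config$kT)
    boltz <- boltz / sum(boltz)
    expect_equal(conv$p[[1]], boltz, tolerance = 1e-9)
    # damped iteration reaches the same fixed point
    conv2 <- scmf_iterate(sys, damping = 0.9, tol = 1e-12)
    expect_equal(conv2$p[[1]], boltz, tolerance = 1e-6)
  }
})

test_that("uncoupled systems converge in <= 2 undamped iterations", {
  set.seed(9)
  e_bb <- lapply(c(3, 2, 4), function(k) rnorm(k, sd = 3))
  sys <- multicopy_from_tables(e_bb)
  conv <- scmf_iterate(sys, damping = 0)
  expect_true(conv$converged)
  expect_lte(conv$n_iter, 2)
  for (i in 1:3) {
    boltz <- exp(-(e_bb[[i]] - min(e_bb[[i]])) / sys$config$kT)
    expect_equal(conv$p[[i]], boltz / sum(boltz), tolerance = 1e-12)
  }
  # a >= 10 kT split with no coupling gives near one-hot probabilities
  split <- multicopy_from_tables(list(c(0, 10 * 0.593), c(0, 10 * 0.593)))
  conv2 <- scmf_iterate(split, damping = 0)
  expect_gt(conv2$p[[1]][1], 0.999)
  expect_gt(conv2$p[[2]][1], 0.999)
})

test_that("symmetric systems keep the uniform fixed point", {
  ep <- matrix(1, 3, 3)
  e_pair <- list(list(NULL, ep), list(t(ep), NULL))
  sys <- multicopy_from_tables(e_bb = list(rep(2, 3), rep(2, 3)),
                               e_pair = e_pair)
  conv <- scmf_iterate(sys, damping = 0.5, tol = 1e-10)
  expect_equal(conv$p[[1]], rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(conv$p[[2]], rep(1 / 3, 3), tolerance = 1e-12)
  # probabilities remain simplex-valued through the iteration
  for (p in conv$p) {
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
})

test_that("free energy at convergence never exceeds the uniform start", {
  set.seed(17)
  for (rep in 1:10) {
    counts <- sample(2:4, 3, replace = TRUE)
    e_bb <- lapply(counts, function(k) rnorm(k, sd = 1.5))
    e_pair <- vector("list", 3)
    for (i in 1:3) e_pair[[i]] <- vector("list", 3)
    for (i in 1:3) for (j in 1:3) if (j > i) {
      m <- matrix(rnorm(counts[i] * counts[j], sd = 0.5), counts[i],
                  counts[j])
      e_pair[[i]][[j]] <- m
      e_pair[[j]][[i]] <- t(m)
    }
    sys <- multicopy_from_tables(e_bb, e_pair = e_pair)
    f0 <- free_energy(sys)
    conv <- scmf_iterate(sys, damping = 0.5, tol = 1e-10)
    expect_lte(free_energy(conv), f0 + 1e-9)
  }
})

test_that("select_conformation picks the highest-probability rotamers", {
  sys <- multicopy_from_tables(e_bb = list(c(0, 1), c(0, 0)))
  sys$p <- list(c(0.2, 0.8), c(0.5, 0.5))
  conf <- select_conformation(sys)
  expect_equal(conf$rot_idx, c(2L, 1L))   # tie at 0.5 -> lowest index
})

test_that("chi1 configuration enumeration: products, HIS and free slots", {
  mk_set <- function(rt, chi1s) {
    patchsampler:::new_rotamer_set(rt, lapply(chi1s, function(c1)
      c(c1, rep(180, n_chi(rt) - 1))), rep("library", length(chi1s)))
  }
  # 2 standard residues x 3 bins each -> 9
  sets <- list(mk_set("LEU", c(60, 180, -60)), mk_set("MET", c(60, 180,
                                                               -60)))
  expect_length(enumerate_chi1_configurations(sets), 9)
  # HIS with 6 rotamers sampled exhaustively: 6 x 3 -> 18
  sets2 <- list(mk_set("HIS", rep(c(60, 180, -60), 2)),
                mk_set("LEU", c(60, 180, -60)))
  expect_length(enumerate_chi1_configurations(sets2), 18)
  # SER is a single free slot regardless of its rotamer count
  sets3 <- list(mk_set("SER", c(60, 180, -60)),
                mk_set("LEU", c(60, 180, -60)))
  cfgs <- enumerate_chi1_configurations(sets3)
  expect_length(cfgs, 3)
  expect_equal(cfgs[[1]]$idx[[1]], 1:3)
  # a residue occupying only 2 bins contributes a factor 2 (bucket oracle)
  sets4 <- list(mk_set("LEU", c(55, 65, 180)), mk_set("MET", c(60, 180,
                                                               -60)))
  bins4 <- chi1_bin(c(55, 65, 180))
  expect_length(enumerate_chi1_configurations(sets4),
                length(unique(bins4)) * 3)
  # empty rotamer set errors
  expect_error(enumerate_chi1_configurations(list(
    list(res_type = "LEU", chis = list(), source = character(0),
         bins = character(0)))), "zero rotamers")
})

test_that("filter_patch: one conformation per configuration, bins honored", {
  ts <- tiny_patch_system(types = c("LEU", "MET", "SER"), seed = 2)
  toy <- ts$toy
  sys <- build_multicopy_system(ts$patch, toy$unbound, toy$library,
                                ts$params)
  cfgs <- enumerate_chi1_configurations(sys$rotamer_sets)
  confs <- filter_patch(ts$patch, toy$unbound, toy$library, ts$params,
                        sys = sys)
  expect_length(confs, length(cfgs))
  # every conformation honors its configuration's chi1 bins (SER exempt)
  for (k in seq_along(confs)) {
    conf <- confs[[k]]
    for (i in seq_along(sys$rotamer_sets)) {
      rt <- sys$rotamer_sets[[i]]$res_type
      if (rt %in% c("SER", "CYS", "HIS")) next
      expect_true(conf$rot_idx[i] %in% cfgs[[k]]$idx[[i]])
    }
  }
  # determinism: bit-identical on a second run
  confs2 <- filter_patch(ts$patch, toy$unbound, toy$library, ts$params,
                         sys = sys)
  expect_identical(confs, confs2)
})

test_that("on funneled systems the filter recovers the exhaustive minimum", {
  # engineered tables: a unique minimum separated by >= 5 kcal/mol
  set.seed(23)
  for (rep in 1:5) {
    counts <- c(3, 3, 3)
    e_bb <- lapply(counts, function(k) runif(k, 6, 12))
    truth <- vapply(counts, sample.int, integer(1), size = 1)
    for (i in 1:3) e_bb[[i]][truth[i]] <- 0
    sys <- multicopy_from_tables(e_bb)
    conv <- scmf_iterate(sys)
    conf <- select_conformation(conv)
    orc <- oracle_exhaustive_energies(sys)
    expect_equal(unname(conf$rot_idx),
                 as.integer(orc$grid[which.min(orc$energies), ]))
  }
})
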