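test_that("bound_UBB: identity when bound equals unbound; CA coincidence", {
  toy <- make_toy_case(seed = 2, unbound_perturbation = lapply(1:8,
                                                              function(i) 0))
  keysB <- unique(toy$bound$atoms$reskey[toy$bound$atoms$chain == "B"])
  A <- subset_structure(toy$bound,
                        setdiff(unique(toy$bound$atoms$reskey), keysB))
  members <- unique(toy$unbound$atoms$reskey)
  g <- build_bound_ubb(A, toy$unbound, members)
  for (k in g$reskeys) {
    res_b <- get_residue(A, k)
    sc_names <- rownames(g$coords[[k]])
    expect_equal(g$coords[[k]], residue_coords(res_b, sc_names),
                 tolerance = 1e-9)
  }
})

test_that("bound_UBB: rigidity and exact CA coincidence under per-residue motion", {
  toy <- make_toy_case(seed = 4)
  keysB <- unique(toy$bound$atoms$reskey[toy$bound$atoms$chain == "B"])
  A <- subset_structure(toy$bound,
                        setdiff(unique(toy$bound$atoms$reskey), keysB))
  # "bound" = unbound rigidly rotated+translated per residue
  bound_rot <- toy$unbound
  set.seed(1)
  for (k in unique(bound_rot$atoms$reskey)) {
    res <- get_residue(bound_rot, k)
    th <- runif(1, -pi, pi)
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3)
    xyz <- as.matrix(res[, c("x", "y", "z")]) %*% R
    res$x <- xyz[, 1] + runif(1, -9, 9)
    res$y <- xyz[, 2] + runif(1, -9, 9)
    res$z <- xyz[, 3]
    bound_rot <- patchsampler:::replace_residue(bound_rot, k, res)
  }
  members <- unique(toy$unbound$atoms$reskey)
  g <- build_bound_ubb(bound_rot, toy$unbound, members)
  for (k in g$reskeys) {
    # intra-residue distances preserved (rigid graft)
    res_b <- get_residue(bound_rot, k)
    sc_names <- rownames(g$coords[[k]])
    d_graft <- as.numeric(dist(g$coords[[k]]))
    d_bound <- as.numeric(dist(residue_coords(res_b, sc_names)))
    expect_equal(d_graft, d_bound, tolerance = 1e-8)
    # grafted side chain rides on the unbound backbone: since bound is a
    # rigid copy, the graft reproduces the unbound side chain exactly
    res_u <- get_residue(toy$unbound, k)
    expect_equal(g$coords[[k]], residue_coords(res_u, sc_names),
                 tolerance = 1e-6)
  }
  # per-residue superposition against the quaternion oracle
  k <- g$reskeys[2]
  res_b <- get_residue(bound_rot, k)
  res_u <- get_residue(toy$unbound, k)
  bb <- intersect(c("N", "CA", "C", "O"), res_b$elety)
  orc <- oracle_superpose(residue_coords(res_b, bb),
                          residue_coords(res_u, bb))
  expect_lt(orc$rmsd, 1e-6)
})

test_that("rotamer_UBB selects the brute-force closest rotamer", {
  toy <- make_toy_case(seed = 6)
  keysB <- unique(toy$bound$atoms$reskey[toy$bound$atoms$chain == "B"])
  A <- subset_structure(toy$bound,
                        setdiff(unique(toy$bound$atoms$reskey), keysB))
  members <- unique(toy$unbound$atoms$reskey)
  g <- build_bound_ubb(A, toy$unbound, members)
  r <- build_rotamer_ubb(g, toy$unbound, toy$library)
  # bound side chains sit exactly on library rotamers and the backbone is
  # shared, so the closest rotamer reproduces bound_UBB exactly
  for (k in toy$truth$flex_keys) {
    expect_lt(patchsampler::rmsd_coords(r$coords[[k]], g$coords[[k]]),
              1e-6)
  }
  # explicit argmin check on one residue
  k <- toy$truth$flex_keys[5]
  ru <- get_residue(toy$unbound, k)
  rs <- patchsampler:::residue_rotamers(ru, toy$library)
  rmsds <- vapply(rs$coords, function(co)
    patchsampler::rmsd_coords(co, g$coords[[k]]), numeric(1))
  expect_equal(unname(measure_chis(rbind(residue_coords(ru, c("N", "CA",
                                                              "C")),
                                         r$coords[[k]]), ru$resid[1])),
               unname(rs$chis[[which.min(rmsds)]]), tolerance = 1e-6)
})

test_that("all-atom patch RMSD: identity and closed form", {
  toy <- make_toy_case(seed = 1)
  members <- unique(toy$unbound$atoms$reskey)
  t1 <- patchsampler:::patch_coord_table(toy$unbound, members)
  expect_equal(all_atom_patch_rmsd(t1, t1), 0)
  # one atom moved 2 A among n atoms -> 2/sqrt(n)
  t2 <- t1
  t2$x[4] <- t2$x[4] + 2
  expect_equal(all_atom_patch_rmsd(t1, t2), 2 / sqrt(nrow(t1)),
               tolerance = 1e-12)
  expect_error(all_atom_patch_rmsd(t1, t2[-1, ]), "mismatch")
})

test_that("best pick: bound member gives zero; linear-scan oracle", {
  ts <- tiny_patch_system(types = c("SER", "LEU", "MET"), seed = 7)
  toy <- ts$toy
  sys <- build_multicopy_system(ts$patch, toy$unbound, toy$library,
                                ts$params)
  confs <- filter_patch(ts$patch, toy$unbound, toy$library, ts$params,
                        sys = sys)
  unb <- unbound_conformation(ts$patch, toy$unbound, ts$params)
  ens <- finalize_ensemble(confs, unb)
  members <- ts$patch$members
  keysB <- unique(toy$bound$atoms$reskey[toy$bound$atoms$chain == "B"])
  A <- subset_structure(toy$bound,
                        setdiff(unique(toy$bound$atoms$reskey), keysB))
  tb <- A$atoms[A$atoms$reskey %in% members,
                c("reskey", "elety", "x", "y", "z")]
  bp <- best_pick(ens, tb, toy$unbound, members)
  # linear scan oracle
  rmsds <- vapply(ens$members, function(m)
    all_atom_patch_rmsd(patchsampler:::patch_coord_table(toy$unbound,
                                                         members, m),
                        tb), numeric(1))
  expect_equal(bp$rmsds, rmsds, tolerance = 1e-10)
  expect_equal(bp$index, which.min(rmsds))
  # ensemble containing the bound conformation itself scores zero
  bound_conf <- confs[[1]]
  for (k in names(bound_conf$coords)) {
    res_b <- get_residue(A, k)
    bound_conf$coords[[k]] <-
      residue_coords(res_b, rownames(bound_conf$coords[[k]]))
  }
  ens2 <- finalize_ensemble(list(bound_conf), unb)
  bp2 <- best_pick(ens2, tb, toy$unbound, members)
  expect_equal(bp2$rmsd, 0, tolerance = 1e-9)
  expect_equal(bp2$index, 1L)
  # ensemble of only the unbound conformation returns its RMSD
  ens3 <- finalize_ensemble(list(), unb)
  bp3 <- best_pick(ens3, tb, toy$unbound, members)
  expect_equal(bp3$rmsd,
               all_atom_patch_rmsd(
                 patchsampler:::patch_coord_table(toy$unbound, members,
                                                  unb), tb),
               tolerance = 1e-10)
})

test_that("case summaries count thresholds and improvements correctly", {
  reports <- data.frame(
    backbone_rmsd = c(0.2, 0.8, 1.5, 2.5, 0.4),
    rmsd_unbound_to_bound = c(1.2, 0.9, 2.0, 3.0, 0.5),
    best_pick_rmsd = c(0.5, 0.5, 1.8, 3.2, 0.5))
  s <- summarize_cases(reports, thresholds = c(1, 2))
  expect_equal(s$threshold_counts$count, c(3, 4))
  expect_equal(s$threshold_counts$fraction, c(0.6, 0.8))
  expect_equal(s$n_improved, 3)   # rows 1, 2, 3 improve; 4 worsens, 5 ties
  expect_equal(s$mean_improvement,
               mean(c(0.7, 0.4, 0.2, -0.2, 0.0)))
  expect_equal(s$by_backbone_band$n, c(3, 1, 1))
  expect_equal(s$by_backbone_band$within_1A, c(3, 0, 0))
  # all within 1 A
  s2 <- summarize_cases(data.frame(backbone_rmsd = rep(0.1, 4),
                                   rmsd_unbound_to_bound = rep(2, 4),
                                   best_pick_rmsd = rep(0.5, 4)),
                        thresholds = 1)
  expect_equal(s2$threshold_counts$fraction, 1)
  # empty thresholds: counts only
  s3 <- summarize_cases(reports, thresholds = numeric(0))
  expect_equal(nrow(s3$threshold_counts), 0)
  expect_equal(s3$n, 5)
})
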