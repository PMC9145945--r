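# Build a trajectory by rigidly shifting the ligand of a complex by a given
# offset per frame (protein fixed).
traj_with_shifts <- function(cpx, shifts, timestep_ps = 5) {
  p <- as.matrix(cpx$protein[, c("x", "y", "z")])
  l <- as.matrix(cpx$ligand[, c("x", "y", "z")])
  xyz <- t(vapply(seq_len(nrow(shifts)), function(f) {
    lf <- sweep(l, 2, shifts[f, ], "+")
    c(as.vector(t(p)), as.vector(t(lf)))
  }, numeric(3 * (nrow(p) + nrow(l)))))
  as_trajectory(cpx, xyz, timestep_ps)
}

test_that("RMSD closed forms: identity and rigid translation", {
  cpx <- gen_complex("HYDROPHOBIC")$cpx
  traj <- traj_with_shifts(cpx, rbind(c(0, 0, 0), c(0, 0, 0), c(3, 0, 0)))
  lig_raw <- compute_rmsd(traj, "ligand", superpose = FALSE)
  expect_equal(lig_raw$rmsd_A, c(0, 0, 3))
  expect_equal(lig_raw$time_ps, c(0, 5, 10))
  bb <- compute_rmsd(traj, "backbone", superpose = FALSE)
  expect_equal(bb$rmsd_A, c(0, 0, 0))
  ser <- rmsd_series(traj)
  expect_equal(ser$rmsd_ligand_raw_A[3], 3)
  expect_equal(ser$rmsd_backbone_A, c(0, 0, 0))
})

test_that("superposed RMSD is invariant under global rigid motion", {
  set.seed(17)
  cpx <- gen_complex("HBOND")$cpx
  n_atoms <- nrow(cpx$protein) + nrow(cpx$ligand)
  base <- c(as.vector(t(as.matrix(cpx$protein[, c("x", "y", "z")]))),
            as.vector(t(as.matrix(cpx$ligand[, c("x", "y", "z")]))))
  frames <- rbind(base)
  for (f in 1:4) {
    motion <- pdlscreen:::random_rigid_motion()
    moved <- pdlscreen:::apply_rigid(matrix(base, ncol = 3, byrow = TRUE),
                                     motion)
    frames <- rbind(frames, as.vector(t(moved)))
  }
  traj <- as_trajectory(cpx, frames)
  lig <- compute_rmsd(traj, "ligand", superpose = TRUE)
  bb <- compute_rmsd(traj, "backbone", superpose = TRUE)
  expect_true(all(abs(lig$rmsd_A) < 1e-6))
  expect_true(all(abs(bb$rmsd_A) < 1e-6))
  # without superposition the motion is visible
  raw <- compute_rmsd(traj, "ligand", superpose = FALSE)
  expect_gt(max(raw$rmsd_A), 1)
})

test_that("superposed RMSD matches the independent bio3d route", {
  set.seed(23)
  cpx <- gen_complex("HBOND")$cpx
  traj <- gen_trajectory(cpx, n_frames = 10, mode = "drift", amplitude = 0.4)
  ours <- compute_rmsd(traj, "ligand", superpose = TRUE)
  bbsel <- pdlscreen:::selection_rows(traj, "backbone")
  ligsel <- pdlscreen:::selection_rows(traj, "ligand")
  ref <- traj$xyz[1, ]
  for (f in c(4, 10)) {
    fitted <- bio3d::fit.xyz(
      fixed = ref, mobile = traj$xyz[f, ],
      fixed.inds = pdlscreen:::xyz_cols(bbsel),
      mobile.inds = pdlscreen:::xyz_cols(bbsel)
    )
    r <- bio3d::rmsd(ref, fitted, a.inds = pdlscreen:::xyz_cols(ligsel),
                     b.inds = pdlscreen:::xyz_cols(ligsel))
    # bio3d::rmsd() rounds to 3 decimals
    expect_lt(abs(ours$rmsd_A[f] - r), 6e-4)
  }
})

test_that("contact persistence counts frames and multiple contacts", {
  cpx <- gen_complex("HBOND")$cpx
  # always-on contact
  static <- gen_trajectory(cpx, n_frames = 20, mode = "static")
  p1 <- compute_persistence(static)
  expect_equal(p1$persistence[p1$category == "HBOND"], 1.0)
  # contact in 50 of 100 frames
  shifts <- rbind(matrix(0, 50, 3),
                  matrix(rep(c(50, 0, 0), each = 50), 50, 3))
  half <- traj_with_shifts(cpx, shifts)
  p2 <- compute_persistence(half)
  expect_equal(p2$persistence[p2$category == "HBOND"], 0.5)
  # two simultaneous same-subtype contacts on one residue -> 2.0
  prot <- make_prot("ASP", 122, c("OD1", "OD2"), c("O", "O"),
                    rbind(c(0, 0, 0), c(0, 2.5, 0)))
  lig <- make_lig("N", rbind(c(2.5, 1.2, 0)), nH = 2L)
  both <- make_cpx(prot, lig)
  expect_equal(detect_interactions(both)$count, 2L)
  p3 <- compute_persistence(gen_trajectory(both, 10, mode = "static"))
  expect_equal(p3$persistence[p3$category == "HBOND"], 2.0)
})

test_that("persistence is linear under frame concatenation", {
  cpx <- gen_complex("HBOND")$cpx
  s1 <- matrix(0, 30, 3)
  s2 <- matrix(rep(c(50, 0, 0), each = 20), 20, 3)
  pa <- compute_persistence(traj_with_shifts(cpx, s1))
  pb <- compute_persistence(traj_with_shifts(cpx, s2))
  pab <- compute_persistence(traj_with_shifts(cpx, rbind(s1, s2)))
  va <- sum(pa$persistence[pa$category == "HBOND"])
  vb <- if (nrow(pb) > 0) sum(pb$persistence[pb$category == "HBOND"]) else 0
  vab <- sum(pab$persistence[pab$category == "HBOND"])
  expect_equal(vab, (30 * va + 20 * vb) / 50)
})

test_that("single-frame persistence equals the static SIFt mapping", {
  cpx <- gen_complex("IONIC")$cpx
  tr <- gen_trajectory(cpx, 2, mode = "static")
  one <- as_trajectory(cpx, tr$xyz[1, , drop = FALSE])
  p <- compute_persistence(one)
  s <- detect_interactions(cpx)
  expect_equal(sum(p$persistence[p$category == "IONIC"]),
               sum(s$count[s$interaction == "IONIC"]))
})

test_that("trajectories round-trip through multi-model PDB", {
  cpx <- gen_complex("HBOND")$cpx
  traj <- gen_trajectory(cpx, n_frames = 5, mode = "drift", amplitude = 0.3,
                         seed = 4)
  p <- tempfile(fileext = ".pdb")
  write_trajectory(traj, p)
  lig_sdf <- gen_complex("HBOND")$ligand_sdf
  back <- read_trajectory(p, ligand_resname = "LIG", ligand_sdf = lig_sdf)
  expect_equal(nrow(back$xyz), 5)
  expect_equal(back$xyz, unname(traj$xyz), tolerance = 1e-3)
  # analysis agrees on both representations
  expect_equal(compute_rmsd(back, "ligand", superpose = FALSE)$rmsd_A,
               compute_rmsd(traj, "ligand", superpose = FALSE)$rmsd_A,
               tolerance = 1e-3)
})

test_that("empty selections and degenerate trajectories fail loudly", {
  cpx <- gen_complex("HBOND")$cpx
  traj <- gen_trajectory(cpx, 3, mode = "static")
  expect_error(as_trajectory(cpx, matrix(0, 2, 5)), "columns")
  w <- cpx
  w$protein <- w$protein[0, ]
  expect_error(compute_rmsd(as_trajectory(w, traj$xyz[, -(1:(3 * nrow(cpx$protein)))]),
                            "backbone"), "empty selection")
})
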