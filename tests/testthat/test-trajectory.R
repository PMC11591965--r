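make_traj <- function(nf, n, seed = 1) {
  set.seed(seed)
  trajectory(array(rnorm(nf * n * 3), c(nf, n, 3)))
}

test_that("multi-model PDB and XYZ files round-trip through the readers", {
  traj <- make_traj(3, 4)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(traj, pdb)
  write_trajectory(traj, xyz)
  back_pdb <- read_trajectory(pdb)
  back_xyz <- read_trajectory(xyz)
  expect_equal(dim(back_pdb$coords), c(3, 4, 3))
  expect_equal(back_pdb$coords, traj$coords, tolerance = 1e-2)
  expect_lt(max(abs(back_pdb$coords - traj$coords)), 1e-3 + 1e-9)
  expect_lt(max(abs(back_xyz$coords - traj$coords)), 1e-3 + 1e-9)
  expect_equal(nrow(back_pdb$residue_ids), 4)
})

test_that("a model with a missing atom is reported by its MODEL number", {
  traj <- make_traj(3, 4)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, pdb)
  lines <- readLines(pdb)
  ca <- grep("^ATOM", lines)
  # drop one CA from the second model (atoms 5-8)
  writeLines(lines[-ca[6]], pdb)
  expect_error(read_trajectory(pdb), "MODEL 2")
})

test_that("superposition undoes an arbitrary rigid-body motion", {
  traj <- make_traj(5, 6, seed = 2)
  # rotate + translate every frame by a different rigid motion
  rot_z <- function(a) matrix(c(cos(a), -sin(a), 0,
                                sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  moved <- traj$coords
  base <- traj$coords[1, , ]
  for (f in 1:5) {
    moved[f, , ] <- base %*% rot_z(f) + matrix(10 * f, 6, 3)
  }
  sup <- superpose(trajectory(moved), "first")
  expect_lt(max(sup$per_frame_rmsd), 1e-9)
  expect_error(superpose(make_traj(3, 2)), "3 residues")
})

test_that("superposition attains the brute-force optimal RMSD", {
  set.seed(7)
  P <- matrix(rnorm(12), 4, 3)
  Q <- matrix(rnorm(12), 4, 3)
  co <- array(0, c(2, 4, 3)); co[1, , ] <- Q; co[2, , ] <- P
  sup <- superpose(trajectory(co), "first")
  # exhaustive search over quaternion rotations
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2)); w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z), 2*(x*z + w*y),
             2*(x*y + w*z), 1 - 2*(x^2 + z^2), 2*(y*z - w*x),
             2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  Pc <- scale(P, scale = FALSE); Qc <- scale(Q, scale = FALSE)
  set.seed(11)
  best <- Inf
  for (r in 1:20000) {
    R <- quat_rot(rnorm(4))
    best <- min(best, sqrt(mean(rowSums((Pc %*% R - Qc)^2))))
  }
  expect_equal(sup$per_frame_rmsd[2], best, tolerance = 1e-3)
})

test_that("RMSD matches the direct formula and the worked example", {
  # one residue displaced by 2 A in one frame, N = 4 -> RMSD 1.0
  set.seed(5)
  frame1 <- matrix(rnorm(12), 4, 3)
  co <- array(0, c(2, 4, 3))
  co[1, , ] <- frame1
  co[2, , ] <- frame1
  co[2, 1, 3] <- co[2, 1, 3] + 2
  traj <- trajectory(co)
  ref <- as.numeric(t(co[1, , ]))
  m <- unname(rbind(ref, as.numeric(t(co[2, , ]))))
  direct <- unname(sqrt(rowSums(sweep(m, 2, ref)^2) / 4))
  sup <- list(aligned = traj, reference = co[1, , ],
              per_frame_rmsd = direct)
  class(sup) <- "superposition"
  expect_equal(rmsd_series(sup), direct, tolerance = 1e-12)
  expect_equal(direct[2], 1.0, tolerance = 1e-9)
  expect_equal(direct[1], 0)
})

test_that("RMSF matches the direct formula, zero for static trajectories", {
  traj <- make_traj(6, 5, seed = 3)
  sup <- superpose(traj, "mean")
  co <- sup$aligned$coords
  direct <- sapply(1:5, function(i) {
    mu <- colMeans(co[, i, ])
    sqrt(mean(rowSums(sweep(co[, i, ], 2, mu)^2)))
  })
  expect_equal(rmsf_profile(sup), direct, tolerance = 1e-10)

  static <- trajectory(array(rep(matrix(rnorm(15), 5, 3), each = 4),
                             c(4, 5, 3)))
  sup0 <- list(aligned = static, reference = static$coords[1, , ],
               per_frame_rmsd = rep(0, 4))
  class(sup0) <- "superposition"
  expect_equal(rmsf_profile(sup0), rep(0, 5))

  # residue oscillating +/- a along x -> RMSF = a there, 0 elsewhere
  co2 <- array(0, c(2, 4, 3))
  co2[, , 1] <- matrix(c(0, 2, 4, 9), 2, 4, byrow = TRUE)
  co2[, , 2] <- matrix(c(0, 1, 0, 1), 2, 4, byrow = TRUE)
  a <- 0.75
  co2[1, 2, 3] <- a; co2[2, 2, 3] <- -a
  sup2 <- list(aligned = trajectory(co2))
  class(sup2) <- "superposition"
  expect_equal(rmsf_profile(sup2), c(0, a, 0, 0))
})

test_that("RMSD and RMSF are invariant to a global rigid motion", {
  traj <- make_traj(5, 6, seed = 4)
  sup1 <- superpose(traj, "mean")
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- traj$coords
  for (f in 1:5) moved[f, , ] <- traj$coords[f, , ] %*% R + 5
  sup2 <- superpose(trajectory(moved), "mean")
  expect_equal(rmsd_series(sup1), rmsd_series(sup2), tolerance = 1e-8)
  expect_equal(rmsf_profile(sup1), rmsf_profile(sup2), tolerance = 1e-8)
})
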