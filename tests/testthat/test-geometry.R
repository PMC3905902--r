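test_that("distance, angle and dihedral give textbook values on constructed points", {
  expect_equal(dist_xyz(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(dist_xyz(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(angle_xyz(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(dihedral_xyz(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
  expect_error(angle_xyz(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "degenerate")
  expect_error(dihedral_xyz(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("mirror images flip the dihedral sign but preserve its magnitude", {
  set.seed(11)
  for (i in 1:20) {
    pts <- matrix(rnorm(12), 4, 3)
    d <- try(dihedral_xyz(pts[1, ], pts[2, ], pts[3, ], pts[4, ]), silent = TRUE)
    if (inherits(d, "try-error")) next
    mir <- pts; mir[, 3] <- -mir[, 3]
    dm <- dihedral_xyz(mir[1, ], mir[2, ], mir[3, ], mir[4, ])
    expect_equal(dm, -d, tolerance = 1e-9)
  }
})

test_that("measurements are invariant under common proper rigid transforms", {
  set.seed(4)
  pts <- matrix(rnorm(12, sd = 3), 4, 3)
  d0 <- dist_xyz(pts[1, ], pts[2, ])
  a0 <- angle_xyz(pts[1, ], pts[2, ], pts[3, ])
  h0 <- dihedral_xyz(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
  for (i in 1:25) {
    R <- random_rotation(); t <- rnorm(3, sd = 10)
    q <- apply_rigid(pts, R, t)
    expect_equal(dist_xyz(q[1, ], q[2, ]), d0, tolerance = 1e-9)
    expect_equal(angle_xyz(q[1, ], q[2, ], q[3, ]), a0, tolerance = 1e-9)
    expect_equal(dihedral_xyz(q[1, ], q[2, ], q[3, ], q[4, ]), h0,
                 tolerance = 1e-9)
  }
})

test_that("superposition recovers identity and planted transforms", {
  set.seed(21)
  X <- matrix(rnorm(24, sd = 4), 8, 3)
  tr0 <- superpose(X, X)
  expect_equal(tr0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tr0$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(tr0$rmsd, 0, tolerance = 1e-9)
  R <- random_rotation(); t <- rnorm(3, sd = 5)
  Y <- apply_rigid(X, R, t)
  tr <- superpose(Y, X)
  expect_lt(tr$rmsd, 1e-9)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
  expect_equal(apply_transform(Y, tr), X, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(superpose(X[1:2, ], X[1:2, ]), "at least 3")
})

test_that("reflection-related point sets keep a positive residual (no improper rotations)", {
  set.seed(8)
  X <- matrix(rnorm(15, sd = 3), 5, 3)
  Y <- X; Y[, 1] <- -Y[, 1]
  tr <- superpose(Y, X)
  expect_gt(tr$rmsd, 0.1)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch equals a brute-force search over rotations on small instances", {
  set.seed(33)
  for (i in 1:4) {
    n <- sample(4:8, 1)
    X <- matrix(rnorm(3 * n, sd = 3), n, 3)
    Y <- matrix(rnorm(3 * n, sd = 3), n, 3)
    expect_equal(superpose(X, Y)$rmsd, brute_force_rmsd(X, Y),
                 tolerance = 1e-6)
  }
})

test_that("Kabsch agrees with the bio3d fitting routine on a protein-sized pair", {
  snaps <- make_snapshot_series()
  X <- coord_matrix(snaps$ES)[1:28, ]   # protein scaffold atoms
  set.seed(5)
  Y <- apply_rigid(X, random_rotation(), rnorm(3)) +
    matrix(rnorm(length(X), sd = 0.2), nrow(X))
  ours <- superpose(Y, X)
  fitted <- matrix(bio3d::fit.xyz(as.numeric(t(X)), as.numeric(t(Y)),
                                  fixed.inds = 1:(3 * nrow(X)),
                                  mobile.inds = 1:(3 * nrow(X))),
                   ncol = 3, byrow = TRUE)
  theirs <- sqrt(mean(rowSums((fitted - X)^2)))
  expect_equal(ours$rmsd, theirs, tolerance = 1e-6)
})

test_that("reaction coordinates combine breaking/forming distances as defined", {
  expect_equal(reaction_coordinate(2.0, 2.0)$q1, 0)         # synchronous TS
  expect_equal(reaction_coordinate(1.64, 2.52)$q1, -0.88)   # pre-catalytic state
  rc <- reaction_coordinate(1.64, 2.52, d_hw_ow = 1.0, d_hw_oasp = 1.7)
  expect_equal(rc$q2, -1.23)
  expect_error(reaction_coordinate(1.64, 2.52, d_hw_ow = 1.0), "both")
  # antisymmetry under swapping the breaking and forming bonds
  set.seed(2)
  for (i in 1:10) {
    d <- runif(2, 1.4, 3.6)
    expect_equal(reaction_coordinate(d[1], d[2])$q1,
                 -reaction_coordinate(d[2], d[1])$q1)
  }
})
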