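# Rotamer what-if edits and structure comparison.

test_that("set_chi1 hits the target exactly and moves only the side chain", {
  m <- build_gps_model(chi1_his = -170, chi1_nu = 180)
  x0 <- frame_coords(m)
  m2 <- set_chi1(m, "A", 910, 62)
  site <- locate_gps(m2, "A", nucleophile_residue = 912)
  d <- frame_descriptors(m2, site, acceptor_policy = "ND1")
  expect_equal(d$chi1_his, 62, tolerance = 1e-6)
  # atoms outside the His side chain are untouched
  x1 <- frame_coords(m2)
  outside <- m$topology$resno != 910L |
    m$topology$atom_name %in% c("N", "CA", "C", "O", "CB")
  expect_identical(x1[outside, ], x0[outside, ])
  # intra-side-chain distances unchanged (rigid rotation)
  sc <- which(!outside)
  d0 <- as.matrix(dist(x0[sc, ])); d1 <- as.matrix(dist(x1[sc, ]))
  expect_lt(max(abs(d0 - d1)), 1e-9)
  # round trip back
  m3 <- set_chi1(m2, "A", 910, -170)
  expect_equal(frame_coords(m3), x0, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(set_chi1(m, "A", 911, 60, insert = "Z"), "not found")
})

test_that("imidazole flip is an involution that swaps the ring nitrogens", {
  m <- build_gps_model()
  x0 <- frame_coords(m)
  f1 <- flip_imidazole(m, "A", 910)
  f2 <- flip_imidazole(f1, "A", 910)
  expect_equal(frame_coords(f2), x0, tolerance = 1e-9, ignore_attr = TRUE)
  t <- m$topology
  i <- function(nm) which(t$resno == 910L & t$atom_name == nm)
  x1 <- frame_coords(f1)
  # CG lies on the rotation axis
  expect_equal(x1[i("CG"), ], x0[i("CG"), ], tolerance = 1e-12)
  # atom-exchange oracle: the chi-2 flip carries each ring atom onto the
  # position of its ring counterpart (ND1 <-> CD2, CE1 <-> NE2), up to the
  # small intrinsic asymmetry of the imidazole geometry
  expect_lt(sqrt(sum((x1[i("ND1"), ] - x0[i("CD2"), ])^2)), 0.25)
  expect_lt(sqrt(sum((x1[i("CD2"), ] - x0[i("ND1"), ])^2)), 0.25)
  expect_lt(sqrt(sum((x1[i("CE1"), ] - x0[i("NE2"), ])^2)), 0.45)
  expect_lt(sqrt(sum((x1[i("NE2"), ] - x0[i("CE1"), ])^2)), 0.45)
  # ring internal geometry is preserved exactly
  ring <- c(i("CG"), i("ND1"), i("CD2"), i("CE1"), i("NE2"))
  expect_equal(as.matrix(dist(x1[ring, ])), as.matrix(dist(x0[ring, ])),
               tolerance = 1e-9)
})

test_that("Kabsch superposition matches the quaternion oracle", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(3:10, 1L)
    A <- matrix(rnorm(3L * n, sd = 4), ncol = 3L)
    if (qr(sweep(A, 2, colMeans(A)))$rank < 2L) next
    B <- sweep(A %*% t(random_rotation()), 2L, rnorm(3), FUN = "+") +
      matrix(rnorm(3L * n, sd = 0.3), ncol = 3L)
    sup <- kabsch_superpose(A, B)
    expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
    expect_equal(sup$rmsd, quaternion_superpose_oracle(A, B), tolerance = 1e-9)
    # symmetry of the minimised rmsd
    expect_equal(kabsch_superpose(B, A)$rmsd, sup$rmsd, tolerance = 1e-9)
    # independent library cross-check (bio3d rounds to 3 decimals)
    expect_lt(abs(sup$rmsd -
                    bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)),
              6e-4)
  }
})

test_that("superposition of exact and noisy copies behaves as expected", {
  set.seed(32)
  A <- matrix(rnorm(60, sd = 5), ncol = 3L)
  sup0 <- kabsch_superpose(A, A)
  expect_equal(sup0$rmsd, 0, tolerance = 1e-12)
  expect_equal(sup0$rotation, diag(3), tolerance = 1e-9)
  B <- sweep(A %*% t(random_rotation()), 2L, c(3, -2, 8), FUN = "+")
  expect_lt(kabsch_superpose(A, B)$rmsd, 1e-9)
  # large-n noisy copy: rmsd ~ sigma * sqrt(3)
  n <- 4000L; sigma <- 0.8
  A2 <- matrix(rnorm(3L * n, sd = 6), ncol = 3L)
  B2 <- A2 + matrix(rnorm(3L * n, sd = sigma), ncol = 3L)
  expect_equal(kabsch_superpose(A2, B2)$rmsd, sigma * sqrt(3),
               tolerance = 0.05)
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("outlier trimming removes planted displacements and recovers the core", {
  set.seed(33)
  n <- 100L
  A <- matrix(rnorm(3L * n, sd = 6), ncol = 3L)
  B <- A + matrix(rnorm(3L * n, sd = 0.2), ncol = 3L)
  bad <- sample(n, 10L)
  B[bad, ] <- B[bad, ] + matrix(rnorm(30L, sd = 8), ncol = 3L)
  full <- kabsch_superpose(A, B)
  trimmed <- rmsd_outlier_trim(A, B, threshold = 3.5)
  expect_lt(trimmed$rmsd, full$rmsd)
  expect_lt(trimmed$rmsd, 0.5)
  expect_true(all(!bad %in% attr(trimmed, "kept")) ||
                mean(bad %in% attr(trimmed, "kept")) < 0.2)
  # no outliers: identical to the plain superposition
  clean <- rmsd_outlier_trim(A, A + matrix(rnorm(3L * n, sd = 0.1), ncol = 3L),
                             threshold = 3.5)
  expect_equal(clean$n_pairs, n)
})

test_that("sequence alignment pairs common C-alphas and skips missing loops", {
  full <- make_ca_chain("ACDEFGHIKLMNPQRSTVWY")
  pairs_self <- pair_common_calpha(full, full, "A", "A")
  expect_equal(nrow(pairs_self), 20L)
  # drop an unresolved loop (residues 8-10) from the second model
  topo <- full$topology
  keep <- !(topo$resno %in% 8:10)
  gapped <- conformer_ensemble(topo[keep, ], frame_coords(full, 1)[keep, ],
                               source = "loop-gapped copy")
  pairs <- pair_common_calpha(full, gapped, "A", "A")
  expect_equal(nrow(pairs), 17L)
  expect_false(any(pairs$resno_a %in% 8:10))
  sup <- superpose_common_calpha(full, gapped, "A", "A")
  expect_lt(sup$rmsd, 1e-9)
  expect_equal(sup$n_pairs, 17L)
})
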