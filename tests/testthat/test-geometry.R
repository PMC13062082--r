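# Elementary geometry: torsions, the attack frame, attack angles,
# hydrogen-bond idealisation, rotamer bins and planarity strain.

test_that("dihedral reproduces cis/trans and rejects degenerate input", {
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(abs(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))), 180)
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "degenerate")
  expect_error(dihedral(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)),
               "collinear")
})

test_that("dihedral is invariant under rigid motion", {
  set.seed(11)
  for (i in 1:50) {
    p <- replicate(4, rnorm(3), simplify = FALSE)
    ref <- tryCatch(dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
                    error = function(e) NULL)
    if (is.null(ref)) next
    R <- random_rotation(); tr <- rnorm(3, sd = 10)
    q <- lapply(p, function(x) as.vector(R %*% x) + tr)
    expect_equal(dihedral(q[[1]], q[[2]], q[[3]], q[[4]]), ref,
                 tolerance = 1e-9)
  }
})

test_that("attack frame is orthonormal, right-handed, and covariant", {
  set.seed(12)
  for (i in 1:200) {
    C <- rnorm(3); O <- C + rnorm(3); N <- C + rnorm(3)
    fr <- tryCatch(build_attack_frame(C, O, N), error = function(e) NULL)
    if (is.null(fr)) next
    M <- rbind(fr$x_axis, fr$y_axis, fr$z_axis)
    expect_equal(M %*% t(M), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(det(M), 1, tolerance = 1e-8)
    # z orthogonal to both in-plane bond directions
    expect_lt(abs(sum(fr$z_axis * (O - C))), 1e-9)
    expect_lt(abs(sum(fr$z_axis * (N - C))), 1e-9)
    # covariance under rigid motion
    R <- random_rotation(); tr <- rnorm(3)
    fr2 <- build_attack_frame(as.vector(R %*% C) + tr,
                              as.vector(R %*% O) + tr,
                              as.vector(R %*% N) + tr)
    expect_equal(fr2$x_axis, as.vector(R %*% fr$x_axis), tolerance = 1e-9)
    expect_equal(fr2$z_axis, as.vector(R %*% fr$z_axis), tolerance = 1e-9)
  }
  expect_error(build_attack_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
})

test_that("attack angles recover a spherical construction oracle", {
  # oracle: place Ogamma explicitly from direction cosines in the frame
  set.seed(13)
  n_bad <- 0L
  for (i in 1:1000) {
    C <- rnorm(3); O <- C + rnorm(3); N <- C + rnorm(3)
    fr <- tryCatch(build_attack_frame(C, O, N), error = function(e) NULL)
    if (is.null(fr)) { n_bad <- n_bad + 1L; next }
    tx <- runif(1, 1, 179); ty <- runif(1, 1, 179)
    cx <- cos(tx * pi / 180); cy <- cos(ty * pi / 180)
    rem <- 1 - cx^2 - cy^2
    if (rem < 0) next
    d <- runif(1, 0.5, 6)
    M <- cbind(fr$x_axis, fr$y_axis, fr$z_axis)
    og <- C + d * as.vector(M %*% c(cx, cy, sample(c(-1, 1), 1) * sqrt(rem)))
    th <- attack_angles(fr, og)
    expect_equal(unname(th[["theta_x"]]), tx, tolerance = 1e-6)
    expect_equal(unname(th[["theta_y"]]), ty, tolerance = 1e-6)
    # direction-cosine consistency
    expect_lte(cos(th[[1]] * pi / 180)^2 + cos(th[[2]] * pi / 180)^2, 1 + 1e-9)
  }
  expect_lt(n_bad, 100L)
  # trivial placements
  fr <- build_attack_frame(c(0, 0, 0), c(-1, 0.5, 0), c(1.3, 0, 0))
  expect_equal(unname(attack_angles(fr, fr$z_axis * 3)),
               c(90, 90), tolerance = 1e-9)
  expect_equal(unname(attack_angles(fr, fr$x_axis * 3)),
               c(0, 90), tolerance = 1e-9)
  expect_error(attack_angles(fr, c(0, 0, 0)), "coincides")
})

test_that("idealised hydroxyl hydrogen minimises linearity over the cone", {
  set.seed(14)
  for (i in 1:40) {
    og <- rnorm(3)
    cb <- og + 1.52 * rnorm(3) / sqrt(sum(rnorm(3)^2))
    nn <- og + runif(1, 2.5, 3.5) * {v <- rnorm(3); v / sqrt(sum(v^2))}
    got <- hbond_geometry(og, Cbeta = cb, N_acceptor = nn)
    oracle <- cone_hbond_oracle(og, cb, nn, step = 0.5)
    # closed form never exceeds any explicit cone position, and the grid
    # minimum can overshoot a sharp conical minimum by its step
    expect_lte(got$linearity_dev, oracle + 1e-6)
    expect_lt(abs(got$linearity_dev - oracle), 0.5)
    expect_equal(got$d_NO, sqrt(sum((nn - og)^2)), tolerance = 1e-12)
  }
  # fine-grid agreement on a handful of instances (the grid can overshoot
  # a sharp conical minimum by its step times the local slope)
  for (i in 1:3) {
    og <- rnorm(3); cb <- og + c(1.5, 0.1 * i, 0); nn <- og + c(1, 2.5, 0.3 * i)
    got <- hbond_geometry(og, Cbeta = cb, N_acceptor = nn)
    oracle <- cone_hbond_oracle(og, cb, nn, step = 0.01)
    expect_lte(got$linearity_dev, oracle + 1e-6)
    expect_lt(abs(got$linearity_dev - oracle), 0.1)
  }
})

test_that("explicit hydrogen at the cone minimum equals the idealised result", {
  og <- c(0, 0, 0); cb <- c(1.52, 0, 0); nn <- c(-0.5, 2.8, 0)
  ideal <- hbond_geometry(og, Cbeta = cb, N_acceptor = nn)
  # construct the in-plane cone position towards the acceptor
  th <- 108.5 * pi / 180
  u <- c(1, 0, 0)
  aperp <- nn - sum(nn * u) * u; aperp <- aperp / sqrt(sum(aperp^2))
  H <- og + 0.96 * (cos(th) * u + sin(th) * aperp)
  explicit <- hbond_geometry(og, Cbeta = cb, H = H, N_acceptor = nn)
  expect_equal(explicit$linearity_dev, ideal$linearity_dev, tolerance = 1e-9)
})

test_that("chi1 bins and omega strain match a brute-force circular oracle", {
  grid <- seq(-179.9, 180, by = 0.1)
  bins <- classify_chi1(grid)
  om <- omega_planarity(grid)
  for (k in seq(1, length(grid), by = 7)) {
    a <- grid[k]
    d <- vapply(c(60, -60, 180), function(c0) circ_dist_oracle(a, c0), numeric(1))
    exp_bin <- if (any(d < 30)) c("+60", "-60", "180")[which(d < 30)[1]]
    else "unassigned"
    expect_identical(bins[k], exp_bin)
    exp_dev <- min(circ_dist_oracle(a, 0), circ_dist_oracle(a, 180))
    expect_equal(om$deviation[k], exp_dev, tolerance = 1e-9)
    expect_identical(om$strained[k], exp_dev > 25)
  }
  # documented canonical cases
  expect_identical(classify_chi1(c(61, -65, -175, 95)),
                   c("+60", "-60", "180", "unassigned"))
  expect_equal(omega_planarity(c(180, 150, -170, 25))$deviation,
               c(0, 30, 10, 25))
  expect_identical(omega_planarity(c(180, 150, -170, 25))$strained,
                   c(FALSE, TRUE, FALSE, FALSE))
})
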