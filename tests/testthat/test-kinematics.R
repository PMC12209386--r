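test_that("Hamilton product has the identity, i*j = k, and the norm identity", {
  q <- c(0.3, -0.5, 0.7, 0.4)
  expect_equal(quat_multiply(c(1, 0, 0, 0), q), c(w = 0.3, x = -0.5, y = 0.7, z = 0.4))
  expect_equal(unname(quat_multiply(c(0, 1, 0, 0), c(0, 0, 1, 0))), c(0, 0, 0, 1))
  set.seed(11)
  a <- matrix(rnorm(4000), 1000, 4)
  b <- matrix(rnorm(4000), 1000, 4)
  expect_equal(quat_norm(quat_multiply(a, b)), quat_norm(a) * quat_norm(b),
               tolerance = 1e-12)
  expect_error(quat_multiply(c(1, NA, 0, 0), q), "finite")
})

test_that("conjugation negates the vector part and q x q* recovers the squared norm", {
  expect_equal(unname(quat_conjugate(c(1, 0, 0, 0))), c(1, 0, 0, 0))
  expect_equal(unname(quat_conjugate(c(0, 0, 0, 1))), c(0, 0, 0, -1))
  set.seed(2)
  for (i in 1:20) {
    q <- rnorm(4)
    expect_equal(unname(quat_multiply(q, quat_conjugate(q))),
                 c(sum(q^2), 0, 0, 0), tolerance = 1e-12)
  }
  # conjugate of conjugate is the identity map
  q <- random_unit_quats(5, seed = 3)
  expect_equal(quat_conjugate(quat_conjugate(q)), unname(q), ignore_attr = TRUE)
})

test_that("reference-point rotation follows the passive q* P q convention", {
  expect_equal(unname(rotate_reference(c(1, 0, 0, 0))), c(1, 0, 0))
  expect_equal(unname(rotate_reference(c(0, 0, 0, 1))), c(-1, 0, 0))
  # quarter turn about z: passive conjugation sends (1,0,0) to (0,-1,0),
  # the mirror of the active q P q* image (0,+1,0)
  q45 <- c(cos(pi / 4), 0, 0, sin(pi / 4))
  expect_equal(unname(rotate_reference(q45)), c(0, -1, 0), tolerance = 1e-12)
  # agreement with an independent axis-angle rotation-matrix oracle
  qs <- random_unit_quats(200, seed = 5)
  for (i in seq_len(nrow(qs))) {
    expect_equal(unname(rotate_reference(qs[i, ])),
                 drop(rotation_oracle(qs[i, ]) %*% c(1, 0, 0)),
                 tolerance = 1e-9)
  }
  # unit norm is preserved
  expect_equal(sqrt(rowSums(rotate_reference(qs)^2)), rep(1, 200), tolerance = 1e-9)
  expect_error(rotate_reference(c(0, 0, 0, 0)), "zero-norm")
  expect_warning(rotate_reference(c(2, 0, 0, 0)), "deviates")
})

test_that("displacement series is zero at t0 and matches known rotations", {
  const <- make_rotation_stream(rep(0.3, 50))
  d <- displacement_series(const)
  expect_equal(max(abs(d$xyz)), 0)
  expect_equal(length(d$magnitude), 50L)

  two <- quat_stream(c(0, 0.01), rbind(c(1, 0, 0, 0), c(0, 0, 0, 1)))
  d2 <- displacement_series(two)
  expect_equal(unname(d2$xyz[2, ]), c(-2, 0, 0))
  expect_equal(d2$magnitude, c(0, 2))

  # small oscillation: |X(t) - X(0)| tracks the arc length |theta|
  theta <- 0.01 * sin(2 * pi * 5 * (0:299) / 100)
  d3 <- displacement_series(make_rotation_stream(theta))
  peak <- max(d3$magnitude)
  expect_lt(abs(peak - 0.01) / 0.01, 0.01)
})

test_that("joint angles recover constructed relative rotations and round-trip", {
  n <- 30
  idq <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  t_s <- (0:(n - 1)) / 100
  same <- tremor_recording(list(hand = quat_stream(t_s, idq, "hand"),
                                forearm = quat_stream(t_s, idq, "forearm"),
                                upperarm = quat_stream(t_s, idq, "upperarm")),
                           label = 0)
  ja <- joint_angles(same)
  expect_true(all(abs(c(ja$WFE, ja$WAA, ja$EPS, ja$EFE)) < 1e-12))

  # hand rotated about the flexion (Z) axis only -> WFE = theta, WAA = 0
  theta <- 0.2 * sin(2 * pi * 4 * t_s)
  hand_q <- cbind(cos(theta / 2), 0, 0, sin(theta / 2))
  rec <- tremor_recording(list(hand = quat_stream(t_s, hand_q, "hand"),
                               forearm = quat_stream(t_s, idq, "forearm"),
                               upperarm = quat_stream(t_s, idq, "upperarm")),
                          label = 1)
  ja2 <- joint_angles(rec)
  expect_equal(ja2$WFE, theta, tolerance = 1e-12)
  expect_lt(max(abs(ja2$WAA)), 1e-12)

  # Euler decomposition / recomposition round-trips random rotations
  qs <- random_unit_quats(100, seed = 7)
  e <- euler_zyx(qs)
  q2 <- euler_to_quat(e[, "z"], e[, "y"], e[, "x"])
  sgn <- sign(rowSums(qs * q2))  # q and -q encode one rotation
  expect_lt(max(abs(qs - q2 * sgn)), 1e-9)

  bad <- rec
  bad$streams$forearm <- quat_stream(t_s + 0.001, idq, "forearm")
  expect_error(joint_angles(bad), "time base")
})

test_that("mean-square power matches closed forms", {
  expect_equal(mean_square_power(rep(3, 100)), 9)
  t <- (0:9999) / 1000
  s <- 2.5 * sin(2 * pi * 5 * t)  # whole periods
  expect_equal(mean_square_power(s), 2.5^2 / 2, tolerance = 1e-6)
  x <- rnorm(64)
  expect_equal(mean_square_power(c(x, x)), mean_square_power(x))
})

test_that("the rating regression evaluates the printed coefficients", {
  unit <- c(WFE = 1, WAA = 1, EPS = 1, EFE = 1)
  expect_identical(tremor_rating(unit), 2.6496)
  expect_equal(tremor_rating(c(WFE = 10, WAA = 1, EPS = 1, EFE = 1)),
               2.6496 + 0.3071)
  p <- c(WFE = 0.3, WAA = 2, EPS = 0.07, EFE = 5)
  expect_equal(tremor_rating(10 * p) - tremor_rating(p),
               0.3071 + 0.0731 + 0.1843 + 0.0988)
  # strictly increasing in every power
  for (j in names(p)) {
    p2 <- p; p2[j] <- p2[j] * 1.5
    expect_gt(tremor_rating(p2), tremor_rating(p))
  }
  expect_error(tremor_rating(c(WFE = 0, WAA = 1, EPS = 1, EFE = 1)), "WFE")
  # configurable log base shifts non-unit powers
  nat <- tremor_rating_model(log_base = exp(1))
  expect_equal(tremor_rating(c(WFE = exp(1), WAA = 1, EPS = 1, EFE = 1), nat),
               2.6496 + 0.3071)
})

test_that("the subclinical gate is a strict 0.5 threshold", {
  expect_true(is_subclinical(0.49))
  expect_false(is_subclinical(0.5))
  expect_true(is_subclinical(-3))
  expect_error(is_subclinical(NaN), "finite")
})

test_that("stream CSV round-trips through the columnar dialect", {
  theta <- 0.05 * sin(2 * pi * 5 * (0:99) / 100)
  streams <- list(hand = make_rotation_stream(theta, site = "hand"),
                  forearm = make_rotation_stream(theta / 2, site = "forearm"),
                  upperarm = make_rotation_stream(theta / 4, site = "upperarm"))
  path <- tempfile(fileext = ".csv")
  write_quat_streams(streams, path)
  back <- read_quat_streams(path)
  expect_named(back, c("hand", "forearm", "upperarm"))
  expect_equal(back$hand$q, streams$hand$q, tolerance = 1e-12)
  expect_equal(back$upperarm$time_s, streams$upperarm$time_s)
})
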