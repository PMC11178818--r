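test_that("Rodrigues rotation handles canonical and random cases", {
  expect_equal(rotation_about_axis(c(0, 0, 1), 0), diag(3))
  # 90 degrees about the global zeta axis carries xi to eta
  expect_equal(as.vector(rotation_about_axis(c(0, 0, 1), 90) %*% c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:20) {
    ax <- random_unit()
    ang <- stats::runif(1, -360, 360)
    R <- rotation_about_axis(ax, ang)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    v <- random_unit()
    expect_equal(as.vector(R %*% v), quat_rotate(ax, ang, v),
                 tolerance = 1e-12)
  }
  expect_error(rotation_about_axis(c(1, 1, 0), 10), "unit")
})

test_that("frame re-orthonormalization repairs printed versors gently", {
  fr <- stimulation_frame()
  B <- cbind(fr$x_hat, fr$y_hat, fr$z_hat)
  expect_lt(max(abs(crossprod(B) - diag(3))), 1e-9)
  printed <- list(x = c(0.004, -0.918, 0.397), y = c(-0.270, -0.383, -0.884),
                  z = c(0.963, -0.104, -0.249))
  expect_lt(sqrt(sum((fr$x_hat - printed$x)^2)), 2e-3)
  expect_lt(sqrt(sum((fr$y_hat - printed$y)^2)), 2e-3)
  expect_lt(sqrt(sum((fr$z_hat - printed$z)^2)), 2e-3)
  # a left-handed triple is rejected
  expect_error(frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, -1)),
               "right-handed")
})

test_that("direction_vector matches its closed form and edge cases", {
  fr <- stimulation_frame()
  expect_equal(direction_vector(fr, 0, 0), fr$z_hat, tolerance = 1e-12)
  # the printed primary direction, at the precision of the printed versors
  expect_equal(direction_vector(fr, 0, 0), c(0.963, -0.104, -0.249),
               tolerance = 2e-3)
  # beta = 90 collapses onto the alpha-rotation axis regardless of alpha
  for (a in c(-60, 0, 45))
    expect_equal(direction_vector(fr, a, 90), fr$x_hat, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:25) {
    a <- stats::runif(1, -90, 90); b <- stats::runif(1, -90, 90)
    v <- direction_vector(fr, a, b)
    expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
    # closed form in the frame basis
    cf <- sin(b * pi / 180) * fr$x_hat -
      cos(b * pi / 180) * sin(a * pi / 180) * fr$y_hat +
      cos(b * pi / 180) * cos(a * pi / 180) * fr$z_hat
    expect_equal(v, cf, tolerance = 1e-12)
  }
})

test_that("angles_from_direction inverts direction_vector", {
  fr <- stimulation_frame()
  r <- angles_from_direction(fr, fr$z_hat)
  expect_equal(c(r$alpha, r$beta), c(0, 0), tolerance = 1e-9)
  expect_false(r$degenerate)
  pole <- angles_from_direction(fr, fr$x_hat)
  expect_true(pole$degenerate)
  expect_equal(pole$beta, 90, tolerance = 1e-9)
  expect_equal(pole$alpha, 0)
  set.seed(13)
  for (i in 1:25) {
    a <- stats::runif(1, -89, 89); b <- stats::runif(1, -89, 89)
    r <- angles_from_direction(fr, direction_vector(fr, a, b))
    expect_equal(c(r$alpha, r$beta), c(a, b), tolerance = 1e-6)
  }
  # antipodal input recovers the in-range representative
  v <- direction_vector(fr, 40, -30)
  r <- angles_from_direction(fr, -v)
  expect_equal(c(r$alpha, r$beta), c(40, -30), tolerance = 1e-6)
  expect_error(angles_from_direction(fr, c(2, 0, 0)), "unit")
})

test_that("angle_between reproduces printed angles and its invariances", {
  fr <- stimulation_frame()
  v <- random_unit()
  expect_equal(angle_between(v, v), 0)
  expect_equal(angle_between(v, -v), 180)
  expect_error(angle_between(c(0, 0, 0), v), "zero")
  # printed angle between the edge-minimum and VD-maximum directions
  a24 <- angle_between(direction_vector(fr, -49, 1),
                       direction_vector(fr, -45, 25))
  expect_equal(round(a24), 24)
  set.seed(17)
  u <- random_unit(); w <- random_unit()
  expect_equal(angle_between(u, w), angle_between(w, u))
  R <- rotation_about_axis(random_unit(), 77)
  expect_equal(angle_between(R %*% u, R %*% w), angle_between(u, w),
               tolerance = 1e-10)
})

test_that("angle_grid enumerates the sampling lattice", {
  g <- angle_grid()
  expect_equal(nrow(g), 169)
  expect_true(any(g$alpha_deg == 0 & g$beta_deg == 0))
  expect_equal(nrow(angle_grid(step = 90)), 9)
  expect_true(any(g$alpha_deg == -45 & g$beta_deg == 15))
  expect_false(any(g$alpha_deg == -45 & g$beta_deg == 25))
  # beta-major ordering: beta varies slowest
  expect_equal(g$beta_deg[1:13], rep(-90, 13))
  expect_error(angle_grid(step = 14), "divide")
})

test_that("symmetry identities hold as vector algebra, sign derived not assumed", {
  fr <- stimulation_frame()
  lattice <- expand.grid(a = seq(-90, 90, by = 5), b = seq(-90, 90, by = 5))
  pick <- lattice[seq(1, nrow(lattice), by = 37), ]
  for (i in seq_len(nrow(pick))) {
    a <- pick$a[i]; b <- pick$b[i]
    # (alpha+180, beta+180) lands on the SAME vector as (alpha, -beta)
    expect_equal(direction_vector(fr, a + 180, b + 180),
                 direction_vector(fr, a, -b), tolerance = 1e-12)
    # (alpha+180, beta) is its antipode
    expect_equal(direction_vector(fr, a + 180, b),
                 -direction_vector(fr, a, -b), tolerance = 1e-12)
  }
  s <- symmetry_image(180, 180)
  expect_equal(c(s$alpha, s$beta), c(0, 0))
  expect_equal(s$phase_sign, 1)
  s0 <- symmetry_image(0 + 180, 0 + 180)
  expect_equal(s0$phase_sign, 1)
})

test_that("wrap_angles returns an amplitude-equivalent in-range pair", {
  fr <- stimulation_frame()
  set.seed(19)
  cases <- cbind(stats::runif(20, -260, 260), stats::runif(20, -260, 260))
  for (i in seq_len(nrow(cases))) {
    a <- cases[i, 1]; b <- cases[i, 2]
    w <- wrap_angles(a, b)
    expect_true(w$alpha >= -90 - 1e-9 && w$alpha <= 90 + 1e-9)
    expect_true(w$beta >= -90 - 1e-9 && w$beta <= 90 + 1e-9)
    v1 <- direction_vector(fr, a, b)
    v2 <- direction_vector(fr, w$alpha, w$beta)
    expect_lt(min(sqrt(sum((v1 - v2)^2)), sqrt(sum((v1 + v2)^2))), 1e-9)
  }
})

test_that("frame YAML serialization round-trips", {
  fr <- stimulation_frame()
  tf <- tempfile(fileext = ".yaml")
  write_frame(fr, tf)
  fr2 <- read_frame(tf)
  expect_equal(fr2$origin, fr$origin)
  expect_equal(fr2$x_hat, fr$x_hat, tolerance = 1e-9)
  expect_equal(fr2$z_hat, fr$z_hat, tolerance = 1e-9)
})
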