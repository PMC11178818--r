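# Independent single-element assembly oracle: same continuum operator, but
# built from monomial-coefficient shape gradients and an independent 3-point
# Gauss rule (the implementation uses 2-point).
oracle_hex_K <- function(coords, E, nu) {
  corners <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1),
                                   z = c(-1, 1)))[c(1, 2, 4, 3, 5, 6, 8, 7), ]
  shape_d <- function(xi) {
    t(sapply(seq_len(8), function(a) {
      s <- corners[a, ]
      c(s[1] * (1 + xi[2] * s[2]) * (1 + xi[3] * s[3]),
        s[2] * (1 + xi[1] * s[1]) * (1 + xi[3] * s[3]),
        s[3] * (1 + xi[1] * s[1]) * (1 + xi[2] * s[2])) / 8
    }))
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6); D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu; diag(D)[4:6] <- mu
  gp <- c(-sqrt(3 / 5), 0, sqrt(3 / 5)); gw <- c(5, 8, 5) / 9
  K <- matrix(0, 24, 24)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    dN <- shape_d(c(gp[i], gp[j], gp[k]))  # 8 x 3, rows d/dxi per node
    J <- t(dN) %*% coords
    g <- t(solve(t(J), t(dN)))  # 8 x 3 global gradients
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      c0 <- 3 * (a - 1)
      B[1, c0 + 1] <- g[a, 1]; B[2, c0 + 2] <- g[a, 2]; B[3, c0 + 3] <- g[a, 3]
      B[4, c0 + 1] <- g[a, 2]; B[4, c0 + 2] <- g[a, 1]
      B[5, c0 + 2] <- g[a, 3]; B[5, c0 + 3] <- g[a, 2]
      B[6, c0 + 1] <- g[a, 3]; B[6, c0 + 3] <- g[a, 1]
    }
    K <- K + t(B) %*% D %*% B * det(J) * gw[i] * gw[j] * gw[k]
  }
  K
}

unit_cube <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0,
                      0, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, 1),
                    ncol = 3, byrow = TRUE)

test_that("hex8 stiffness matches an independent assembly oracle", {
  el <- hex8_element(unit_cube, E = 1, nu = 0, rho = 1)
  expect_lt(max(abs(el$K - oracle_hex_K(unit_cube, 1, 0))), 1e-10)
  # rectangular (still affine) element: quadrature also exact
  box <- unit_cube %*% diag(c(0.02, 0.01, 0.005))
  elb <- hex8_element(box, E = 3e9, nu = 0.3, rho = 1000)
  refb <- oracle_hex_K(box, 3e9, 0.3)
  expect_lt(max(abs(elb$K - refb)) / max(abs(refb)), 1e-10)
  # distorted element: constant-strain patch condition (exact under any
  # quadrature) and zero-energy rigid modes
  set.seed(101)
  warped <- unit_cube + matrix(stats::runif(24, -0.08, 0.08), 8, 3)
  el2 <- hex8_element(warped, E = 3e9, nu = 0.3, rho = 1000)
  G <- matrix(stats::rnorm(9, 0, 1e-3), 3, 3)
  u_lin <- as.vector(t(warped %*% t(G)))  # node-major (ux, uy, uz)
  eps <- c(G[1, 1], G[2, 2], G[3, 3], G[1, 2] + G[2, 1],
           G[2, 3] + G[3, 2], G[1, 3] + G[3, 1])
  lam <- 3e9 * 0.3 / (1.3 * 0.4); mu <- 3e9 / 2.6
  D <- matrix(0, 6, 6); D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu; diag(D)[4:6] <- mu
  expect_equal(sum(u_lin * (el2$K %*% u_lin)),
               el2$volume * sum(eps * (D %*% eps)), tolerance = 1e-10)
  u_rigid <- as.vector(t(sweep(warped * 0, 2, c(1, -2, 0.5), "+")))
  expect_lt(max(abs(el2$K %*% u_rigid)), 1e-9 * max(abs(el2$K)))
  expect_equal(el$K, t(el$K))
  # inverted element rejected
  flipped <- unit_cube; flipped[, 3] <- -flipped[, 3]
  expect_error(hex8_element(flipped, 1, 0, 1), "Jacobian")
})

test_that("assembled mass accounts for density, surface mass and attachment", {
  gr <- hex_grid(c(0.01, 0.01, 0.01), c(2, 2, 2))
  mats <- list(m = list(E = 1e9, nu = 0.25, rho = 1700, eta = 0))
  surf <- list(quads = rbind(c(1, 2, 5, 4)), density = 2.5)  # one face, kg/m^2
  mod <- fe_model(gr$nodes, gr$elems, rep("m", 8), mats,
                  fixed_nodes = 1L,
                  attachment = list(mass_kg = 1.6e-4, nodes = c(27L)),
                  surface_mass = surf)
  asm <- assemble(mod)
  expect_equal(asm$Kd, matrix(0, asm$ndof, asm$ndof))  # eta = 0 -> real K*
  got <- sum(asm$M[seq(1, asm$ndof, 3), seq(1, asm$ndof, 3)])
  want <- 1700 * 0.01^3 + 2.5 * 0.005^2 + 1.6e-4
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(asm$M, t(asm$M))
  expect_equal(asm$K, t(asm$K))
})

test_that("static uniaxial patch test is exact", {
  gr <- hex_grid(c(0.01, 0.01, 0.04), c(1, 1, 4))
  bot <- which(abs(gr$nodes[, 3]) < 1e-12)
  top <- which(abs(gr$nodes[, 3] - 0.04) < 1e-12)
  mats <- list(m = list(E = 1e9, nu = 0, rho = 1000, eta = 0))
  mod <- fe_model(gr$nodes, gr$elems, rep("m", nrow(gr$elems)), mats,
                  fixed_nodes = bot,
                  attachment = list(mass_kg = 1e-12, nodes = top))
  u <- solve_harmonic(mod, assemble(mod), 1, c(0, 0, 1), 0)
  # sigma = F/A = 1e4 Pa -> uz = sigma z / E, linear in z
  expect_equal(Re(u[, 3]), 1e4 * gr$nodes[, 3] / 1e9, tolerance = 1e-8)
  expect_lt(max(abs(Im(u))), 1e-15)
  # linearity: doubling the force doubles every amplitude
  u2 <- solve_harmonic(mod, assemble(mod), 2, c(0, 0, 1), 0)
  expect_equal(u2, 2 * u, tolerance = 1e-12)
})

test_that("undamped response is reciprocal", {
  gr <- hex_grid(c(0.02, 0.01, 0.01), c(4, 2, 2))
  mats <- list(m = list(E = 5e8, nu = 0.2, rho = 1200, eta = 0))
  mod <- fe_model(gr$nodes, gr$elems, rep("m", nrow(gr$elems)), mats,
                  fixed_nodes = which(abs(gr$nodes[, 1]) < 1e-12),
                  attachment = list(mass_kg = 1e-12, nodes = nrow(gr$nodes)))
  asm <- assemble(mod)
  A <- asm$K[asm$free, asm$free] - (2 * pi * 800)^2 * asm$M[asm$free, asm$free]
  set.seed(103)
  i <- sample(length(asm$free), 1); j <- sample(length(asm$free), 1)
  ei <- numeric(length(asm$free)); ei[i] <- 1
  ej <- numeric(length(asm$free)); ej[j] <- 1
  expect_equal(solve(A, ei)[j], solve(A, ej)[i], tolerance = 1e-8)
})

test_that("fixed-free rod resonance sits within 2% of the closed form", {
  # f1 = (1/4L) sqrt(E/rho) = 2500 Hz for L = 0.1 m, E = 1e9, rho = 1000
  gr <- hex_grid(c(0.1, 0.005, 0.005), c(20, 1, 1))
  mats <- list(m = list(E = 1e9, nu = 0, rho = 1000, eta = 0.01))
  tip <- which(abs(gr$nodes[, 1] - 0.1) < 1e-12)
  mod <- fe_model(gr$nodes, gr$elems, rep("m", nrow(gr$elems)), mats,
                  fixed_nodes = which(abs(gr$nodes[, 1]) < 1e-12),
                  attachment = list(mass_kg = 1e-12, nodes = tip))
  asm <- assemble(mod)
  fs <- seq(2350, 2650, by = 5)
  resp <- vapply(fs, function(f)
    max(Mod(solve_harmonic(mod, asm, 1, c(1, 0, 0), f)[tip, 1])),
    numeric(1))
  f_peak <- fs[which.max(resp)]
  expect_lt(abs(f_peak - 2500) / 2500, 0.02)
  # damped response is finite and continuous across the sweep
  expect_true(all(is.finite(resp)))
  expect_lt(max(abs(diff(log(resp)))), 1)
})

test_that("direction/frequency sweep has the right structure and symmetry", {
  model <- get_toy_model()
  asm <- get_toy_assembly()
  dirs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, 0, 1))
  sw <- sweep_harmonic(model, dirs, c(500, 2000), asm = asm)
  expect_length(sw$fields, 2)
  expect_length(sw$fields[[1]], 3)
  # antiparallel forces give fields of opposite sign (linearity)
  expect_equal(sw$fields[[1]][[2]], -sw$fields[[1]][[1]], tolerance = 1e-10)
  expect_false(any(vapply(sw$fields, function(fl)
    any(vapply(fl, function(u) any(!is.finite(Mod(u))), logical(1))),
    logical(1))))
  # fixed nodes stay put
  expect_equal(max(Mod(sw$fields[[1]][[1]][model$fixed_nodes, ])), 0)
})

test_that("model validation rejects broken inputs", {
  gr <- hex_grid(c(0.01, 0.01, 0.01), c(1, 1, 1))
  mats <- list(m = list(E = 1e9, nu = 0, rho = 1000, eta = 0))
  expect_error(fe_model(gr$nodes, gr$elems, "m", mats, fixed_nodes = integer()),
               "fixed")
  expect_error(fe_model(rbind(gr$nodes, c(9, 9, 9)), gr$elems, "m", mats,
                        fixed_nodes = 1L), "orphan")
  mod <- fe_model(gr$nodes, gr$elems, "m", mats, fixed_nodes = 1:4,
                  attachment = list(mass_kg = 1e-12, nodes = 8L))
  asm <- assemble(mod)
  expect_error(solve_harmonic(mod, asm, 1, c(1, 1, 0), 100), "unit")
  expect_error(solve_harmonic(mod, asm, -1, c(1, 0, 0), 100), "positive")
})
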