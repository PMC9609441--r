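test_that("kinetic and fracture energies follow their scaling laws", {
  expect_equal(kinetic_energy(100, 1270, 1e-18), 100 * 1270 * 1e-18)
  expect_equal(kinetic_energy(0, 1270, 1e-18), 0)
  # fracture energy density scales as Vi^(-5/12)
  e1 <- fracture_energy(0.3, 5e9, 2e4, 1e-27, 1e-18)
  e2 <- fracture_energy(0.3, 5e9, 2e4, 1e-27, 2e-18)
  expect_equal(e1 / e2, 2^(5 / 12), tolerance = 1e-12)
  expect_error(fracture_energy(0.3, 5e9, 2e4, 1e-27, 0), "vi")
})

test_that("de Vegt rate scales as x^(3/4) and is linear in c", {
  g <- default_grid()
  mech <- material_mechanics()
  S <- devegt_rate(g, 1e-3, mech)
  expect_true(all(S > 0))
  # exact power law across the grid
  expect_equal(log(S[-1] / S[-20]) / log(g$x[-1] / g$x[-20]),
               rep(0.75, 19), tolerance = 1e-10)
  expect_equal(devegt_rate(g, 2e-3, mech), 2 * S, tolerance = 1e-12)
  expect_error(devegt_rate(g, -1, mech), "c_rate")
})

test_that("cumulative breakage laws satisfy their boundary identities", {
  expect_equal(devegt_cumulative_b(1e-6, 1e-6), 1)
  expect_equal(kapur_cumulative_b(1e-6, 1e-6, 3), 1)
  expect_equal(austin_cumulative_b(1e-6, 1e-6, 0.4, 2, 5), 1)
  # Kapur with e = 1.25 is exactly the de Vegt law
  xi <- c(0.1, 0.3, 0.7) * 1e-6
  expect_equal(kapur_cumulative_b(xi, 1e-6, 1.25),
               devegt_cumulative_b(xi, 1e-6), tolerance = 1e-14)
  # Austin with phi = 1 is the Kapur law with e = gamma
  expect_equal(austin_cumulative_b(xi, 1e-6, 1, 2.5, 7),
               kapur_cumulative_b(xi, 1e-6, 2.5), tolerance = 1e-14)
  expect_error(devegt_cumulative_b(2e-6, 1e-6), "exceed")
  expect_error(austin_cumulative_b(1e-7, 1e-6, 1.2, 2, 5), "phi")
})

test_that("Austin rate vanishes below the critical size", {
  expect_equal(austin_rate(0.04e-6, 1e-3, 2, 0.05e-6), 0)
  expect_equal(austin_rate(0.05e-6, 1e-3, 2, 0.05e-6), 1e-3)
  expect_equal(austin_rate(0.1e-6, 1e-3, 2, 0.05e-6), 1e-3 * 2^2)
})

test_that("Kapur rate uses the micrometre scale", {
  expect_equal(kapur_rate(1e-6, 5e-4, 0.75), 5e-4)        # 1 um -> A
  expect_equal(kapur_rate(4e-6, 5e-4, 0.5), 5e-4 * 2)
  expect_error(kapur_rate(1e-6, -1, 0.75), "A")
})

test_that("discretized breakage matrix is lower triangular with unit column sums", {
  g <- default_grid()
  for (B in list(function(xi, xj) devegt_cumulative_b(xi, xj),
                 function(xi, xj) kapur_cumulative_b(xi, xj, 3),
                 function(xi, xj) austin_cumulative_b(xi, xj, 0.3, 0.8, 4))) {
    b <- discretize_breakage(B, g)
    expect_true(all(b[upper.tri(b, diag = TRUE)] == 0))
    expect_true(all(b >= 0))
    expect_equal(colSums(b)[-g$n], rep(1, g$n - 1), tolerance = 1e-12)
  }
  # non-monotone cumulative law is rejected
  expect_error(discretize_breakage(function(xi, xj) rev(xi) / xj, g),
               "monotone")
})

test_that("Kapur(e = 1.25) and de Vegt produce identical b matrices", {
  g <- default_grid()
  b_dv <- discretize_breakage(function(xi, xj) devegt_cumulative_b(xi, xj), g)
  b_kp <- discretize_breakage(function(xi, xj) kapur_cumulative_b(xi, xj, 1.25), g)
  expect_equal(b_dv, b_kp, tolerance = 1e-14)
})

test_that("breakage operator forces the finest bin to be a sink", {
  g <- default_grid()
  for (m in list(devegt_model(1e-3), kapur_model(e = 2, k = 1, A = 1e-3),
                 austin_model(0.5, 1, 4, 1e-3, 1))) {
    op <- breakage_operator(m, g)
    expect_equal(op$S[g$n], 0)
    expect_true(all(op$S[-g$n] >= 0))
  }
})

test_that("pbm_rhs conserves total mass pointwise", {
  g <- default_grid()
  op <- breakage_operator(kapur_model(e = 2, k = 1, A = 1e-3), g)
  w <- default_psd0(g)$w
  expect_equal(sum(pbm_rhs(w, op)), 0, tolerance = 1e-18)
  expect_error(pbm_rhs(w[-1], op), "dimension")
})

test_that("3-bin trajectory matches the matrix-exponential oracle within 1e-6", {
  skip_if_not_installed("Matrix")
  g <- size_grid(edges = c(4, 2, 1, 0.5) * 1e-6)
  w0 <- c(0.5, 0.3, 0.2)
  model <- kapur_model(e = 1.5, k = 0.75, A = 2e-3)
  op <- breakage_operator(model, g)
  # linear system dw/dt = (b - I) diag(S) w
  M <- (op$b - diag(3)) %*% diag(op$S)
  res <- simulate_milling(psd(g, w0), model, t_end = 1800, dt_out = 450)
  for (i in seq_along(res$times)) {
    w_exact <- as.numeric(Matrix::expm(M * res$times[i]) %*% w0)
    expect_equal(res$w[i, ], w_exact, tolerance = 1e-6)
  }
})
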