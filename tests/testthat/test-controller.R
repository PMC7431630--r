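test_that("critic signals follow the composite error definition", {
  g <- controller_gains()
  s0 <- compute_error_signals(10, 10, 0, 0, dt = 1e-3, gains = g)
  expect_equal(s0$e, 0)
  expect_equal(s0$edot, 0)
  expect_equal(s0$re, 0)
  s1 <- compute_error_signals(1, 0, 0, 0, dt = 1e-3, gains = g)
  expect_equal(s1$e, 1)
  expect_equal(s1$re, 2 + 2 * 0 + 2 * 1e-3, tolerance = 1e-9)
  # cost components at e = 1 mm, alpha = 0.1, L1 weighting (ke = 15):
  # Ee = 0.5 * 15 * re^2 with re = 2, Ealpha = 0.5 * 0.2 * 0.01
  re <- g$h1 * 1
  expect_equal(0.5 * 15 * re^2, 30)
  expect_equal(0.5 * g$kalpha * 0.1^2, 0.001)
  # anti-windup clamps the integral
  s2 <- compute_error_signals(1e5, 0, 0, 49.9, dt = 1, gains = g)
  expect_equal(s2$int_e, g$windup_mm_s)
})

test_that("fuzzy output is a normalized weighted mean with exact gradient", {
  net <- fuzzy_network()
  # all-zero weights: alpha = 0
  expect_equal(fuzzy_activation(rep(0, 49), 1, -5, net)$alpha, 0)
  # equal weights c: alpha = c for any input (normalization identity)
  for (cc in c(0.2, 0.7)) {
    for (e in c(-3, 0, 1.2)) {
      expect_equal(fuzzy_activation(rep(cc, 49), e, 4 * e, net)$alpha, cc,
                   tolerance = 1e-12)
    }
  }
  # gradient check: finite-difference dalpha/dw matches mu_i / sum(mu)
  set.seed(7)
  w <- runif(49, 0.2, 0.6)   # keeps output inside the unclipped region
  ev <- fuzzy_activation(w, 0.8, -6, net)
  h <- 1e-6
  for (i in c(1, 17, 25, 49)) {
    wp <- w; wp[i] <- wp[i] + h
    wm <- w; wm[i] <- wm[i] - h
    fd <- (fuzzy_activation(wp, 0.8, -6, net)$alpha_raw -
             fuzzy_activation(wm, 0.8, -6, net)$alpha_raw) / (2 * h)
    expect_lt(abs(fd - ev$mu_norm[i]), 1e-6)
  }
  expect_equal(sum(ev$mu_norm), 1)
})

test_that("weight update has the steepest-descent sign structure", {
  g <- controller_gains()
  net <- fuzzy_network()
  w <- rep(0, 49)
  ev <- fuzzy_activation(w, 0, 0, net)
  # no error, no activation: no update
  expect_equal(update_weights(w, ev$mu_norm, re = 0, alpha = 0, jsign = 1,
                              ke = 15, gains = g), w)
  # positive critic on the corrective side pushes every weight up
  dw <- update_weights(w, ev$mu_norm, re = 2, alpha = 0, jsign = 1,
                       ke = 15, gains = g) - w
  expect_true(all(dw >= 0))
  expect_gt(max(dw), 0)
  # algebraic fixed point: update vanishes when ke h1 re j = kalpha alpha
  alpha <- 0.4
  re_star <- g$kalpha * alpha / (15 * g$h1)
  expect_equal(
    update_weights(w, ev$mu_norm, re = re_star, alpha = alpha, jsign = 1,
                   ke = 15, gains = g),
    w, tolerance = 1e-15
  )
})

test_that("Jacobian signs follow the lateral pull direction", {
  geo <- spine_geometry()
  mus <- muscle_set(geo, D_mm = 50)
  left <- mus$side == "left"
  expect_true(all(mus$jsign[left] == -1))
  expect_true(all(mus$jsign[!left] == 1))
  # degenerate vertical line of action is rejected
  bad <- mus
  bad$origin_z_mm[1] <- bad$insertion_z_mm[1]
  expect_error(assign_jacobian_signs(bad), "Jacobian")
})

test_that("Jacobian sign matches a static perturbation of the plant", {
  # increase one muscle's activation on the otherwise unloaded spine and
  # re-solve the statics: the insertion node must move in the jsign direction
  geo <- spine_geometry()
  mus <- muscle_set(geo, D_mm = 50)
  for (row in c(1, 2, 9)) {        # L1 left, L1 right, L5 left
    m <- mus[row, ]
    node <- m$insertion_node
    org <- c(0, m$origin_z_mm / 1000)
    extra <- function(u) {
      ins <- geo$coords[node, ] + u[c(3 * node - 2, 3 * node - 1)]
      d <- org - ins
      l <- sqrt(sum(d^2))
      kin_f <- 0.01 * force_length(l * 1000, m$l0_mm) *
        force_velocity(0, 1) * m$f_max_N
      f <- numeric(18)
      f[c(3 * node - 2, 3 * node - 1)] <- kin_f * d / l
      list(f = f, K = NULL)
    }
    s <- static_solve(geo, numeric(18), extra_force = extra)
    expect_true(s$converged)
    dz <- s$u[3 * node - 1]
    expect_equal(sign(dz), m$jsign)
  }
})
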