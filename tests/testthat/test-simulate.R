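test_that("steady-state detection finds the earliest sustained window", {
  t <- seq(0, 5, by = 0.01)
  # constant history at target from the start: converged at window end
  d0 <- matrix(0, length(t), 2)
  v0 <- matrix(0, length(t), 2)
  det <- detect_steady_state(t, d0, v0, window_s = 1)
  expect_true(det$converged)
  expect_equal(det$t_converged, 1)
  # oscillation exceeding tolerance forever: never converged
  d1 <- matrix(0.5 * sin(20 * t), ncol = 1)
  det1 <- detect_steady_state(t, abs(d1), v0[, 1, drop = FALSE],
                              tol_pos_mm = 0.2, window_s = 1)
  expect_false(det1$converged)
  # settles at t = 2
  d2 <- matrix(pmax(0, 1 - t / 2), ncol = 1)
  det2 <- detect_steady_state(t, d2, v0[, 1, drop = FALSE],
                              tol_pos_mm = 0.2, window_s = 1)
  expect_true(det2$converged)
  expect_equal(det2$t_converged, 1.6 + 1, tolerance = 0.02)
})

test_that("a controlled run converges to the target posture", {
  sim <- case_sim(3)
  expect_false(sim$unstable)
  expect_true(sim$steady$converged)
  expect_lt(sim$steady$max_err_mm, 0.2)
  expect_lt(sim$steady$max_err_all_mm, 2)
  # activations are unilateral at steady state
  expect_true(all(active_per_level(sim$steady$alpha, sim$muscles) <= 1))
})

test_that("dynamic steady state agrees with the static control fixed point", {
  sim <- case_sim(3)
  st <- solve_control_static(3)
  expect_lt(st$residual_N, 1e-6)
  dyn <- section_loads(sim)$compression_N
  stat <- st$section_loads$compression_N
  expect_equal(dyn, stat, tolerance = 0.03)
})

test_that("the static residual of the plant vanishes at steady state", {
  sim <- case_sim(3)
  res <- sim$raw
  n <- length(res$time)
  u <- res$U[n, ]
  geo <- sim$geometry
  a <- assemble_tangent(geo, u)
  # external + muscle forces at the final state
  mus <- sim$muscles
  fext <- numeric(18)
  lev_nodes <- rev(geo$anatomical[-1])
  fext[3 * (lev_nodes - 1) + 1] <- -sim$case$P
  for (m in seq_len(nrow(mus))) {
    node <- mus$insertion_node[m]
    ins <- geo$coords[node, ] + u[c(3 * node - 2, 3 * node - 1)]
    d <- c(0, mus$origin_z_mm[m] / 1000) - ins
    l <- sqrt(sum(d^2))
    Fm <- muscle_force(res$alpha[n, m], l * 1000, 0, mus$l0_mm[m],
                       mus$ldot_max_mm_s[m], mus$f_max_N[m],
                       passive = mus$passive[m])
    fext[c(3 * node - 2, 3 * node - 1)] <-
      fext[c(3 * node - 2, 3 * node - 1)] + Fm * d / l
  }
  r <- a$f - fext
  expect_lt(sqrt(sum(r[4:18]^2)) / sqrt(sum(fext^2)), 1e-4)
})

test_that("without controllers the loaded column is flagged unstable", {
  sim <- simulate_case(3, control = FALSE,
                       config = simulation_config(t_end = 3))
  expect_true(sim$unstable)
  expect_false(isTRUE(sim$steady$converged))
})

test_that("zero external load needs no activation", {
  sim <- simulate_case(loading_case(P = rep(0, 5), D_mm = 50),
                       config = simulation_config(t_end = 3))
  expect_false(sim$unstable)
  expect_lt(max(sim$raw$alpha), 1e-6)
  expect_lt(max(abs(tidy(sim, "nodes")$error_mm)), 1e-6)
})

test_that("identical configurations give identical histories", {
  a <- simulate_case(2, config = simulation_config(t_end = 1.5))
  b <- simulate_case(2, config = simulation_config(t_end = 1.5))
  expect_identical(a$raw$U, b$raw$U)
  expect_identical(a$raw$alpha, b$raw$alpha)
})

test_that("perturbation pulses raise and lower the muscle force then re-converge", {
  sim <- cached("pert", run_perturbation(1, t_offset = 20))
  d <- tidy(sim, "muscles")
  d <- d[d$level == "L1" & d$side == "left", ]
  base <- mean(d$force_N[d$time_s > 19 & d$time_s < 20])
  down <- mean(d$force_N[d$time_s > 20.6 & d$time_s < 21.0])  # -100 N pulse
  up <- mean(d$force_N[d$time_s > 21.6 & d$time_s < 22.0])    # +100 N pulse
  expect_lt(down, base - 10)
  expect_gt(up, base + 10)
  dn <- tidy(sim, "nodes")
  expect_lt(max(abs(dn$error_mm[dn$time_s > 24])), 0.2)
  # zero-amplitude pulse reproduces the unperturbed run
  short <- simulation_config(t_end = 1)
  plain <- simulate_case(1, config = short)
  null_pulse <- simulate_case(
    1, config = short,
    pulses = tibble::tibble(t0 = 0.4, t1 = 0.6, level = "L1", dP = 0)
  )
  expect_identical(plain$raw$U, null_pulse$raw$U)
  # pulse outside the horizon is rejected
  expect_error(
    simulate_case(1, config = short,
                  pulses = tibble::tibble(t0 = 2, t1 = 3, level = "L1",
                                          dP = 10)),
    "horizon"
  )
})

test_that("load sweep forces scale linearly and stay unilateral", {
  sw <- sweep_sim()
  g <- glance(sw)
  expect_true(g$all_converged)
  expect_gt(g$min_r_squared_active, 0.99)
  per <- sw$forces |>
    dplyr::group_by(.data$L1_load_N, .data$level) |>
    dplyr::summarise(n_act = sum(.data$alpha > 0.01), .groups = "drop")
  expect_true(all(per$n_act <= 1))
  # repeating a load reproduces the same forces (determinism)
  f150 <- sw$forces$force_N[sw$forces$L1_load_N == 150]
  sw2 <- run_load_sweep(150)
  expect_equal(sw2$forces$force_N, f150)
  # a sweep of length one is flagged degenerate but reports forces
  expect_true(all(sw2$fits$degenerate))
  expect_true(all(is.na(sw2$fits$r_squared)))
  expect_error(run_load_sweep(c(150, 2000)), "range")
})

test_that("single-loop controller reaches its stationarity fixed point", {
  sim <- pair_sim(30)
  expect_true(sim$steady$converged)
  st <- stationarity_residual(sim)
  act <- st$alpha > 0.01
  expect_true(any(act))
  expect_lt(max(abs(st$resid[act])), 1e-3)
  # in the full redundant assembly the activation penalty keeps slowly
  # redistributing load; residuals stay small but nonzero
  st5 <- stationarity_residual(case_sim(3))
  expect_lt(max(abs(st5$resid[st5$alpha > 0.01])), 1)
})
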