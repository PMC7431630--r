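test_that("follower-load angle is the arctangent of shear over compression", {
  sl <- tibble::tibble(
    level = c("a", "b"), compression_N = c(100, 100), shear_N = c(0, 5)
  )
  a <- follower_load_angle(sl)
  expect_equal(a$per_level$angle_deg[1], 0)
  expect_equal(a$per_level$angle_deg[2], atan(0.05) * 180 / pi)
  expect_equal(a$per_level$angle_deg[2], 2.86, tolerance = 1e-3)
  expect_equal(a$max_angle_deg, max(a$per_level$angle_deg))
  # sign of the shear does not matter (absolute angle)
  sl$shear_N <- -sl$shear_N
  expect_equal(follower_load_angle(sl)$max_angle_deg, a$max_angle_deg)
  # degenerate resultant is rejected
  sl$compression_N <- c(0, 100)
  expect_error(follower_load_angle(sl), "positive")
})

test_that("section-frame angles are invariant under rigid rotation of the model", {
  # the same cantilever, horizontal and rotated 30 degrees, loaded by the
  # same force expressed in each frame: local compression/shear identical
  n <- 4L
  xs <- seq(0, 190, length.out = n + 1)
  geo1 <- spine_geometry(tibble::tibble(x_mm = xs, z_mm = 0))
  th <- 30 * pi / 180
  geo2 <- spine_geometry(tibble::tibble(
    x_mm = xs * cos(th), z_mm = xs * sin(th)
  ))
  Fax <- -30   # along the column axis
  Flat <- 2    # lateral
  f1 <- numeric(3 * (n + 1))
  f1[3 * n + 1] <- Fax
  f1[3 * n + 2] <- Flat
  f2 <- numeric(3 * (n + 1))
  f2[3 * n + 1] <- Fax * cos(th) - Flat * sin(th)
  f2[3 * n + 2] <- Fax * sin(th) + Flat * cos(th)
  s1 <- static_solve(geo1, f1)
  s2 <- static_solve(geo2, f2)
  sl1 <- recover_section_loads(geo1, s1$ends)
  sl2 <- recover_section_loads(geo2, s2$ends)
  expect_equal(sl2$compression_N, sl1$compression_N, tolerance = 1e-9)
  expect_equal(sl2$shear_N, sl1$shear_N, tolerance = 1e-9)
  a1 <- follower_load_angle(sl1)
  a2 <- follower_load_angle(sl2)
  expect_equal(a2$max_angle_deg, a1$max_angle_deg, tolerance = 1e-9)
})

test_that("summary writer round-trips the tables losslessly", {
  sim <- case_sim(3)
  dir <- withr::local_tempdir()
  paths <- write_summary(list(`3` = sim), dir,
                         equilibria = list(`3` = solve_follower_load(3)))
  expect_true(all(file.exists(paths)))
  sl <- utils::read.csv(paths[["section_loads"]])
  ctl <- sl[sl$model == "control", ]
  expect_equal(ctl$compression_N, section_loads(sim)$compression_N)
  expect_equal(ctl$shear_N, section_loads(sim)$shear_N)
  expect_error(write_summary(list(), dir), "no results")
})

test_that("toy fixtures carry their closed-form expectations", {
  fx <- make_toy_fixture("cantilever", L = 0.19, EI = 1.9, F = 1)
  expect_equal(fx$expected$tip_deflection_mm, 1.2033, tolerance = 1e-4)
  fb <- make_toy_fixture("column_buckling", L = 0.19, EI = 1.9)
  expect_equal(fb$expected$critical_load_N, 129.9, tolerance = 1e-3)
  fm <- make_toy_fixture("single_muscle", F = 10)
  # one-equation statics: tension * sin(phi) balances the lateral load
  phi <- atan2(50, 190)
  expect_equal(fm$expected$required_tension_N * sin(phi), 10,
               tolerance = 1e-12)
  expect_error(make_toy_fixture("unknown"), "arg")
})

test_that("tidiers and glance expose the result surfaces", {
  sim <- case_sim(3)
  nodes <- tidy(sim, "nodes")
  expect_true(all(c("time_s", "node", "error_mm") %in% names(nodes)))
  expect_equal(dplyr::n_distinct(nodes$node), 5)
  g <- glance(sim)
  expect_true(g$converged)
  expect_equal(g$n_active_muscles, sum(sim$steady$alpha > 0.01))
  eq <- solve_follower_load(3)
  expect_equal(nrow(tidy(eq)), 5)
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(autoplot(sweep_sim()), "ggplot")
  expect_s3_class(autoplot(compare_models(sim, eq)), "ggplot")
})
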