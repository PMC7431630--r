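# direct evaluations of the Hill factors, frozen from the closed forms

test_that("force-length quartic takes its exact values and clamps at zero", {
  expect_equal(force_length(1, 1), 5.1 - 29 + 56 - 41 + 10)  # = 1.1
  expect_equal(force_length(1, 1), 1.1)
  expect_equal(force_length(1e-9, 1), 5.1, tolerance = 1e-6)
  # real roots of the quartic bracket the negative region
  rts <- sort(Re(polyroot(c(5.1, -29, 56, -41, 10))[
    abs(Im(polyroot(c(5.1, -29, 56, -41, 10)))) < 1e-8]))
  expect_length(rts, 2)
  mid <- mean(rts)        # polynomial negative between the two real roots
  expect_equal(force_length(mid, 1), 0)
  expect_error(force_length(-1, 1), "positive")
  expect_error(force_length(1, 0), "positive")
})

test_that("force-velocity matches direct evaluation and is increasing", {
  expect_equal(force_velocity(0, 1),
               0.1433 / (0.1074 + exp(-1.409 * sinh(1.6))))
  expect_equal(force_velocity(0, 1), 1.005, tolerance = 1e-3)
  expect_equal(force_velocity(-1, 1), 0.0050, tolerance = 1e-2)
  # strictly increasing over the physiologic range (the exponential inner
  # term underflows in double precision beyond x ~ 0.77, where the factor
  # saturates numerically at its supremum 0.1433/0.1074)
  x <- seq(-1.5, 0.7, length.out = 201)
  expect_true(all(diff(force_velocity(x, 1)) > 0))
  x2 <- seq(-1.5, 2, length.out = 201)
  expect_true(all(diff(force_velocity(x2, 1)) >= 0))
  expect_true(all(force_velocity(x2, 1) > 0))
  expect_true(all(force_velocity(x2, 1) <= 0.1433 / 0.1074))
  expect_true(all(is.finite(force_velocity(c(-5, 5), 1))))
})

test_that("passive force is exponential in the length ratio", {
  expect_equal(passive_force(1, 1), exp(-10.671 + 7.675))
  expect_equal(passive_force(1, 1), 0.0500, tolerance = 1e-3)
  expect_equal(passive_force(1e-6, 1), exp(-10.671), tolerance = 1e-4)
  expect_equal(passive_force(2, 1) / passive_force(1, 1), exp(7.675))
})

test_that("muscle force composes the factors and clips activation", {
  expect_equal(muscle_force(0, 1, 0, 1, 10), 800 * passive_force(1, 1))
  expect_equal(muscle_force(0, 1, 0, 1, 10), 40, tolerance = 1e-2)
  expect_equal(muscle_force(1, 1, 0, 1, 10), 924, tolerance = 1e-3)
  expect_equal(muscle_force(0.5, 1, -10, 1, 10), 42.2, tolerance = 1e-2)
  # activation clipped to [0, 1]
  expect_equal(muscle_force(2, 1, 0, 1, 10), muscle_force(1, 1, 0, 1, 10))
  expect_equal(muscle_force(-1, 1, 0, 1, 10), muscle_force(0, 1, 0, 1, 10))
  # affine and increasing in alpha at fixed (l, ldot)
  a <- seq(0, 1, by = 0.25)
  f <- muscle_force(a, 1, 0, 1, 10)
  expect_true(all(diff(f) > 0))
  expect_equal(diff(f), rep(diff(f)[1], 4))
  # without the passive term, alpha = 0 transmits nothing
  expect_equal(muscle_force(0, 1, 0, 1, 10, passive = FALSE), 0)
  # C++ plant-side evaluation agrees with the R composition
  for (al in c(0, 0.3, 1)) {
    for (ld in c(-5, 0, 5)) {
      expect_equal(
        spinectrl:::cpp_muscle_force(0.19, ld / 1000, al, 0.2, 2, 800, TRUE),
        muscle_force(al, 0.19, ld / 1000, 0.2, 2, 800, passive = TRUE)
      )
    }
  }
})

test_that("muscle kinematics measure the deformed straight line", {
  geo <- spine_geometry()
  mus <- muscle_set(geo, D_mm = 50)
  kin <- muscle_kinematics(mus, geo)
  # L1 muscle on the +D side at the reference posture
  l1r <- kin$l_mm[kin$level == "L1" & kin$side == "right"]
  expect_equal(l1r, sqrt(190^2 + 40^2), tolerance = 1e-9)
  expect_equal(l1r, 194.2, tolerance = 1e-3)
  # zero velocity state: ldot = 0
  expect_equal(kin$ldot_mm_s, rep(0, 10))
  # insertion velocity parallel to the line of action: ldot = |v|
  v <- numeric(18)
  node <- mus$insertion_node[kin$level == "L1" & kin$side == "right"][1]
  uvec <- c(kin$ux, kin$uz)[c(2, 12)]  # ux, uz of that muscle (row 2)
  speed <- 3 / 1000                    # 3 mm/s along the line
  v[3 * (node - 1) + 1:2] <- speed * uvec
  kin2 <- muscle_kinematics(mus, geo, v = v)
  expect_equal(kin2$ldot_mm_s[2], 3, tolerance = 1e-9)
})

test_that("resting lengths default to the target posture", {
  geo <- spine_geometry()
  mus <- muscle_set(geo, D_mm = 50)
  kin <- muscle_kinematics(mus, geo)
  expect_equal(mus$l0_mm, kin$l_mm)
  expect_equal(mus$ldot_max_mm_s, mus$l0_mm / 0.1)
})
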