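geom <- pampa_geometry()

test_that("membrane retention follows the donor/acceptor mass balance", {
  # nothing moved: RM = 0
  r0 <- concentration_record(C_D0 = 1e-7, C_Dt = 1e-7, C_At = 0, t = 14400)
  expect_equal(membrane_retention(r0, geom), 0)

  # hand arithmetic: 1 - 0.5 - (10/9) * 0.3
  r <- concentration_record(C_D0 = 1e-7, C_Dt = 0.5e-7, C_At = 0.27e-7,
                            t = 14400)
  expect_equal(membrane_retention(r, geom), 1 - 0.5 - (0.2 / 0.18) * 0.27,
               tolerance = 1e-12)

  # everything retained is flagged as inconsistent (RM >= 1)
  r1 <- concentration_record(C_D0 = 1e-7, C_Dt = 0, C_At = 0, t = 14400)
  expect_error(membrane_retention(r1, geom), "RM")

  # small negative RM (noise) clamps to zero with a warning
  rneg <- concentration_record(C_D0 = 1e-7, C_Dt = 0.9e-7, C_At = 0.1e-7,
                               t = 14400)
  expect_warning(rm_ <- membrane_retention(rneg, geom), "clamped")
  expect_equal(rm_, 0)

  # large negative RM (mass creation) is rejected
  rbad <- concentration_record(C_D0 = 1e-7, C_Dt = 0.9e-7, C_At = 0.5e-7,
                               t = 14400)
  expect_error(membrane_retention(rbad, geom), "mass creation")
})

test_that("lag time grows affinely with retention", {
  expect_equal(lag_time(0), 60)
  expect_equal(lag_time(0.4), 90)
  rm_grid <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(lag_time(rm_grid)) > 0))
  # alternative reciprocal reading stays selectable
  expect_equal(lag_time(0, form = "reciprocal"), 300)
  expect_error(lag_time(1), "RM")
})

test_that("pe_iso is zero at the no-net-transfer boundary", {
  rm_ <- 0.3
  rec <- concentration_record(C_D0 = 1e-7, C_Dt = (1 - rm_) * 1e-7,
                              C_At = 0, t = 14400)
  sol <- pe_iso(rec, geom)
  expect_equal(sol$Pe, 0)
  expect_equal(sol$RM, rm_)
})

test_that("pe_iso inverts forward_simulate over a permeability/retention grid", {
  for (pe in 10^seq(-8, -4, by = 1)) {
    for (rm_ in c(0, 0.2, 0.5, 0.8)) {
      rec <- forward_simulate(Pe_DA = pe, RM = rm_, geom = geom, t = 14400)
      sol <- pe_iso(rec, geom)
      expect_equal(sol$Pe, pe, tolerance = 1e-10)
      expect_equal(sol$RM, rm_, tolerance = 1e-12)
    }
  }
})

test_that("forward_simulate obeys its physical limits and conserves mass", {
  # vanishing permeability: donor stays at (1 - RM), acceptor empty
  rec <- forward_simulate(Pe_DA = 1e-12, RM = 0.3, geom = geom, t = 14400)
  expect_equal(rec$C_Dt / rec$C_D0, 0.7, tolerance = 1e-4)
  expect_equal(rec$C_At / rec$C_D0, 0, tolerance = 1e-4)

  # long-time equilibrium plateau at (1 - RM) r_v / (1 + r_v)
  r_v <- geom$V_D / geom$V_A
  rec_inf <- forward_simulate(Pe_DA = 1e-5, RM = 0.3, geom = geom, t = 1e7)
  expect_equal(rec_inf$C_Dt / rec_inf$C_D0, 0.7 * r_v / (1 + r_v),
               tolerance = 1e-9)

  # exact mass conservation: donor + acceptor + retained = initial
  for (pe in c(1e-7, 1e-5)) for (rm_ in c(0, 0.4)) {
    rec <- forward_simulate(Pe_DA = pe, RM = rm_, geom = geom, t = 14400)
    lhs <- geom$V_D * rec$C_Dt + geom$V_A * rec$C_At +
      rm_ * geom$V_D * rec$C_D0
    expect_equal(lhs, geom$V_D * rec$C_D0, tolerance = 1e-15)
  }
})

test_that("pe_gradient reduces to pe_iso for symmetric permeabilities", {
  set.seed(11)
  for (case in 1:50) {
    pe <- 10^runif(1, -8, -4)
    rm_ <- runif(1, 0, 0.6)
    iso <- forward_simulate(Pe_DA = pe, RM = rm_, geom = geom, t = 14400)
    grad <- forward_simulate(Pe_DA = pe, Pe_AD = pe, RM = rm_, geom = geom,
                             t = 14400, pH_donor = 5)
    res <- pe_gradient(iso, grad, geom, tol = 1e-6)
    expect_true(res$converged)
    expect_equal(res$Pe_DA, pe_iso(iso, geom)$Pe, tolerance = 1e-6)
    expect_equal(res$r_a, geom$V_D / geom$V_A, tolerance = 1e-6)
    expect_lte(res$iterations, 100L)
  }
})

test_that("pe_gradient recovers asymmetric directional permeabilities", {
  pe_ad <- 5e-6; pe_da <- 1e-6; rm_ <- 0.2
  iso <- forward_simulate(Pe_DA = pe_ad, RM = rm_, geom = geom, t = 14400)
  grad <- forward_simulate(Pe_DA = pe_da, Pe_AD = pe_ad, RM = rm_,
                           geom = geom, t = 14400, pH_donor = 5)
  res <- pe_gradient(iso, grad, geom, tol = 1e-3)
  expect_true(res$converged)
  expect_equal(res$Pe_AD, pe_ad, tolerance = 1e-10)
  expect_equal(res$Pe_DA, pe_da, tolerance = 1e-3)
  expect_gte(res$iterations, 1L)

  # refinement consistency: tightening the tolerance moves the answer
  # by less than the loose tolerance
  res6 <- pe_gradient(iso, grad, geom, tol = 1e-6)
  expect_equal(res$Pe_DA, res6$Pe_DA, tolerance = 1e-3)
  expect_equal(res6$Pe_DA, pe_da, tolerance = 1e-6)
})

test_that("degenerate records surface clear errors", {
  # incubation shorter than the lag time
  rec <- forward_simulate(Pe_DA = 1e-6, RM = 0.4, geom = geom, t = 14400)
  rec_short <- concentration_record(rec$C_D0, rec$C_Dt, rec$C_At, t = 50)
  expect_error(pe_iso(rec_short, geom), "lag time")

  # past-equilibrium donor level: log argument non-positive
  r_v <- geom$V_D / geom$V_A
  # donor at 0.40 of initial with zero retention sits below the
  # equilibrium plateau r_v/(1 + r_v) = 0.474
  past <- concentration_record(C_D0 = 1e-7, C_Dt = 0.4e-7,
                               C_At = (0.18 / 0.2) * 0.6e-7, t = 14400)
  expect_error(pe_iso(past, geom), "equilibrium")

  # iso record must actually be iso-pH
  grad <- forward_simulate(Pe_DA = 1e-6, RM = 0.1, geom = geom,
                           t = 14400, pH_donor = 5)
  expect_error(pe_gradient(grad, grad, geom), "equal donor and acceptor pH")
})
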