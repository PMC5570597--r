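test_that("the equilibrated cell is at steady state", {
  eq <- equilibrated_default()
  expect_lt(abs(eq$Vm + 86), 1.5)
  ev <- ionic_current(eq$Vm, eq$state, membrane_params())
  expect_lt(abs(ev$I_ion), 0.01)
  expect_lt(max(abs(ev$dstate[1:13, ])), 1e-4)
})

test_that("a suprathreshold stimulus fires and repolarises", {
  tr <- run_single_cell(membrane_params(), n_beats = 1, bcl = 600,
                        t_end = 550, init = equilibrated_default())
  expect_gt(max(tr$Vm), 20)
  expect_lt(tr$Vm[which.min(abs(tr$t - 500))], -80)
})

test_that("the kernel matches an independent coding of the published cell model", {
  ref <- cellref_trace(t_end = 450, dt = 0.02, n_beats = 1,
                       equilibrate = 1000)
  p <- membrane_params(augmentation = FALSE)
  eq <- equilibrate_membrane(p, t_end = 1000)
  tr <- run_single_cell(p, n_beats = 1, t_end = 450, init = eq,
                        record_dt = 1)
  # compare away from the upstroke (1 sample of jitter there dominates)
  sel <- ref$t > 5 & ref$t < 440
  expect_lt(max(abs(tr$Vm[sel] - ref$Vm[sel])), 2)
  expect_lt(abs(apd90(tr$t, tr$Vm) - apd90(ref$t, ref$Vm)), 2)
})

test_that("state invariants are enforced", {
  eq <- equilibrated_default()
  bad <- eq$state; bad["m", 1] <- 1.5
  expect_error(ionic_current(-85, bad), "outside")
  expect_error(ionic_current(NaN, eq$state), "non-finite")
  expect_error(step_membrane(eq$state, eq$Vm, dt = -0.1), "positive")
})

test_that("augmentation currents vanish at rest and activate beyond +160 mV", {
  p <- membrane_params()
  eq <- equilibrate_membrane(p)
  virgin <- eq$state; virgin["pore", 1] <- 0
  expect_lt(abs(augmentation_currents(-85, virgin, p)), 1e-9)
  # the potassium component is negligible at +100 mV relative to +200 mV
  i100 <- augmentation_currents(100, virgin, p)
  i200 <- augmentation_currents(200, virgin, p)
  expect_lt(i100, 0.01 * i200)
  # disabled: identically zero
  p0 <- membrane_params(augmentation = FALSE)
  expect_identical(augmentation_currents(200, virgin, p0), 0)
})

test_that("a sustained +200 mV clamp draws more outward current with augmentation", {
  step_clamp <- function(aug) {
    p <- membrane_params(augmentation = aug)
    S <- equilibrate_membrane(p)$state
    out <- numeric(20)
    for (i in 1:20) {
      ev <- ionic_current(200, S, p)
      out[i] <- ev$I_ion
      S <- step_membrane(S, 200, dt = 0.5, params = p)$state
      S[, 1] <- pmin(pmax(S[, 1], 0), c(rep(1, 13), rep(Inf, 6)))
    }
    out
  }
  on <- step_clamp(TRUE); off <- step_clamp(FALSE)
  expect_true(all(on > off))
})

test_that("augmentation is inert over a paced beat at physiological voltages", {
  run <- function(aug) {
    p <- membrane_params(augmentation = aug)
    run_single_cell(p, n_beats = 1, t_end = 500,
                    init = equilibrate_membrane(p), record_dt = 1)$Vm
  }
  expect_lt(max(abs(run(TRUE) - run(FALSE))), 0.1)
})

test_that("time-step refinement converges: APD90 changes under 1 ms", {
  eq <- equilibrated_default()
  apds <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    tr <- run_single_cell(membrane_params(), n_beats = 1, t_end = 450,
                          dt = dt, init = eq, record_dt = 0.5)
    apd90(tr$t, tr$Vm)
  }, 0)
  expect_lt(abs(apds[1] - apds[2]), 1)
  expect_lt(abs(apds[2] - apds[3]), 1)
})

test_that("a zero-current clamp leaves the state unchanged", {
  eq <- equilibrated_default()
  S <- eq$state; V <- eq$Vm
  for (i in 1:500) {
    st <- step_membrane(S, V, dt = 0.02)
    S <- st$state; V <- st$Vm
  }
  expect_lt(max(abs(S - eq$state) / pmax(abs(eq$state), 1e-3)), 1e-3)
  expect_lt(abs(V - eq$Vm), 1e-2)
})

test_that("restitution sanity: APD90 at cycle length 500 ms is 250-350 ms", {
  tr <- run_single_cell(membrane_params(), n_beats = 5, bcl = 500,
                        init = equilibrated_default())
  a <- apd90(tr$t, tr$Vm, onset = 2000)
  expect_gt(a, 250)
  expect_lt(a, 350)
})

test_that("rate interpolation tables match direct evaluation", {
  v <- seq(-400.123, 400.321, by = 0.7123)  # off-grid sample points
  expect_lt(veshock:::cpp_tt04_table_error(v), 1e-4)
})

test_that("both model variants hit their published APD90 benchmarks", {
  apd_at_1000 <- function(variant) {
    p <- membrane_params(variant = variant)
    tr <- run_single_cell(p, n_beats = 1, bcl = 1000, t_end = 500,
                          init = equilibrate_membrane(p), record_dt = 0.5)
    apd90(tr$t, tr$Vm)
  }
  expect_lt(abs(apd_at_1000("hv2004") - 276), 8)   # published ~276 ms
  expect_lt(abs(apd_at_1000("hv2006") - 301), 8)   # published ~301 ms
  # short-APD arrhythmia variant: APD90 around 40 ms
  pv <- membrane_params_vt()
  trv <- run_single_cell(pv, n_beats = 2, bcl = 300, t_end = 600,
                         init = equilibrate_membrane(pv), record_dt = 0.5)
  a <- apd90(trv$t, trv$Vm, onset = 300)
  expect_gt(a, 25); expect_lt(a, 55)
})
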