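test_that("transcription follows leak + Hill induction per operator", {
  nl <- compiled_circuit("XOR")
  p <- expression_params()
  # no inducer: every wired species at leak x copy scale
  ab0 <- transcription_levels(nl, c(IPTG = 0, aTc = 0), p)
  expect_equal(unname(ab0[["T1"]]), 3 * p$leak_fraction)
  expect_equal(unname(ab0[["A1"]]), 9 * p$leak_fraction)
  # the (unwired) switch is fully transcribed
  expect_equal(unname(ab0[[names(nl$switches)[1]]]), 1)
  # saturation: theta -> 1
  ab_inf <- transcription_levels(nl, c(IPTG = 1e9, aTc = 1e9), p)
  expect_equal(unname(ab_inf[["T1"]]), 3, tolerance = 1e-6)
  # IPTG alone induces T1 and A2, leaves T2 and A1 at leak
  ab <- transcription_levels(nl, c(IPTG = p$on_conc, aTc = 0), p)
  expect_gt(ab[["T1"]], 2.9)
  expect_gt(ab[["A2"]], 8.7)
  expect_equal(unname(ab[["T2"]]), 3 * p$leak_fraction)
  expect_equal(unname(ab[["A1"]]), 9 * p$leak_fraction)
  expect_error(transcription_levels(nl, c(IPTG = -1), p), "negative")
  # master T7 switch off silences everything
  p_off <- expression_params(t7_induced = FALSE)
  expect_true(all(transcription_levels(nl, c(IPTG = 100), p_off) == 0))
})

test_that("equilibrium solver matches the closed-form two-species case", {
  p <- expression_params()
  withr::with_seed(31, {
    for (rep in 1:20) {
      S <- runif(1, 0.1, 10)
      T <- runif(1, 0.1, 10)
      K <- 10^runif(1, -2, 6)
      st <- solve_equilibrium(list(S = c(s = S), T = c(t = T),
                                   A = numeric(0)),
                              K = list(ST = matrix(K, 1, 1)),
                              params = p)
      expect_equal(st$ST[1, 1], oracle_two_species(S, T, K),
                   tolerance = 1e-9)
      expect_lt(st$residual, 1e-9)
    }
  })
})

test_that("solver limits: no binding and antisense-dominated binding", {
  p <- expression_params()
  st0 <- solve_equilibrium(list(S = c(s = 2), T = c(t = 3),
                                A = c(a = 4)),
                           K = list(ST = matrix(0, 1, 1),
                                    TA = matrix(0, 1, 1)), params = p)
  expect_equal(unname(st0$S), 2)
  expect_equal(unname(st0$T), 3)
  expect_equal(unname(st0$A), 4)
  expect_true(all(st0$ST == 0) && all(st0$TA == 0))

  # K_TA >> K_ST with excess antisense: the switch stays dark
  st <- solve_equilibrium(list(S = c(s = 1), T = c(t = 3), A = c(a = 5)),
                          K = list(ST = matrix(1e3, 1, 1),
                                   TA = matrix(1e8, 1, 1)), params = p)
  expect_lt(st$ST[1, 1] / 1, 0.05)
})

test_that("mass conservation holds across random binding systems", {
  p <- expression_params()
  withr::with_seed(73, {
    for (rep in 1:30) {
      ns <- sample(1:3, 1); nt <- sample(1:3, 1); na <- sample(1:3, 1)
      st <- solve_equilibrium(
        list(S = runif(ns, 0, 10), T = runif(nt, 0, 10),
             A = runif(na, 0, 10)),
        K = list(ST = matrix(10^runif(ns * nt, -3, 5), ns, nt),
                 TA = matrix(10^runif(nt * na, -3, 5), nt, na)),
        params = p)
      expect_lt(st$residual, 1e-9)
    }
  })
})

test_that("readout composes sensor occupancies by gate logic", {
  p <- expression_params()
  nl <- compiled_circuit("XOR")
  energies <- netlist_energies(nl)
  # no triggers (T7 off): basal level only
  st_off <- simulate_state(nl, c(IPTG = 0, aTc = 0),
                                       expression_params(t7_induced = FALSE),
                                       energies = energies)
  lvl_off <- readout(st_off, nl, p)
  expect_equal(unname(lvl_off["green"]), p$reporter_basal)

  # OR switch with sensor 1 fully triggered is within 1% of fully-on
  st_one <- simulate_state(nl, c(IPTG = p$on_conc, aTc = 0),
                                       p, energies = energies)
  st_both_triggers <- solve_equilibrium(
    list(S = st_one$totals$S, T = c(T1 = 3, T2 = 3),
         A = stats::setNames(c(0, 0), names(st_one$totals$A))),
    energies, p)
  lvl_one_only_trigger <- solve_equilibrium(
    list(S = st_one$totals$S, T = c(T1 = 3, T2 = 0),
         A = stats::setNames(c(0, 0), names(st_one$totals$A))),
    energies, p)
  l1 <- readout(lvl_one_only_trigger, nl, p)["green"]
  l2 <- readout(st_both_triggers, nl, p)["green"]
  expect_lt(abs(l2 - l1) / l2, 0.01)
})

test_that("AND sensors need both triggers", {
  p <- expression_params()
  ha <- compiled_circuit("HALF_ADDER")
  tt <- truth_table(ha, p)
  # one input high: red (CARRY) stays near basal (second-order leak)
  on_rows <- tt$IPTG + tt$aTc == 1
  expect_true(all(tt$level_red[on_rows] <
                    p$reporter_basal + 0.1 * p$reporter_gain))
  expect_true(all(!tt$call_red[on_rows]))
  expect_true(tt$call_red[tt$IPTG == 1 & tt$aTc == 1])
})

test_that("predicted truth tables match gate logic", {
  truth <- list(
    XOR = function(a, b) c(green = xor(a, b)),
    NAND = function(a, b) c(green = !(a && b)),
    HALF_ADDER = function(a, b) c(green = xor(a, b), red = a && b),
    HALF_SUBTRACTOR = function(a, b) c(green = xor(a, b),
                                       red = !a && b),
    FEYNMAN = function(a, b) c(green = xor(a, b), red = a)
  )
  for (circ in names(truth)) {
    nl <- compiled_circuit(circ)
    tt <- truth_table(nl)
    expect_equal(nrow(tt), 4)
    for (r in seq_len(nrow(tt))) {
      want <- truth[[circ]](tt$IPTG[r] == 1, tt$aTc[r] == 1)
      for (ch in names(want)) {
        expect_equal(tt[[paste0("call_", ch)]][r], unname(want[[ch]]),
                     info = sprintf("%s row %d channel %s", circ, r, ch))
      }
    }
  }
})

test_that("triggered fraction is monotone in cognate antisense", {
  p <- expression_params()
  withr::with_seed(19, {
    for (rep in 1:20) {
      K_ST <- 10^runif(1, 1, 5)
      K_TA <- 10^runif(1, 2, 8)
      S <- runif(1, 0.5, 3)
      T <- runif(1, 1, 6)
      prev <- Inf
      for (A in c(0, 1, 3, 9, 27)) {
        st <- solve_equilibrium(
          list(S = c(s = S), T = c(t = T), A = c(a = A)),
          K = list(ST = matrix(K_ST, 1, 1), TA = matrix(K_TA, 1, 1)),
          params = p)
        frac <- st$ST[1, 1] / S
        expect_lte(frac, prev + 1e-12)
        prev <- frac
      }
    }
  })
})

test_that("weakening the antisense never improves NIMPLY repression", {
  lib <- fixture_library()
  cfg_full <- design_config(rng_seed = 5)
  cfg_bulged <- design_config(rng_seed = 5, antisense_bulge = "single_nt")
  cfg_none <- design_config(rng_seed = 5, antisense_overhang_mode = "none",
                            antisense_bulge = "single_nt")
  repressed_level <- function(cfg) {
    nl <- assign_plasmids(wire_inducers(
      compile_gate(logic_spec("NIMPLY"), lib, cfg)))
    tt <- truth_table(nl)
    tt$level_green[tt$IPTG == 1 & tt$aTc == 1]
  }
  l_full <- repressed_level(cfg_full)
  l_bulged <- repressed_level(cfg_bulged)
  l_none <- repressed_level(cfg_none)
  expect_lte(l_full, l_bulged)
  expect_lte(l_bulged, l_none)
})

test_that("dose grids capture the digital XOR response surface", {
  nl <- compiled_circuit("XOR")
  p <- expression_params()
  m1 <- dose_grid(nl, list(IPTG = 0, aTc = 0), p)
  expect_equal(dim(m1), c(1, 1))
  expect_lt(m1[1, 1], attr(truth_table(nl, p), "threshold"))

  g <- c(0, 5, 20, 100)
  m <- dose_grid(nl, list(IPTG = g, aTc = g), p)
  # near-symmetric under input swap (the two NIMPLY arms are
  # independently designed, so only approximately)
  expect_equal(unname(m), unname(t(m)), tolerance = 0.05)
  # boundary rows respond monotonically to the crossing inducer
  expect_true(all(diff(m[1, ]) > -1e-9))
  expect_true(all(diff(m[nrow(m), ]) < 1e-9))
  expect_gte(xor_digitality(m), p$digitality_ratio)
})
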