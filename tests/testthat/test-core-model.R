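p <- model_parameters()

test_that("logistic gate has the standard form and symmetry", {
  expect_equal(logistic(0), 0.5)
  expect_gte(logistic(50), 1 - 1e-20)
  # tr_a*A + tr_i*i at A = 0, i = 10 with table coefficients
  expect_equal(logistic(-0.05 * 0 + 0.30 * 10), 1 / (1 + exp(-3)))
  expect_equal(logistic(3), 0.95257412682243336, tolerance = 1e-14)
  x <- seq(-8, 8, by = 0.37)
  expect_equal(logistic(-x), 1 - logistic(x))
  expect_true(all(diff(logistic(x)) > 0))
})

test_that("auxin source selects the scenario-specific rates", {
  expect_equal(auxin_source(5, "epidermis", "B", p), 8.36)
  expect_equal(auxin_source(15, "epidermis", "B", p), 22.53)
  expect_equal(auxin_source(10, "epidermis", "B", p), 8.36)  # 10 < z = 10.6
  expect_equal(auxin_source(11, "epidermis", "B", p), 22.53) # 11 >= z
  for (v in c("A", "B", "C", "D")) {
    spec <- if (v == "D") list(rates = rep(1, 40)) else NULL
    expect_equal(auxin_source(1:20, "cortex", v, p, spec), rep(0, 20))
  }
  expect_equal(auxin_source(1:3, "epidermis", "A", p, list(rate = 4)),
               rep(4, 3))
  expect_error(auxin_source(1:25, "epidermis", "D", p, list(rates = rep(1, 20))),
               "every position")
  expect_warning(
    val <- auxin_source(1:25, "epidermis", "C", p,
                        list(knot_x = c(1, 7, 13, 19, 25),
                             knot_y = c(10, -5, 10, 10, 10))),
    "clamped")
  expect_true(all(val >= 0))
})

test_that("auxin balance: source, wall fluxes, turnover", {
  cell <- new_cell("epidermis", i = 5, A = 0)
  expect_equal(auxin_rhs(cell, list(), params = p), 8.36)
  # two identical neighbors with equal facing PIN2: wall fluxes cancel
  a <- new_cell("epidermis", i = 5, A = 2,
                PINm = c(apical = 10, basal = 10, outer = 0))
  nb <- list(
    list(cell = a, face_self = "apical", face_neighbor = "basal"),
    list(cell = a, face_self = "basal", face_neighbor = "apical"))
  expect_equal(auxin_rhs(a, nb, params = p), 8.36 - p$d_a * 2)
  expect_error(auxin_rhs(a, list(list(cell = a, face_self = "up",
                                      face_neighbor = "basal"))),
               "face pairing")
  # external sink: pure removal through the named face
  sink <- list(list(cell = NULL, face_self = "outer"))
  b <- new_cell("epidermis", i = 15, A = 3,
                PINm = c(apical = 0, basal = 0, outer = 7))
  expect_equal(auxin_rhs(b, sink, params = p),
               22.53 - p$k_a * 3 * 7 - p$d_a * 3)
})

test_that("isolated-cell auxin steady state matches source/d_a", {
  f <- function(A) auxin_rhs(new_cell("epidermis", i = 5, A = A), list(),
                             params = p)
  A_star <- euler_to_steady(f, 0, dt = 1, t_end = 2500)
  expect_equal(A_star, 8.36 / 0.018, tolerance = 1e-3)
  expect_equal(8.36 / 0.018, 464.4444, tolerance = 1e-6)
})

test_that("cytoplasmic PIN2: synthesis, auxin-enhanced turnover, steady states", {
  none <- model_parameters(tr_wn = 0) # trafficking disabled on ammonium
  expect_equal(pin2_cytoplasm_rhs(new_cell("epidermis", PINc = 0), N = 0,
                                  params = none), 30.49)
  f0 <- function(x) pin2_cytoplasm_rhs(new_cell("epidermis", A = 0, PINc = x),
                                       N = 0, params = none)
  expect_equal(euler_to_steady(f0, 0, dt = 1, t_end = 500),
               30.49 / 0.065, tolerance = 1e-3)
  fq <- function(x) pin2_cytoplasm_rhs(new_cell("epidermis", A = 100, PINc = x),
                                       N = 0, params = none)
  expect_equal(euler_to_steady(fq, 0, dt = 1, t_end = 500),
               30.49 / (2 * 0.065), tolerance = 1e-3)
})

test_that("trafficking rate composes regime selection, gate and allocation", {
  cl <- new_cell("epidermis", i = 10, A = 0, PINc = 100)
  amm <- pin2_trafficking_rate(cl, N = 0, params = p)
  expect_equal(amm$total, 100 * 0.13 * logistic(3))
  expect_equal(unname(amm$allocation["outer"]), 0)
  nit <- pin2_trafficking_rate(cl, N = 1, params = p)
  expect_equal(nit$total, 100 * 0.246 * logistic(3), tolerance = 1e-12)
  expect_equal(nit$total, 23.4333, tolerance = 1e-4)
  expect_equal(unname(nit$allocation[c("outer", "apical")]), c(0.60, 0.40))
  # delivery debits the cytoplasm: rhs includes -total
  expect_equal(pin2_cytoplasm_rhs(cl, N = 1, params = p),
               30.49 - 0.065 * 100 - nit$total)
})

test_that("membrane PIN2: delivery, decay, nitrate switches the outer face on", {
  cl <- new_cell("epidermis", i = 4, A = 50, PINc = 0,
                 PINm = c(apical = 30, basal = 0, outer = 10))
  expect_equal(pin2_membrane_rhs(cl, "apical", N = 0, params = p),
               -0.065 * (1 + 0.5) * 30)
  # steady state with constant delivery T: PINm* = alloc * T / d_p at A = 0
  mk <- function(x) new_cell("epidermis", i = 10, A = 0, PINc = 100,
                             PINm = c(apical = x, basal = 0, outer = 0))
  fT <- function(x) pin2_membrane_rhs(mk(x), "apical", N = 0, params = p)
  Ttot <- pin2_trafficking_rate(mk(0), N = 0, params = p)$total
  expect_equal(euler_to_steady(fT, 0, dt = 1, t_end = 400), Ttot / 0.065,
               tolerance = 1e-3)
  # regime switch: the outer face gains delivery only under nitrate
  fresh <- new_cell("epidermis", i = 10, A = 0, PINc = 100)
  expect_equal(pin2_membrane_rhs(fresh, "outer", N = 0, params = p), 0)
  expect_gt(pin2_membrane_rhs(fresh, "outer", N = 1, params = p), 0)
})

test_that("division factor: synthesis/degradation structure", {
  z0 <- new_cell("epidermis", i = 3, A = 0, DIV = 0)
  z0$length <- 0
  expect_equal(division_factor_rhs(z0, maxA = 1, params = p), 0)
  zd <- z0; zd$DIV <- 5
  expect_equal(division_factor_rhs(zd, maxA = 1, params = p), -0.3 * 5)
  at_max <- new_cell("epidermis", i = 1, A = 1, DIV = 0)
  at_max$i <- 0; at_max$length <- 0
  expect_equal(division_factor_rhs(at_max, maxA = 1, params = p),
               1.5 * 20 / 2)
  expect_error(division_factor_rhs(z0, maxA = 0), "maxA")
  # synthesis decreases monotonically with position
  synth <- vapply(1:20, function(i) {
    c <- new_cell("epidermis", i = i, A = 1); c$length <- 0
    division_factor_rhs(c, maxA = 1, params = p)
  }, numeric(1))
  expect_true(all(diff(synth) < 0))
})

test_that("growth is auxin-gated logistic with saturating relative rate", {
  expect_equal(growth_rhs(new_cell("epidermis", A = 0), p), 0)
  full <- new_cell("epidermis", A = 5, length = 200)
  expect_equal(growth_rhs(full, p), 0)
  tiny <- new_cell("epidermis", A = 1e6, length = 0.01)
  expect_equal(growth_rhs(tiny, p) / (0.3 * 0.01), 1, tolerance = 1e-4)
  over <- new_cell("epidermis", A = 1, length = 150)
  over$length <- 250
  expect_warning(r <- growth_rhs(over, p), "clamped")
  expect_equal(r, 0)
})
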