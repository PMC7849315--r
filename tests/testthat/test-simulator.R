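p <- model_parameters()

# Assemble the full rhs of one cell from the exported R primitives, using
# the simulator's wall topology (shootward apical walls, shared lateral
# wall between files, window-top export).
r_rhs_state <- function(state, params, N) {
  n <- length(state$epidermis$A)
  maxA <- max(c(state$epidermis$A, state$cortex$A))
  get_cell <- function(fl, file, k) {
    new_cell(file, i = k, length = fl$length[k],
             zone = if (fl$zone[k] == 0) "meristem" else "elongation",
             A = fl$A[k], PINc = fl$PINc[k],
             PINm = c(apical = fl$PINm_apical[k], basal = fl$PINm_basal[k],
                      outer = fl$PINm_outer[k]), DIV = fl$DIV[k])
  }
  out <- list()
  for (file in c("epidermis", "cortex")) {
    fl <- state[[file]]
    other <- state[[setdiff(c("epidermis", "cortex"), file)]]
    other_name <- setdiff(c("epidermis", "cortex"), file)
    dA <- dPc <- dPa <- dPo <- dDIV <- dL <- numeric(n)
    for (k in seq_len(n)) {
      cell <- get_cell(fl, file, k)
      nb <- list()
      if (k > 1) nb <- c(nb, list(list(cell = get_cell(fl, file, k - 1),
                                       face_self = "basal",
                                       face_neighbor = "apical")))
      nb <- c(nb, if (k < n) {
        list(list(cell = get_cell(fl, file, k + 1), face_self = "apical",
                  face_neighbor = "basal"))
      } else {
        list(list(cell = NULL, face_self = "apical")) # window-top export
      })
      nb <- c(nb, list(list(cell = get_cell(other, other_name, k),
                            face_self = "outer", face_neighbor = "outer")))
      dA[k] <- auxin_rhs(cell, nb, variant = "B", params = params)
      dPc[k] <- pin2_cytoplasm_rhs(cell, N = N, params = params)
      dPa[k] <- pin2_membrane_rhs(cell, "apical", N = N, params = params)
      dPo[k] <- pin2_membrane_rhs(cell, "outer", N = N, params = params)
      dDIV[k] <- division_factor_rhs(cell, maxA = maxA, params = params)
      dL[k] <- growth_rhs(cell, params = params)
    }
    out[[file]] <- list(A = dA, PINc = dPc, PINm_apical = dPa,
                        PINm_outer = dPo, DIV = dDIV, length = dL)
  }
  out
}

test_that("one integrator step matches the R-level right-hand sides", {
  st <- nontrivial_state(p) # 6 cells per file, fewer than the window
  pp <- p
  for (cond in c("ammonium", "nitrate")) {
    N <- as.integer(cond == "nitrate")
    dt <- 1e-6
    run <- run_simulation(pp, cond, dt = dt, horizon = dt, method = "euler",
                          init = st, events = FALSE)
    want <- r_rhs_state(st, pp, N)
    for (file in c("epidermis", "cortex")) {
      for (q in names(want[[file]])) {
        got <- (run[[file]][[q]] - st[[file]][[q]]) / dt
        expect_equal(got, want[[file]][[q]], tolerance = 1e-6,
                     label = paste(cond, file, q))
      }
    }
  }
})

test_that("Euler and RK4 agree to 0.1% as the step shrinks", {
  e <- run_simulation(p, "nitrate", dt = 2.5e-4, horizon = 5, method = "euler")
  r <- run_simulation(p, "nitrate", dt = 1e-3, horizon = 5, method = "rk4")
  for (q in c("A", "PINc", "PINm_apical", "PINm_outer", "DIV", "length")) {
    expect_equal(e$epidermis[[q]], r$epidermis[[q]], tolerance = 1e-3,
                 label = q)
  }
})

test_that("auxin mass ledger closes to 1e-8 relative over 1e4 steps", {
  run <- run_simulation(p, "nitrate", dt = 0.001, horizon = 10)
  expect_lte(run$ledger$max_rel_closure_error, 1e-8)
  lg <- run$ledger
  expect_equal(lg$final_auxin,
               lg$initial_auxin + lg$input - lg$degradation -
                 lg$boundary_efflux - lg$advection_loss,
               tolerance = 1e-10)
})

test_that("runs are deterministic and keep all pools non-negative", {
  a <- run_simulation(p, "nitrate", dt = 0.001, horizon = 20)
  b <- run_simulation(p, "nitrate", dt = 0.001, horizon = 20)
  expect_identical(a$epidermis, b$epidermis)
  expect_identical(a$cortex, b$cortex)
  set.seed(11)
  for (rep in 1:4) {
    st <- nontrivial_state(p)
    for (f in c("epidermis", "cortex")) {
      st[[f]]$A <- st[[f]]$A * runif(6, 0, 2)
      st[[f]]$PINm_outer <- st[[f]]$PINm_outer * runif(6, 0, 2)
    }
    run <- run_simulation(p, sample(c("ammonium", "nitrate"), 1),
                          dt = 0.001, horizon = 2, init = st)
    pools <- unlist(run$epidermis[c("A", "PINc", "PINm_apical", "PINm_basal",
                                    "PINm_outer", "DIV", "length")])
    expect_true(all(pools >= -1e-12))
  }
})

test_that("the stability bound triggers a named error", {
  st <- initial_root_state(p)
  st$epidermis$PINm_apical <- rep(2000, p$window)
  st$epidermis$A <- rep(1, p$window)
  expect_error(run_simulation(p, "ammonium", dt = 0.001, horizon = 1,
                              init = st),
               "unstable")
})

test_that("division halves daughters, conserves amounts and logs position", {
  st <- initial_root_state(p)
  st$epidermis$DIV[3] <- 20      # above DIV_thr with length 10 >= 7
  st$epidermis$A[3] <- 0.5
  st$epidermis$A[20] <- 50       # holds maxA so cell 3 stays meristematic
  dt <- 1e-5
  run <- run_simulation(p, "ammonium", dt = dt, horizon = dt, init = st)
  expect_equal(length(run$epidermis$A), p$window) # trimmed back to window
  expect_equal(run$epidermis$length[3], 5, tolerance = 1e-3)
  expect_equal(run$epidermis$length[4], 5, tolerance = 1e-3)
  expect_equal(run$epidermis$DIV[3], 0)
  expect_equal(run$epidermis$DIV[4], 0)
  expect_equal(run$epidermis$A[3], run$epidermis$A[4], tolerance = 1e-6)
  expect_equal(run$division_log$epidermis[3], 1)
  expect_lte(run$ledger$max_rel_closure_error, 1e-10) # conservation incl. event
})

test_that("elongation transition uses a closed threshold, one-way", {
  pp <- model_parameters(maxA_mode = 1, DIV_thr = 1e6)
  thr <- pp$A_thr_ammonium
  st <- initial_root_state(pp)
  st$epidermis$A[5] <- thr + 1e-9   # at/above threshold
  st$epidermis$A[6] <- thr - 1e-3   # just below
  dt <- 1e-6
  run <- run_simulation(pp, "ammonium", dt = dt, horizon = dt, init = st)
  expect_equal(run$epidermis$zone[5], 1L)
  expect_equal(run$epidermis$zone[6], 0L)
  # the same auxin level that transitions on ammonium can stay
  # meristematic on nitrate (higher threshold)
  st2 <- initial_root_state(pp)
  st2$epidermis$A[5] <- (pp$A_thr_ammonium + pp$A_thr_nitrate) / 2
  run_a <- run_simulation(pp, "ammonium", dt = dt, horizon = dt, init = st2)
  run_n <- run_simulation(pp, "nitrate", dt = dt, horizon = dt, init = st2)
  expect_equal(run_a$epidermis$zone[5], 1L)
  expect_equal(run_n$epidermis$zone[5], 0L)
})

test_that("all-zero sources collapse to the trivial state", {
  pz <- model_parameters(s1 = 0, s2 = 0)
  run <- run_simulation(pz, "nitrate", dt = 0.001, horizon = 40)
  expect_lt(max(run$epidermis$A, run$cortex$A), 1e-8)
  expect_equal(run$epidermis$length, rep(10, pz$window)) # growth stalled
})

test_that("steady summaries are insensitive to the naive initialization", {
  r1 <- cached_regime_run("ammonium")
  init2 <- initial_root_state(p, length = 12, PINc = 100)
  r2 <- run_simulation(p, "ammonium", dt = 0.001, horizon = 300,
                       snapshot_every = 2, init = init2)
  s1 <- summarize_run(r1); s2 <- summarize_run(r2)
  expect_equal(s1$onset_index[["epidermis"]], s2$onset_index[["epidermis"]])
  expect_equal(s1$meristem_size_um[["epidermis"]],
               s2$meristem_size_um[["epidermis"]], tolerance = 0.025)
})

test_that("summaries: division fractions, onsets, single-cell toy state", {
  run <- cached_regime_run("ammonium")
  s <- summarize_run(run)
  for (f in c("epidermis", "cortex")) {
    d <- s$division_fractions[[f]]
    if (sum(d) > 0) expect_equal(sum(d), 1)
  }
  # division events concentrate inside the meristem, near-zero beyond onset
  dfrac <- s$division_fractions$epidermis
  onset <- s$onset_index[["epidermis"]]
  expect_gt(sum(dfrac[seq_len(onset)]), 0.95)
  expect_gte(min(s$onset_index), 1)
  # single-cell toy state: meristem size equals that cell's length
  toy <- run
  one <- function(fl) lapply(fl, `[`, 1)
  toy$epidermis <- one(run$epidermis); toy$epidermis$zone <- 0L
  toy$cortex <- one(run$cortex); toy$cortex$zone <- 0L
  toy$snapshots <- list()
  st <- summarize_run(toy)
  expect_equal(st$meristem_size_um[["epidermis"]], toy$epidermis$length[1])
  expect_error(summarize_run(structure(list(epidermis = list(A = numeric(0)),
                                            params = p),
                                       class = "nitroroot_run")),
               "empty")
})

test_that("steady-state membrane PIN2 contrasts between regimes", {
  ss_a <- steady_state_profile(p, "ammonium")
  ss_n <- steady_state_profile(p, "nitrate")
  # nitrate exceeds ammonium in apical+outer membrane PIN2 at every index
  tot_a <- ss_a$PINm_apical + ss_a$PINm_outer
  tot_n <- ss_n$PINm_apical + ss_n$PINm_outer
  expect_true(all(tot_n > tot_a))
  # outer-face share equals l_n * N exactly at steady state
  expect_equal(ss_n$PINm_outer / (ss_n$PINm_apical + ss_n$PINm_outer),
               rep(p$l_n, nrow(ss_n)))
  expect_true(all(ss_a$PINm_outer == 0))
  # total membrane PIN2 is non-decreasing in the basal trafficking rates
  tots <- vapply(c(0.1, 0.2, 0.3, 0.4), function(tr) {
    ss <- steady_state_profile(model_parameters(tr_n = tr), "nitrate")
    sum(ss$PINm_apical + ss$PINm_outer)
  }, numeric(1))
  expect_true(all(diff(tots) > 0))
  # lateralization index (apical+basal over outer): finite and lower on
  # nitrate than the ammonium Inf (no lateral signal) in the cortex
  lat_n <- (ss_n$PINm_apical + ss_n$PINm_basal) / ss_n$PINm_outer
  expect_equal(unique(round(lat_n, 10)), round(0.4 / 0.6, 10))
  expect_true(all(is.infinite(
    (ss_a$PINm_apical[1:3] + ss_a$PINm_basal[1:3]) /
      pmax(ss_a$PINm_outer[1:3], 0))))
})
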