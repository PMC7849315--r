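#' Initial (naive) root state
#'
#' Both files start as `window` meristematic cells of 10 micrometres with
#' no auxin, no membrane PIN2, no division factor, and the cytoplasmic
#' PIN2 pool at its trafficking-free steady state `m_p / d_p`.
#'
#' @param params a [model_parameters()] object.
#' @param length initial cell length (micrometres).
#' @param PINc initial cytoplasmic PIN2 (default `m_p / d_p`).
#' @return A list with elements `epidermis` and `cortex`, each a list of
#'   per-cell state vectors (`A`, `PINc`, `PINm_apical`, `PINm_basal`,
#'   `PINm_outer`, `DIV`, `length`, `zone`).
#' @export
initial_root_state <- function(params = model_parameters(), length = 10,
                               PINc = NULL) {
  n <- params$window
  if (is.null(PINc)) PINc <- params$m_p / params$d_p
  one <- list(A = rep(0, n), PINc = rep(PINc, n),
              PINm_apical = rep(0, n), PINm_basal = rep(0, n),
              PINm_outer = rep(0, n), DIV = rep(0, n),
              length = rep(length, n), zone = rep(0L, n))
  list(epidermis = one, cortex = one)
}

#' Run the multicellular root simulation
#'
#' Advances the two cell files through time with a fixed-step integrator
#' (classical RK4 by default, explicit Euler as a cross-check option).
#' After every step the elongation transition (relative auxin at or above
#' the regime-dependent threshold; one-way), cell divisions (division
#' factor at or above `DIV_thr` and length at or above `min_div_length`;
#' daughters split all amounts 50/50 and reset the division factor), and
#' window advection (cells pushed past `window` are dropped and their
#' auxin booked to the ledger) are applied. The auxin mass ledger
#' accumulates source input, degradation, shootward boundary efflux and
#' advection loss with the same quadrature weights as the state update,
#' so it closes to machine precision.
#'
#' The run is fully deterministic: no randomness enters the dynamics.
#'
#' @param params a [model_parameters()] object.
#' @param regime a [nitrogen_regime()], regime string, or condition name.
#' @param variant auxin-source scenario, see [auxin_source()].
#' @param source_spec variant-specific source description.
#' @param dt time step (model time units). The run stops with an error if
#'   `dt` times the largest per-pool rate coefficient reaches 0.5.
#' @param horizon maximum simulated time.
#' @param method `"rk4"` or `"euler"`.
#' @param snapshot_every snapshot cadence in time units (`NULL` records
#'   only initial and final states).
#' @param ss_tol relative change in file-level summaries between
#'   checkpoints below which the run is declared steady and stopped early
#'   (`0` disables the check).
#' @param ss_interval checkpoint spacing (time units) for the steady-state
#'   test.
#' @param init initial state, as returned by [initial_root_state()].
#' @param events apply transition/division/advection events (disable for
#'   pure-ODE integration checks).
#' @return An object of class `"nitroroot_run"`: final per-file state,
#'   `time`, `ledger`, `division_log`, `snapshots`, `converged` flag and
#'   the run configuration.
#' @examples
#' \donttest{
#' run <- run_simulation(regime = "nitrate", horizon = 50)
#' summarize_run(run)$onset_index
#' }
#' @export
run_simulation <- function(params = model_parameters(),
                           regime = "ammonium", variant = "B",
                           source_spec = NULL, dt = 0.001, horizon = 300,
                           method = c("rk4", "euler"),
                           snapshot_every = NULL, ss_tol = 0,
                           ss_interval = 10, init = NULL, events = TRUE) {
  method <- match.arg(method)
  validate_parameters(params)
  if (is.character(regime)) {
    regime <- if (regime %in% c("ammonium", "nitrate")) {
      condition_regime(regime)
    } else {
      nitrogen_regime(regime)
    }
  }
  stopifnot(inherits(regime, "nitroroot_regime"), dt > 0, horizon > 0)
  if (is.null(init)) init <- initial_root_state(params)
  src <- auxin_source(seq_len(params$window), "epidermis", variant, params,
                      source_spec)
  snap_every <- if (is.null(snapshot_every)) 0L else
    max(1L, as.integer(round(snapshot_every / dt)))
  sched <- as.matrix(regime$schedule[, c("time", "N")])
  res <- .sim_run_cpp(init, unclass(params), sched, src, dt, horizon,
                      method, snap_every, ss_tol, ss_interval, events)
  res$params <- params
  res$regime <- regime
  res$variant <- variant
  res$config <- list(dt = dt, horizon = horizon, method = method,
                     source_spec = source_spec)
  class(res) <- "nitroroot_run"
  res
}

#' @export
print.nitroroot_run <- function(x, ...) {
  cat("<nitroroot simulation run>\n")
  cat("  time:", format(x$time), if (isTRUE(x$converged)) "(steady)" else
    "(horizon reached)", "\n")
  cat("  cells:", length(x$epidermis$A), "epidermis,",
      length(x$cortex$A), "cortex\n")
  cat("  ledger max rel closure error:",
      format(x$ledger$max_rel_closure_error, digits = 3), "\n")
  invisible(x)
}

file_df <- function(fl, file, time = NA_real_, maxA = NA_real_) {
  n <- length(fl$A)
  data.frame(time = time, file = file, i = seq_len(n), length = fl$length,
             zone = ifelse(fl$zone == 0L, "meristem", "elongation"),
             A = fl$A, relative_auxin = if (is.finite(maxA) && maxA > 0)
               fl$A / maxA else NA_real_,
             PINc = fl$PINc, PINm_apical = fl$PINm_apical,
             PINm_basal = fl$PINm_basal, PINm_outer = fl$PINm_outer,
             DIV = fl$DIV)
}

#' Tidy per-cell table of a run (final state or all snapshots)
#'
#' @param run a [run_simulation()] result.
#' @param snapshots if `TRUE`, stack all recorded snapshots; otherwise
#'   return the final state only.
#' @return A data frame with one row per cell: `time`, `file`, `i`,
#'   `length`, `zone`, `A`, `relative_auxin`, `PINc`, `PINm_apical`,
#'   `PINm_basal`, `PINm_outer`, `DIV`.
#' @export
trajectory_table <- function(run, snapshots = FALSE) {
  stopifnot(inherits(run, "nitroroot_run"))
  if (!snapshots || length(run$snapshots) == 0) {
    maxA <- run$maxA
    return(rbind(file_df(run$epidermis, "epidermis", run$time, maxA),
                 file_df(run$cortex, "cortex", run$time, maxA)))
  }
  do.call(rbind, lapply(run$snapshots, function(s) {
    mA <- max(c(s$epidermis$A, s$cortex$A, 0))
    rbind(file_df(s$epidermis, "epidermis", s$time, mA),
          file_df(s$cortex, "cortex", s$time, mA))
  }))
}

onset_of <- function(zone_vec, window) {
  idx <- which(zone_vec == 1L)
  if (length(idx) == 0) as.integer(window) + 1L else as.integer(min(idx))
}

#' Summary statistics of a simulation run
#'
#' Reduces a run to the model's reported quantities: per-file meristem
#' size (micrometres from the QC to the first elongation-zone cell, and
#' cell count), elongation onset index, the division-event fraction per
#' position, per-position profiles, the PIN2 lateralization index
#' (apical + basal signal over outer signal; `Inf` where the outer face
#' is empty), and the synchrony index (absolute difference of the two
#' files' onset indices, in cells). A file in which no cell has
#' transitioned reports onset `window + 1`.
#'
#' The long-run state is a division/growth limit cycle, not a fixed
#' point, so instantaneous zonation statistics oscillate by one to two
#' cells. When the run carries snapshots, onset indices are therefore
#' reported as the median, and meristem sizes as the mean, over the
#' trailing third of the recorded snapshots; profiles always come from
#' the final state.
#'
#' @param run a [run_simulation()] result.
#' @return A list with elements `meristem_size_um`, `meristem_cells`,
#'   `onset_index`, `synchrony_index`, `division_fractions`, `profiles`
#'   and `lateralization_index`.
#' @export
summarize_run <- function(run) {
  stopifnot(inherits(run, "nitroroot_run"))
  if (length(run$epidermis$A) == 0) stop("empty trajectory", call. = FALSE)
  window <- run$params$window
  files <- list(epidermis = run$epidermis, cortex = run$cortex)
  if (length(run$snapshots) >= 3) {
    times <- vapply(run$snapshots, function(s) s$time, numeric(1))
    late <- run$snapshots[times >= max(times) * 2 / 3]
    onset_mat <- vapply(late, function(s) {
      c(onset_of(s$epidermis$zone, window), onset_of(s$cortex$zone, window))
    }, numeric(2))
    onset <- apply(onset_mat, 1, stats::median)
    names(onset) <- names(files)
    mer_um <- vapply(seq_along(files), function(k) {
      mean(vapply(late, function(s) {
        f <- s[[names(files)[k]]]
        m <- onset_of(f$zone, window) - 1L
        if (m <= 0) 0 else sum(f$length[seq_len(min(m, length(f$length)))])
      }, numeric(1)))
    }, numeric(1))
    names(mer_um) <- names(files)
    mer_cells <- onset - 1
  } else {
    onset <- vapply(files, function(f) onset_of(f$zone, window), integer(1))
    mer_cells <- onset - 1L
    mer_um <- vapply(names(files), function(nm) {
      f <- files[[nm]]
      k <- min(mer_cells[[nm]], length(f$length))
      if (k <= 0) 0 else sum(f$length[seq_len(k)])
    }, numeric(1))
  }
  div <- run$division_log
  divfrac <- lapply(div, function(d) {
    tot <- sum(d)
    if (tot > 0) d / tot else d
  })
  prof <- trajectory_table(run)
  lat <- (prof$PINm_apical + prof$PINm_basal) / prof$PINm_outer
  prof$lateralization_index <- lat
  list(meristem_size_um = mer_um, meristem_cells = mer_cells,
       onset_index = onset,
       synchrony_index = abs(onset[["epidermis"]] - onset[["cortex"]]),
       division_fractions = divfrac, profiles = prof,
       lateralization_index = lat)
}

#' Calibrate the elongation thresholds to target onset positions
#'
#' Finds, by bisection, the relative-auxin threshold for each nitrogen
#' condition such that the steady-state epidermal elongation onset sits at
#' the target cell position (defaults: cell 11 on ammonium, cell 13 on
#' nitrate, the experimentally observed onsets). Onset position is a
#' non-decreasing step function of the threshold, so bisection brackets
#' the target plateau and the midpoint of the bracket is returned.
#'
#' Because the long-run state is a limit cycle, the onset used here is
#' the median onset over the trailing third of snapshots recorded every
#' two time units (see [summarize_run()]).
#'
#' @param params base parameters (the returned thresholds override
#'   `A_thr_ammonium` / `A_thr_nitrate`).
#' @param targets named integer vector of target epidermal onsets.
#' @param dt,horizon integration settings passed to [run_simulation()].
#' @param tol bisection interval width at which to stop.
#' @return Named numeric vector `c(ammonium = , nitrate = )`.
#' @export
calibrate_elongation_thresholds <- function(params = model_parameters(),
                                            targets = c(ammonium = 11,
                                                        nitrate = 13),
                                            dt = 0.001, horizon = 300,
                                            tol = 0.002) {
  out <- numeric(0)
  for (cond in names(targets)) {
    onset_at <- function(thr) {
      p <- params
      p$A_thr_ammonium <- thr
      p$A_thr_nitrate <- thr
      run <- run_simulation(p, regime = cond, dt = dt, horizon = horizon,
                            snapshot_every = 2)
      summarize_run(run)$onset_index[["epidermis"]]
    }
    lo <- 0.05; hi <- 0.95
    if (onset_at(lo) > targets[[cond]] || onset_at(hi) < targets[[cond]]) {
      stop("target onset ", targets[[cond]], " not bracketed for ", cond,
           call. = FALSE)
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (onset_at(mid) >= targets[[cond]]) hi <- mid else lo <- mid
    }
    out[cond] <- (lo + hi) / 2
  }
  out
}
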