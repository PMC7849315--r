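# Seeded generators that emulate the study's measurement structure:
# cell-length profiles calibrated to the printed position-10..20 slopes,
# model-based steady-state observations for recovery tests, and
# ratiometric (Venus/Tomato) auxin-reporter profiles.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Default calibration of the phenomenological generators
#'
#' Carries, per (condition, tissue): the meristematic baseline length
#' `L0`, the elongation-onset position, the target ordinary-least-squares
#' slope of mean cell length over positions 10-20 (the study's printed
#' values: ammonium 3.32639 / 1.22033 and nitrate 1.70502 / 0.82342
#' micrometres per cell for epidermis / cortex), and the Gamma noise
#' shape. The epidermal onsets are the observed positions 11 (ammonium)
#' and 13 (nitrate); cortex onsets are not printed and are set to 13 in
#' both conditions (cortex elongation is delayed on ammonium and matched
#' to the epidermis on nitrate). Also carries the ratiometric-reporter
#' block (per-condition profile shapes and noise) and reference PIN2
#' face-intensity contrasts.
#'
#' @param ... named overrides (`lengths`, `r2d2`, `pin2` blocks).
#' @return A list of class `"nitroroot_calibration"`.
#' @export
generator_calibration <- function(...) {
  cal <- list(
    lengths = data.frame(
      condition = rep(c("ammonium", "nitrate"), each = 2),
      tissue = rep(c("epidermis", "cortex"), 2),
      L0 = 10,
      onset = c(11, 13, 13, 13),
      slope = c(3.32639, 1.22033, 1.70502, 0.82342),
      shape = 25,
      stringsAsFactors = FALSE),
    r2d2 = list(
      baseline = 0.22, noise_shape = 60,
      # per-condition rise of the underlying auxin index beyond onset
      epidermis = list(ammonium = list(onset = 11, gain = 0.09),
                       nitrate = list(onset = 13, gain = 0.05)),
      cortex = list(ammonium = list(onset = 11, gain = 0.005),
                    nitrate = list(onset = 13, gain = 0.05))),
    pin2 = list(membrane_total = c(ammonium = 240, nitrate = 300),
                lateralization = c(ammonium = Inf, nitrate = 0.67)))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cal))
  if (length(unknown)) {
    stop("unknown calibration block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cal[names(dots)] <- dots
  structure(cal, class = "nitroroot_calibration")
}

# Mean length curve: flat baseline below the onset, linear beyond it, with
# the per-segment slope chosen in closed form so that the OLS slope of the
# mean curve over positions lo..hi equals `target`.
length_mean_curve <- function(L0, onset, target, positions = 1:20,
                              lo = 10, hi = 20) {
  x <- lo:hi
  g <- pmax(0, x - onset + 1)
  cx <- (x - mean(x)) / sum((x - mean(x))^2)
  denom <- sum(cx * g)
  if (denom <= 0) stop("onset too distal for the slope window", call. = FALSE)
  m_seg <- target / denom
  mu <- L0 + m_seg * pmax(0, positions - onset + 1)
  if (any(mu <= 0)) stop("infeasible slope/onset combination", call. = FALSE)
  mu
}

#' Generate synthetic cell-length profiles
#'
#' Draws per-root cell-length observations for positions 1-20 in both
#' tissues of one condition. The mean curve is flat at `L0` below the
#' onset position and linear beyond it, with the segment slope solved in
#' closed form so that the expected OLS slope over positions 10-20 equals
#' the calibration target; observations are Gamma distributed around the
#' mean (shape from the calibration), matching the noise family used for
#' the study's length regressions.
#'
#' @param calibration a [generator_calibration()].
#' @param condition `"ammonium"` or `"nitrate"`.
#' @param n_roots number of replicate roots (>= 2).
#' @param seed integer seed; the generator is a pure function of
#'   (calibration, condition, n_roots, seed).
#' @param noiseless if `TRUE`, return the mean curve itself (the
#'   deterministic limit of infinite Gamma shape).
#' @return A validated observation table with `measurement == "length"`.
#' @export
generate_length_profiles <- function(calibration = generator_calibration(),
                                     condition = c("ammonium", "nitrate"),
                                     n_roots = 18, seed = 1,
                                     noiseless = FALSE) {
  condition <- match.arg(condition)
  stopifnot(n_roots >= 2)
  blocks <- calibration$lengths
  blocks <- blocks[blocks$condition == condition, , drop = FALSE]
  positions <- 1:20
  out <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(blocks)), function(b) {
      row <- blocks[b, ]
      mu <- length_mean_curve(row$L0, row$onset, row$slope, positions)
      do.call(rbind, lapply(seq_len(n_roots), function(r) {
        val <- if (noiseless) mu else
          stats::rgamma(length(mu), shape = row$shape,
                        rate = row$shape / mu)
        data.frame(condition = condition, tissue = row$tissue,
                   position = positions, replicate = paste0("root", r),
                   measurement = "length", value = val,
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  rownames(out) <- NULL
  validate_observations(out)
  out
}

#' Generate model-based steady-state observations
#'
#' Simulate-then-corrupt generator for parameter-recovery and
#' model-comparison studies: evaluates the positional steady state of the
#' transport subsystem ([steady_state_profile()]) under the requested
#' source scenario and wraps each per-position prediction in
#' multiplicative Gamma noise with coefficient of variation `cv`
#' (`cv = 0` returns the predictions exactly). Zero-mean records (e.g.
#' the outer face on ammonium) are kept as exact zeros.
#'
#' @param params,variant,source_spec model configuration, see
#'   [steady_state_profile()].
#' @param conditions conditions to include.
#' @param measurements subset of `"relative_auxin"`, `"pin2_apical"`,
#'   `"pin2_outer"`, `"pin2_basal"`.
#' @param n_roots replicate roots per condition.
#' @param cv noise coefficient of variation (>= 0).
#' @param seed integer seed.
#' @param positions positions from the QC.
#' @return A validated observation table; the included measurements are
#'   recorded in `attr(, "measurements")`.
#' @export
generate_model_observations <- function(params = model_parameters(),
                                        variant = "B", source_spec = NULL,
                                        conditions = c("ammonium", "nitrate"),
                                        measurements = c("relative_auxin",
                                                         "pin2_apical",
                                                         "pin2_outer"),
                                        n_roots = 5, cv = 0.05, seed = 1,
                                        positions = 1:20) {
  stopifnot(cv >= 0, n_roots >= 1)
  measurements <- match.arg(measurements,
                            c("relative_auxin", "pin2_apical", "pin2_outer",
                              "pin2_basal"), several.ok = TRUE)
  preds <- do.call(rbind, lapply(conditions, function(cond) {
    steady_state_profile(params, cond, variant, source_spec,
                         n_pos = max(positions))
  }))
  colmap <- c(relative_auxin = "relative_auxin", pin2_apical = "PINm_apical",
              pin2_outer = "PINm_outer", pin2_basal = "PINm_basal")
  out <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(preds)), function(k) {
      row <- preds[k, ]
      if (!(row$i %in% positions)) return(NULL)
      do.call(rbind, lapply(measurements, function(m) {
        mu <- row[[colmap[[m]]]]
        val <- if (cv == 0 || mu <= 0) rep(mu, n_roots) else
          mu * stats::rgamma(n_roots, shape = 1 / cv^2, rate = 1 / cv^2)
        if (m == "relative_auxin") val <- pmin(val, 1)
        data.frame(condition = row$condition, tissue = row$file,
                   position = row$i, replicate = paste0("root", seq_len(n_roots)),
                   measurement = m, value = val, stringsAsFactors = FALSE)
      }))
    }))
  })
  rownames(out) <- NULL
  validate_observations(out)
  attr(out, "measurements") <- measurements
  out
}

#' Normalize a ratiometric auxin-reporter profile
#'
#' Converts paired degradable (Venus) and stable (Tomato) reporter
#' signals into a relative auxin profile: the ratio `r = venus/tomato`
#' is inverted (auxin degrades the Venus moiety, so low ratio means high
#' auxin) and scaled by its maximum, giving values in (0, 1] with 1 at
#' the position of highest auxin activity.
#'
#' @param venus,tomato positive numeric vectors of equal length.
#' @return Relative auxin per position, in (0, 1].
#' @examples
#' normalize_r2d2(c(2, 1), c(2, 2)) # c(0.5, 1)
#' @export
normalize_r2d2 <- function(venus, tomato) {
  stopifnot(length(venus) == length(tomato))
  if (any(tomato <= 0)) stop("tomato signal must be positive", call. = FALSE)
  if (any(venus <= 0)) stop("venus signal must be positive", call. = FALSE)
  inv <- tomato / venus
  inv / max(inv)
}

#' Generate synthetic ratiometric-reporter profiles
#'
#' Draws per-root Venus/Tomato signal pairs whose normalized profiles
#' reproduce the observed auxin-activity contrasts: on ammonium the
#' epidermal profile rises steeply beyond the onset position while the
#' cortex stays near baseline; on nitrate both files share a common
#' trend. Signals carry Gamma noise; each root is normalized by its own
#' maximum (per-root normalization).
#'
#' @param calibration a [generator_calibration()].
#' @param condition `"ammonium"` or `"nitrate"`.
#' @param n_roots replicate roots.
#' @param seed integer seed.
#' @param positions positions from the QC.
#' @return A validated observation table with
#'   `measurement == "relative_auxin"`.
#' @export
generate_r2d2_profiles <- function(calibration = generator_calibration(),
                                   condition = c("ammonium", "nitrate"),
                                   n_roots = 5, seed = 1, positions = 1:20) {
  condition <- match.arg(condition)
  cal <- calibration$r2d2
  shape <- cal$noise_shape
  out <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_roots), function(r) {
      sig <- lapply(c("epidermis", "cortex"), function(ts) {
        blk <- cal[[ts]][[condition]]
        u <- cal$baseline + blk$gain * pmax(0, positions - blk$onset + 1)
        tomato <- stats::rgamma(length(positions), shape = shape,
                                rate = shape / 100)
        venus_mu <- 100 / u
        venus <- stats::rgamma(length(positions), shape = shape,
                               rate = shape / venus_mu)
        list(venus = venus, tomato = tomato)
      })
      names(sig) <- c("epidermis", "cortex")
      # per-root normalization across both tissues jointly
      inv <- lapply(sig, function(s) s$tomato / s$venus)
      mx <- max(unlist(inv))
      do.call(rbind, lapply(c("epidermis", "cortex"), function(ts) {
        data.frame(condition = condition, tissue = ts, position = positions,
                   replicate = paste0("root", r),
                   measurement = "relative_auxin",
                   value = inv[[ts]] / mx, stringsAsFactors = FALSE)
      }))
    }))
  })
  rownames(out) <- NULL
  validate_observations(out)
  out
}
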