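#' Model parameters for the two-file root growth model
#'
#' Constructs the full parameter set of the multicellular root model:
#' auxin sources and transport, PIN2 synthesis/degradation/trafficking,
#' division-factor kinetics, and zone-dependent growth. Defaults are the
#' posterior-mean estimates of the model's calibration plus a small set of
#' package-level constants (elongation thresholds, division trigger, window
#' size) documented in the methods vignette.
#'
#' Units: lengths in micrometres, auxin and PIN2 pools in arbitrary units,
#' time in model units fixed by the normalization `k_a = 1` (only the ratio
#' `d_a / k_a = 0.018` is identified).
#'
#' @param ... named overrides of any default parameter, e.g. `l_n = 0.5`.
#'
#' @return An object of class `"nitroroot_params"` (a named list).
#'
#' @details Parameter meanings:
#' * `s1`, `s2`: auxin source rates into epidermal cells below / at-or-above
#'   the source-switch index `z` (QC-proximal production vs the influx from
#'   the lateral root cap).
#' * `k_a`: carrier-mediated (PIN2-proportional) auxin transport rate;
#'   `d_a`: first-order auxin turnover.
#' * `m_p`, `d_p`, `q_p`: basal PIN2 synthesis, basal degradation, and the
#'   auxin scale at which degradation is enhanced (degradation rate
#'   `d_p * (1 + A / q_p)`).
#' * `l_n`: fraction of trafficked PIN2 redirected to the lateral (outer)
#'   face under nitrate; `tr_n` / `tr_wn`: basal trafficking rates on
#'   nitrate / ammonium; `tr_a`, `tr_i`: logistic coefficients on auxin and
#'   on cell index gating the trafficking flux.
#' * `k_v0`..`k_v4`, `t_v`, `h1`, `h2`: division-factor synthesis and
#'   degradation constants (Hill-type auxin modulation, positional
#'   restriction `1 / (1 + exp(i * t_v))`).
#' * `k_l_meristem`, `k_l_elongation`, `m_l_meristem`, `m_l_elongation`:
#'   logistic growth rate and maximum length per zone.
#' * `maxA_mode`: `"dynamic"` (maximum auxin over all windowed cells of both
#'   files, recomputed each step) or a fixed positive number; `maxL`:
#'   length normalization of the division-factor synthesis term.
#' * `A_thr_ammonium`, `A_thr_nitrate`: relative-auxin thresholds that
#'   trigger the meristem-to-elongation transition; defaults were frozen
#'   from [calibrate_elongation_thresholds()] so that default steady states
#'   place the epidermal elongation onset at cell 11 (ammonium) and
#'   cell 13 (nitrate).
#' * `DIV_thr`, `min_div_length`: division-factor threshold and minimum
#'   length for mitosis; `window`: number of cells retained per file.
#' * `literal_equations`: if `TRUE`, trafficking does not debit the
#'   cytoplasmic pool and membrane PIN2 does not decay (the non-conservative
#'   literal reading of the trafficking rule, for comparison runs only).
#'
#' @examples
#' p <- model_parameters()
#' p$tr_n
#' p2 <- model_parameters(l_n = 0.5, window = 30)
#' @export
model_parameters <- function(...) {
  p <- list(
    s1 = 8.36, s2 = 22.53, z = 10.6,
    k_a = 1, d_a = 0.018,
    m_p = 30.49, d_p = 0.065, q_p = 100,
    l_n = 0.60, tr_n = 0.246, tr_wn = 0.13, tr_a = -0.05, tr_i = 0.30,
    k_v0 = 1.5, k_v1 = 20, k_v2 = 0.3, k_v3 = 3.5, k_v4 = 0.5,
    t_v = 0.1, h1 = 2, h2 = 3,
    k_l_meristem = 0.3, k_l_elongation = 0.3,
    m_l_meristem = 200, m_l_elongation = 200,
    maxA_mode = "dynamic", maxL = 200,
    A_thr_ammonium = 0.4833, A_thr_nitrate = 0.5149,
    DIV_thr = 8, min_div_length = 7,
    window = 40,
    literal_equations = FALSE
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  p <- structure(p, class = "nitroroot_params")
  validate_parameters(p)
  p
}

#' Validate a parameter object
#'
#' Checks sign, range and type invariants of a [model_parameters()] object
#' and errors on the first violation.
#'
#' @param p a `"nitroroot_params"` object.
#' @return `p`, invisibly.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "nitroroot_params"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  nonneg <- c("s1", "s2", "k_a", "d_a", "m_p", "d_p", "q_p",
              "tr_n", "tr_wn", "tr_i", "k_v0", "k_v1", "k_v2", "k_v3",
              "k_v4", "t_v", "k_l_meristem", "k_l_elongation",
              "m_l_meristem", "m_l_elongation", "maxL",
              "A_thr_ammonium", "A_thr_nitrate", "DIV_thr",
              "min_div_length")
  for (nm in nonneg) {
    if (!num1(p[[nm]]) || p[[nm]] < 0) {
      stop("parameter '", nm, "' must be a single non-negative number",
           call. = FALSE)
    }
  }
  if (!num1(p$tr_a)) stop("parameter 'tr_a' must be a finite number", call. = FALSE)
  if (!num1(p$l_n) || p$l_n < 0 || p$l_n > 1) {
    stop("parameter 'l_n' must lie in [0, 1]", call. = FALSE)
  }
  if (!num1(p$h1) || p$h1 < 1 || !num1(p$h2) || p$h2 < 1) {
    stop("Hill exponents 'h1' and 'h2' must be >= 1", call. = FALSE)
  }
  if (!num1(p$z) || p$z <= 0) stop("'z' must be > 0", call. = FALSE)
  if (!num1(p$window) || p$window < 20 || p$window != round(p$window)) {
    stop("'window' must be an integer >= 20", call. = FALSE)
  }
  if (is.character(p$maxA_mode)) {
    if (!identical(p$maxA_mode, "dynamic")) {
      stop("'maxA_mode' must be \"dynamic\" or a fixed positive number",
           call. = FALSE)
    }
  } else if (!num1(p$maxA_mode) || p$maxA_mode <= 0) {
    stop("'maxA_mode' must be \"dynamic\" or a fixed positive number",
         call. = FALSE)
  }
  if (!is.logical(p$literal_equations) || length(p$literal_equations) != 1L) {
    stop("'literal_equations' must be TRUE or FALSE", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.nitroroot_params <- function(x, ...) {
  cat("<nitroroot model parameters>\n")
  num <- vapply(x, is.numeric, logical(1))
  vals <- unlist(x[num])
  cat(paste0("  ", format(names(vals)), " = ", format(vals, digits = 6)),
      sep = "\n")
  cat("  maxA_mode =", if (is.character(x$maxA_mode)) x$maxA_mode else
    format(x$maxA_mode), "\n")
  cat("  literal_equations =", x$literal_equations, "\n")
  invisible(x)
}

#' Nitrogen regime (binary nitrate schedule)
#'
#' A nitrogen regime is a piecewise-constant, right-continuous binary
#' signal over time: `N = 1` on nitrate, `N = 0` on ammonium. Transfer
#' experiments (growth on ammonium, then transfer onto nitrate) are
#' encoded as a schedule of switch times.
#'
#' @param schedule a data frame with columns `time` (strictly increasing,
#'   first entry covers the simulation start) and `N` (0 or 1), or a
#'   regime string such as `"0:ammonium,500:nitrate"`.
#' @return An object of class `"nitroroot_regime"`.
#' @examples
#' r <- nitrogen_regime("0:ammonium,500:nitrate")
#' regime_n(r, 100) # 0
#' regime_n(r, 500) # 1 (right-continuous)
#' @export
nitrogen_regime <- function(schedule) {
  if (is.character(schedule) && length(schedule) == 1L) {
    parts <- strsplit(schedule, ",", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    bad <- vapply(kv, length, integer(1)) != 2L
    if (any(bad)) stop("malformed regime string: ", schedule, call. = FALSE)
    times <- as.numeric(vapply(kv, `[`, character(1), 1L))
    lab <- vapply(kv, `[`, character(1), 2L)
    n <- ifelse(lab %in% c("nitrate", "1"), 1,
                ifelse(lab %in% c("ammonium", "0"), 0, NA))
    if (anyNA(times) || anyNA(n)) {
      stop("regime entries must be time:ammonium or time:nitrate", call. = FALSE)
    }
    schedule <- data.frame(time = times, N = n)
  }
  stopifnot(is.data.frame(schedule), all(c("time", "N") %in% names(schedule)))
  schedule <- schedule[order(schedule$time), c("time", "N"), drop = FALSE]
  if (nrow(schedule) < 1L) stop("empty regime schedule", call. = FALSE)
  if (any(diff(schedule$time) <= 0)) {
    stop("regime switch times must be strictly increasing", call. = FALSE)
  }
  if (!all(schedule$N %in% c(0, 1))) {
    stop("N must be binary (0 = ammonium, 1 = nitrate)", call. = FALSE)
  }
  structure(list(schedule = schedule), class = "nitroroot_regime")
}

#' Evaluate a nitrogen regime at given times
#'
#' @param regime a [nitrogen_regime()] object.
#' @param t numeric vector of times.
#' @return Integer vector of 0/1 nitrate indicators (right-continuous
#'   lookup; times before the first switch take the first value).
#' @export
regime_n <- function(regime, t) {
  stopifnot(inherits(regime, "nitroroot_regime"))
  s <- regime$schedule
  idx <- findInterval(t, s$time)
  idx[idx < 1L] <- 1L
  as.integer(s$N[idx])
}

# Constant-regime helper used throughout: condition name -> regime object.
condition_regime <- function(condition) {
  condition <- match.arg(condition, c("ammonium", "nitrate"))
  nitrogen_regime(data.frame(time = 0, N = as.integer(condition == "nitrate")))
}

#' @rdname model_parameters
#' @param params a `"nitroroot_params"` object.
#' @param condition `"ammonium"` or `"nitrate"`.
#' @return `elongation_threshold()`: the relative-auxin elongation threshold
#'   for the given condition.
#' @export
elongation_threshold <- function(params, condition) {
  condition <- match.arg(condition, c("ammonium", "nitrate"))
  if (condition == "ammonium") params$A_thr_ammonium else params$A_thr_nitrate
}
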