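#' Positional steady state of the auxin/PIN2 transport subsystem
#'
#' Solves for the steady state of auxin, cytoplasmic PIN2 and membrane
#' PIN2 with cells held at fixed positions 1..`n_pos` in both files —
#' the quasi-static per-position pattern that the fluorescence and
#' auxin-reporter measurements sample. Because basal faces carry no PIN2,
#' within-file transport is strictly shootward, so the steady state at
#' positions `1..n_pos` is independent of any cells above and can be
#' computed exactly by a forward recursion: at each position the coupled
#' epidermis/cortex pair is a linear 2x2 system given the membrane pools,
#' and the weak dependence of the pools on auxin (via `q_p` and `tr_a`)
#' is resolved by an outer fixed-point iteration.
#'
#' Used as the model prediction inside the likelihood and the model-based
#' observation generator; cross-checked against time integration of the
#' same equations in the test suite.
#'
#' @param params a [model_parameters()] object (`literal_equations` must
#'   be `FALSE`; the literal non-conservative variant has no bounded
#'   membrane steady state).
#' @param condition `"ammonium"` or `"nitrate"`.
#' @param variant,source_spec auxin-source scenario, see [auxin_source()].
#' @param n_pos number of positions from the QC.
#' @param tol fixed-point tolerance on relative auxin change.
#' @param max_iter iteration cap (error if exceeded).
#' @return A data frame with one row per (file, position): `condition`,
#'   `file`, `i`, `A`, `relative_auxin` (normalized by the maximum auxin
#'   over both files and all positions), `PINc`, `PINm_apical`,
#'   `PINm_basal`, `PINm_outer`.
#' @export
steady_state_profile <- function(params = model_parameters(),
                                 condition = c("ammonium", "nitrate"),
                                 variant = "B", source_spec = NULL,
                                 n_pos = 20, tol = 1e-12, max_iter = 500) {
  condition <- match.arg(condition)
  validate_parameters(params)
  if (params$literal_equations) {
    stop("steady_state_profile requires the mass-conserving equations",
         call. = FALSE)
  }
  N <- as.integer(condition == "nitrate")
  p <- params
  i_vec <- seq_len(n_pos)
  src_e <- auxin_source(i_vec, "epidermis", variant, p, source_spec)
  rate_sel <- N * p$tr_n + (1 - N) * p$tr_wn
  alloc_o <- p$l_n * N
  alloc_a <- 1 - alloc_o

  membrane_pools <- function(A) {
    gate <- logistic(p$tr_a * A + p$tr_i * i_vec)
    dp_eff <- p$d_p * (1 + A / p$q_p)
    tau <- rate_sel * gate
    PINc <- p$m_p / (dp_eff + tau)
    Tflux <- PINc * tau
    list(PINc = PINc, Pa = alloc_a * Tflux / dp_eff,
         Po = alloc_o * Tflux / dp_eff)
  }

  A_e <- rep(0, n_pos); A_c <- rep(0, n_pos)
  for (iter in seq_len(max_iter)) {
    me <- membrane_pools(A_e)
    mc <- membrane_pools(A_c)
    new_e <- numeric(n_pos); new_c <- numeric(n_pos)
    up_e <- 0; up_c <- 0 # shootward influx from the position below
    for (k in i_vec) {
      a11 <- p$d_a + p$k_a * (me$Pa[k] + me$Po[k])
      a22 <- p$d_a + p$k_a * (mc$Pa[k] + mc$Po[k])
      a12 <- -p$k_a * mc$Po[k]
      a21 <- -p$k_a * me$Po[k]
      b1 <- src_e[k] + up_e
      b2 <- up_c
      det <- a11 * a22 - a12 * a21
      new_e[k] <- (b1 * a22 - a12 * b2) / det
      new_c[k] <- (a11 * b2 - a21 * b1) / det
      up_e <- p$k_a * new_e[k] * me$Pa[k]
      up_c <- p$k_a * new_c[k] * mc$Pa[k]
    }
    delta <- max(abs(new_e - A_e), abs(new_c - A_c)) /
      max(max(new_e, new_c), 1e-12)
    A_e <- new_e; A_c <- new_c
    if (delta < tol) break
    if (iter == max_iter) {
      stop("steady-state iteration did not converge", call. = FALSE)
    }
  }
  me <- membrane_pools(A_e)
  mc <- membrane_pools(A_c)
  maxA <- max(A_e, A_c)
  if (maxA <= 0) maxA <- 1
  out <- rbind(
    data.frame(condition = condition, file = "epidermis", i = i_vec,
               A = A_e, relative_auxin = A_e / maxA, PINc = me$PINc,
               PINm_apical = me$Pa, PINm_basal = 0, PINm_outer = me$Po),
    data.frame(condition = condition, file = "cortex", i = i_vec,
               A = A_c, relative_auxin = A_c / maxA, PINc = mc$PINc,
               PINm_apical = mc$Pa, PINm_basal = 0, PINm_outer = mc$Po))
  rownames(out) <- NULL
  out
}
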