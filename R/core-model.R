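#' Standard logistic function
#'
#' Gate used by the PIN2 trafficking rule: trafficking saturates between 0
#' and its maximal rate according to a logistic function of auxin level and
#' cell index, `logistic(tr_a * A + tr_i * i)`.
#'
#' @param x numeric vector.
#' @return `1 / (1 + exp(-x))`, elementwise in `(0, 1)`.
#' @examples
#' logistic(0)          # 0.5
#' logistic(-0.05 * 0 + 0.30 * 10) # 0.952574...
#' @export
logistic <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  stats::plogis(x)
}

#' Construct a cell record
#'
#' A cell is a plain named list holding the per-cell state of the model:
#' position index from the quiescent centre (QC), length, zone, auxin
#' amount, cytoplasmic PIN2, per-face membrane PIN2 and the division
#' factor.
#'
#' @param file `"epidermis"` or `"cortex"`.
#' @param i 1-based cell index counted from the QC.
#' @param length cell length (micrometres).
#' @param zone `"meristem"` or `"elongation"`.
#' @param A auxin amount (arbitrary units, >= 0).
#' @param PINc cytoplasmic PIN2 pool (>= 0).
#' @param PINm named numeric vector with entries `apical`, `basal`,
#'   `outer` (each >= 0).
#' @param DIV division factor (>= 0).
#' @param lineage lineage identifier.
#' @return A list of class `"nitroroot_cell"`.
#' @export
new_cell <- function(file = c("epidermis", "cortex"), i = 1L, length = 10,
                     zone = c("meristem", "elongation"), A = 0, PINc = 0,
                     PINm = c(apical = 0, basal = 0, outer = 0), DIV = 0,
                     lineage = 1L) {
  file <- match.arg(file)
  zone <- match.arg(zone)
  stopifnot(i >= 1, length > 0, A >= 0, PINc >= 0, DIV >= 0,
            all(PINm >= 0), all(c("apical", "basal", "outer") %in% names(PINm)))
  structure(list(file = file, i = as.numeric(i), length = length, zone = zone,
                 A = A, PINc = PINc, PINm = PINm[c("apical", "basal", "outer")],
                 DIV = DIV, lineage = lineage),
            class = "nitroroot_cell")
}

#' Auxin source rate by position and tissue
#'
#' Evaluates the auxin influx into a cell for each of the four source
#' scenarios considered during model selection. Cortical cells receive no
#' influx under any scenario (the model excludes a significant auxin flow
#' into the cortex).
#'
#' @param i cell index (vectorized, 1-based from the QC).
#' @param file `"epidermis"` or `"cortex"`.
#' @param variant one of `"A"` (uniform rate along the epidermis), `"B"`
#'   (QC-proximal rate `s1` below the switch index `z`, lateral-root-cap
#'   rate `s2` at or above it), `"C"` (natural cubic spline over positions,
#'   clamped non-negative), `"D"` (independent per-cell rates).
#' @param params a [model_parameters()] object.
#' @param source_spec variant-specific source description:
#'   `A`: `list(rate = )` (defaults to `params$s1`);
#'   `B`: ignored (uses `s1`, `s2`, `z` from `params`);
#'   `C`: `list(knot_x = , knot_y = )` (default knots at positions
#'   1, 7, 13, 19, 25 with values `s1`);
#'   `D`: `list(rates = )`, one non-negative rate per position (must cover
#'   every requested index).
#' @return Numeric vector of source rates (a.u. per time).
#' @examples
#' p <- model_parameters()
#' auxin_source(5, "epidermis", "B", p)   # 8.36  (i < z)
#' auxin_source(15, "epidermis", "B", p)  # 22.53 (i >= z)
#' auxin_source(15, "cortex", "B", p)     # 0
#' @export
auxin_source <- function(i, file = c("epidermis", "cortex"),
                         variant = c("B", "A", "C", "D"),
                         params = model_parameters(), source_spec = NULL) {
  file <- match.arg(file)
  variant <- match.arg(variant)
  stopifnot(is.numeric(i), all(i >= 1))
  if (file == "cortex") return(rep(0, length(i)))
  switch(variant,
    A = {
      rate <- if (!is.null(source_spec$rate)) source_spec$rate else params$s1
      stopifnot(rate >= 0)
      rep(rate, length(i))
    },
    B = ifelse(i < params$z, params$s1, params$s2),
    C = {
      kx <- if (!is.null(source_spec$knot_x)) source_spec$knot_x else
        c(1, 7, 13, 19, 25)
      ky <- if (!is.null(source_spec$knot_y)) source_spec$knot_y else
        rep(params$s1, length(kx))
      stopifnot(length(kx) == length(ky))
      val <- stats::spline(kx, ky, xout = i, method = "natural")$y
      if (any(val < 0)) {
        warning("spline source negative at some positions; clamped to 0")
        val <- pmax(val, 0)
      }
      val
    },
    D = {
      rates <- source_spec$rates
      if (is.null(rates) || max(i) > length(rates)) {
        stop("variant D source vector must supply a rate for every position",
             call. = FALSE)
      }
      stopifnot(all(rates >= 0))
      rates[i]
    }
  )
}

face_names <- c("apical", "basal", "outer")

#' Auxin balance of one cell
#'
#' Net auxin rate for a cell: positional source plus PIN2-mediated wall
#' fluxes minus first-order turnover. For each shared wall, the flux into
#' the focal cell is `k_a * (A_j * PINm[j, face toward i] - A_i *
#' PINm[i, face toward j])`. A wall entry with `cell = NULL` is an external
#' sink: auxin pumped through that face leaves the system with no return
#' term.
#'
#' @param cell a [new_cell()] record.
#' @param neighbors list of walls, each `list(cell = <cell or NULL>,
#'   face_self = , face_neighbor = )`; every shared wall appears once.
#' @param regime a [nitrogen_regime()] object (unused by the auxin balance
#'   itself; accepted for a uniform rhs signature).
#' @param variant,params,source_spec source scenario, see [auxin_source()].
#' @param t time at which the regime is evaluated.
#' @return dA/dt (a.u. per time).
#' @export
auxin_rhs <- function(cell, neighbors = list(), regime = NULL,
                      variant = "B", params = model_parameters(),
                      source_spec = NULL, t = 0) {
  src <- auxin_source(cell$i, cell$file, variant, params, source_spec)
  flux <- 0
  for (w in neighbors) {
    if (!all(c("face_self") %in% names(w)) ||
        !(w$face_self %in% face_names) ||
        (!is.null(w$cell) && !(w$face_neighbor %in% face_names))) {
      stop("unknown face pairing in neighbor list", call. = FALSE)
    }
    out <- params$k_a * cell$A * cell$PINm[[w$face_self]]
    inn <- if (is.null(w$cell)) 0 else
      params$k_a * w$cell$A * w$cell$PINm[[w$face_neighbor]]
    flux <- flux + inn - out
  }
  unname(src + flux - params$d_a * cell$A)
}

#' PIN2 trafficking flux and per-face allocation
#'
#' Total trafficking flux out of the cytoplasmic pool,
#' `PINc * (N * tr_n + (1 - N) * tr_wn) * logistic(tr_a * A + tr_i * i)`,
#' and its allocation over membrane faces: the lateral (outer) face
#' receives the fraction `l_n * N`, the apical face the remainder, the
#' basal face nothing (PIN2 is apically polarized in both files; nitrate
#' redirects part of the flux laterally).
#'
#' @inheritParams auxin_rhs
#' @param N binary nitrate indicator (0 = ammonium, 1 = nitrate); may also
#'   be given as a [nitrogen_regime()] via `regime` + `t`.
#' @return `list(total = , allocation = , per_face = )`.
#' @examples
#' p <- model_parameters()
#' cl <- new_cell("epidermis", i = 10, A = 0, PINc = 100)
#' pin2_trafficking_rate(cl, N = 1, params = p)$total # 100*0.246*logistic(3)
#' @export
pin2_trafficking_rate <- function(cell, N = NULL, regime = NULL,
                                  params = model_parameters(), t = 0) {
  if (is.null(N)) N <- regime_n(regime, t)
  stopifnot(N %in% c(0, 1))
  rate <- N * params$tr_n + (1 - N) * params$tr_wn
  total <- cell$PINc * rate * logistic(params$tr_a * cell$A + params$tr_i * cell$i)
  alloc <- c(apical = 1 - params$l_n * N, basal = 0, outer = params$l_n * N)
  list(total = unname(total), allocation = alloc, per_face = total * alloc)
}

#' Cytoplasmic PIN2 balance
#'
#' Basal synthesis minus auxin-enhanced degradation,
#' `m_p - d_p * PINc * (1 + A / q_p)`, minus the trafficking outflow to the
#' membranes (delivery debits the cytoplasmic pool so that PIN2 mass is
#' conserved; disabled when `params$literal_equations` is `TRUE`).
#'
#' @inheritParams pin2_trafficking_rate
#' @return dPINc/dt.
#' @export
pin2_cytoplasm_rhs <- function(cell, N = NULL, regime = NULL,
                               params = model_parameters(), t = 0) {
  if (is.null(N)) N <- if (is.null(regime)) 0 else regime_n(regime, t)
  traffic <- if (params$literal_equations) 0 else
    pin2_trafficking_rate(cell, N = N, params = params)$total
  unname(params$m_p - params$d_p * cell$PINc * (1 + cell$A / params$q_p) - traffic)
}

#' Membrane PIN2 balance for one face
#'
#' Delivery from the cytoplasm (the face's allocation share of the
#' trafficking flux) minus auxin-enhanced membrane turnover at the same
#' law as the cytoplasmic pool, `d_p * (1 + A / q_p) * PINm`. Membrane
#' turnover is dropped when `params$literal_equations` is `TRUE`.
#'
#' @inheritParams pin2_trafficking_rate
#' @param face `"apical"`, `"basal"` or `"outer"`.
#' @return dPINm(face)/dt.
#' @export
pin2_membrane_rhs <- function(cell, face = c("apical", "basal", "outer"),
                              N = NULL, regime = NULL,
                              params = model_parameters(), t = 0) {
  face <- match.arg(face)
  if (is.null(N)) N <- if (is.null(regime)) 0 else regime_n(regime, t)
  tr <- pin2_trafficking_rate(cell, N = N, params = params)
  decay <- if (params$literal_equations) 0 else
    params$d_p * (1 + cell$A / params$q_p)
  unname(tr$per_face[[face]] - decay * cell$PINm[[face]])
}

#' Division-factor balance
#'
#' Synthesis `k_v0 * k_v1 * (A/maxA + len/maxL) / (1 + exp(i * t_v))`
#' (auxin- and size-activated, restricted to QC-proximal positions) minus
#' Hill-modulated linear degradation
#' `DIV * k_v2 * (1 + (A/k_v3)^h1) / (1 + (A/k_v4)^h2)`.
#'
#' @inheritParams pin2_trafficking_rate
#' @param maxA normalization for relative auxin (must be > 0).
#' @return dDIV/dt.
#' @export
division_factor_rhs <- function(cell, maxA, params = model_parameters()) {
  if (!is.numeric(maxA) || length(maxA) != 1L || !is.finite(maxA) || maxA <= 0) {
    stop("maxA must be a positive number (relative-auxin normalization undefined)",
         call. = FALSE)
  }
  synth <- params$k_v0 * params$k_v1 *
    (cell$A / maxA + cell$length / params$maxL) /
    (1 + exp(cell$i * params$t_v))
  degr <- cell$DIV * params$k_v2 *
    (1 + (cell$A / params$k_v3)^params$h1) /
    (1 + (cell$A / params$k_v4)^params$h2)
  unname(synth - degr)
}

#' Cell growth rate
#'
#' Auxin-gated logistic growth,
#' `k_l(zone) * A/(A+1) * L * (1 - L / m_l(zone))`; exactly zero when
#' `A = 0` or `L = m_l`. Lengths above the zone maximum clamp the rate to
#' zero with a warning.
#'
#' @inheritParams pin2_trafficking_rate
#' @return dL/dt (micrometres per time), always >= 0.
#' @export
growth_rhs <- function(cell, params = model_parameters()) {
  k_l <- if (cell$zone == "meristem") params$k_l_meristem else params$k_l_elongation
  m_l <- if (cell$zone == "meristem") params$m_l_meristem else params$m_l_elongation
  if (cell$length > m_l) {
    warning("cell length exceeds zone maximum; growth clamped to 0")
    return(0)
  }
  rate <- k_l * (cell$A / (cell$A + 1)) * cell$length * (1 - cell$length / m_l)
  unname(max(rate, 0))
}
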