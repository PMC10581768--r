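#' Lienard oscillator nonlinearity
#'
#' The cubic-type shape function of the planar Lienard system used as the
#' central respiratory pattern generator: `f(x, y) = (a y^2 + b y)(x + y)`.
#'
#' @param x,y Oscillator states, dimensionless.
#' @param a,b Shape parameters, dimensionless.
#' @return f value, dimensionless.
#' @export
lienard_f <- function(x, y, a, b) (a * y^2 + b * y) * (x + y)

#' Central respiratory pattern generator derivatives
#'
#' Two variants share the Lienard core (`dy/dt = alpha x`). The original
#' formulation feeds the alveolar airflow back into the hidden state
#' through the Hering-Breuer reflex term and integrates the muscle
#' pressure without leak:
#' `dx/dt = alpha (f - HB dV_alv/dt)`, `dP_mus/dt = lam_mus y + mu`.
#' The stabilized variant drops the reflex term and adds integral feedback
#' on the muscle pressure, which removes the slow drift of `P_mus`:
#' `dx/dt = alpha f`, `dP_mus/dt = lam_mus y + mu - beta P_mus`.
#' With `beta = 0` and `HB = 0` the two coincide.
#'
#' @param x,y Lienard states, dimensionless.
#' @param P_mus Respiratory muscle pressure, mmHg.
#' @param dV_alv_dt Alveolar airflow, l s^-1 (used by the original variant).
#' @param p A [respiratory_params()].
#' @param variant `"original"` or `"stabilized"`.
#' @return A list with `dx`, `dy`, `dP_mus`.
#' @export
crpg_derivatives <- function(x, y, P_mus, dV_alv_dt, p,
                             variant = c("stabilized", "original")) {
  variant <- match.arg(variant)
  f <- lienard_f(x, y, p$a, p$b)
  if (variant == "original") {
    list(dx = p$alpha * (f - p$HB * dV_alv_dt),
         dy = p$alpha * x,
         dP_mus = p$lam_mus * y + p$mu)
  } else {
    list(dx = p$alpha * f,
         dy = p$alpha * x,
         dP_mus = p$lam_mus * y + p$mu - p$beta * P_mus)
  }
}

#' Pleural pressure from respiratory mechanics
#'
#' `P_pl = P_mus + E_cw (V_th - V_th0)`: the chest wall acts as a linear
#' elastance on the total thoracic volume, offset by the respiratory
#' muscle pressure.
#'
#' @param P_mus Respiratory muscle pressure, mmHg.
#' @param V_th Thoracic volume (intrathoracic blood + alveolar air), l.
#' @param p A [respiratory_params()].
#' @return Pleural pressure, mmHg.
#' @export
pleural_pressure <- function(P_mus, V_th, p) {
  P_mus + p$E_cw * (V_th - p$V_th0)
}

#' Alveolar volume derivative
#'
#' Airflow into the alveolar compartment through the airway resistances,
#' driven by the (negative) sum of pleural and alveolar recoil pressures:
#' `dV_alv/dt = -(P_pl + E_alv V_alv) / (R_ca + R_ua)`.
#'
#' @param P_pl Pleural pressure, mmHg.
#' @param V_alv Alveolar volume, l.
#' @param p A [respiratory_params()].
#' @return dV_alv/dt, l s^-1.
#' @export
alveolar_derivative <- function(P_pl, V_alv, p) {
  -(P_pl + p$E_alv * V_alv) / (p$R_ca + p$R_ua)
}
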