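#' Ramp (positive-part) function
#'
#' Applied to valve flow rates so they are never negative, and in the
#' chamber mass balance to stop the tiny spurious negative flows of the
#' inertial valve law propagating around the loop.
#'
#' @param x Numeric (vectorised).
#' @return `max(x, 0)` elementwise.
#' @export
ramp <- function(x) pmax(x, 0)

#' Vessel pressure
#'
#' Linear elastance about the unstressed volume, with the pleural pressure
#' added for intrathoracic vessels (pulmonary artery and vein).
#'
#' @param V Volume, l.
#' @param p A [vessel_params()].
#' @param P_pl Pleural pressure, mmHg.
#' @return Pressure, mmHg.
#' @export
vessel_pressure <- function(V, p, P_pl = 0) {
  p$E * (V - p$V_d) + if (p$in_thorax) P_pl else 0
}

#' Resistive flow
#'
#' Signed Ohmic flow through a resistance; used for the valveless pulmonary
#' and systemic circulation connections.
#'
#' @param P_up,P_down Upstream/downstream pressures, mmHg.
#' @param R Resistance, mmHg s l^-1.
#' @return Flow, l s^-1.
#' @export
resistive_flow <- function(P_up, P_down, R) (P_up - P_down) / R

#' Non-inertial valve flow
#'
#' A simple check valve: the resistive flow clipped to one direction.
#'
#' @inheritParams resistive_flow
#' @return Flow, l s^-1, never negative.
#' @export
valve_flow_noninertial <- function(P_up, P_down, R) {
  ramp((P_up - P_down) / R)
}

#' Inertial valve flow derivative
#'
#' 'Open on pressure, close on flow': the flow state accelerates under the
#' net pressure gradient less the resistive drop while the valve is open
#' (positive flow, or positive gradient when closed), and its derivative is
#' zero otherwise.
#'
#' @param Q Current valve flow state, l s^-1.
#' @inheritParams resistive_flow
#' @param L Inductance, mmHg s^2 l^-1.
#' @return dQ/dt, l s^-2.
#' @export
valve_flow_derivative_inertial <- function(Q, P_up, P_down, R, L) {
  ifelse(Q > 0 | P_up > P_down, (P_up - P_down - Q * R) / L, 0)
}

#' Chamber volume derivative
#'
#' Incompressible mass balance with ramp clipping of the (possibly slightly
#' negative) inertial valve flows.
#'
#' @param Q_in,Q_out Inflow/outflow, l s^-1.
#' @return dV/dt, l s^-1.
#' @export
chamber_volume_derivative <- function(Q_in, Q_out) ramp(Q_in) - ramp(Q_out)

# Loop topology (flow v: upstream -> downstream):
#   pv: rv -> pa, pul: pa -> pu, mt: pu -> lv, av: lv -> ao,
#   sys: ao -> vc, tc: vc -> rv.
# The closed-loop right-hand side lives in .make_rhs() (engine): valved
# connections (mt, av, tc, pv) are clipped in the mass balance; the purely
# resistive pul and sys connections stay signed (backflow there is
# physical). Each connection flow enters once as inflow and once as
# outflow, so the six volume derivatives sum to zero identically and the
# total blood volume is a linear invariant of the integration.
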