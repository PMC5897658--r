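# Shared fixtures: standard rate sets and protocols used across tests.
# Gating rates in the desensitization fixtures are ~1000x faster than
# desensitization with a small open fraction, the regime in which the
# peak/steady-state analysis maps cleanly onto the two-state reduction.

wt_rates <- function(k_o = 27.8, k_u = 0) {
  rate_set(k_d = 0.17, k_r = 0.69, k_o = k_o, k_c = 200, k_b = 25, k_u = k_u)
}

v558i_rates <- function(k_o = 1.33) {
  rate_set(k_d = 4.06, k_r = 1.12, k_o = k_o, k_c = 200, k_b = 25, k_u = 0)
}

fast_gating_rates <- function(k_d, k_r) {
  rate_set(k_d = k_d, k_r = k_r, k_o = 25, k_c = 5000, k_b = 25, k_u = 0)
}

glut_protocol <- function(dur = 10, exchange_tau = 0) {
  application_protocol(
    protocol_epoch(0, dur, glutamate = 1000, glycine = 30),
    exchange_tau = exchange_tau)
}

mk_protocol <- function(glut_dur = 10, mk_dur = 30, mk = 1, exchange_tau = 0) {
  application_protocol(rbind(
    protocol_epoch(0, glut_dur, glutamate = 1000, glycine = 30),
    protocol_epoch(glut_dur, glut_dur + mk_dur, glutamate = 1000,
                   glycine = 30, mk801 = mk)),
    exchange_tau = exchange_tau)
}

# opening rate that yields a given open probability (percent) at fixed k_c
ko_for_po <- function(po_percent, k_c = 200) {
  p <- po_percent / 100
  p * k_c / (1 - p)
}

# constant-coefficient simulation: glutamate + 1 uM MK-801 from t = 0 with
# instantaneous exchange, matching a single matrix-exponential propagation
sim_const_mk <- function(rates, t_grid, mk = 1) {
  prot <- application_protocol(
    protocol_epoch(0, max(t_grid) + 1, glutamate = 1000, mk801 = mk),
    exchange_tau = 0)
  simulate_occupancies(rates, prot, t_grid)
}
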