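# Independent second transcription of the Garcia & Gordon (1992)
# Benson-Krause combined-fit coefficients, evaluated as explicit powers
# (the package uses Horner form), in umol/kg.
gg92_oracle_umol_kg <- function(T_c, S) {
  ts <- log((298.15 - T_c) / (273.15 + T_c))
  lnC <- 5.80871 + 3.20291 * ts + 4.17887 * ts^2 + 5.10006 * ts^3 -
    9.86643e-2 * ts^4 + 3.80369 * ts^5 +
    S * (-7.01577e-3 - 7.70028e-3 * ts - 1.13864e-2 * ts^2 -
           9.51519e-3 * ts^3) -
    2.75915e-7 * S^2
  exp(lnC)
}

# centered finite-difference gradient of phi at one state
phi_fd_partials <- function(T_c, S, O2, traits) {
  fd <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)
  list(
    dO2 = fd(function(o) phi_eval(T_c, S, o, traits), O2, 1e-3 * max(1, O2)),
    dT = fd(function(t) phi_eval(t, S, O2, traits), T_c, 1e-4),
    dS = fd(function(s) phi_eval(T_c, s, O2, traits), S, 1e-4))
}
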