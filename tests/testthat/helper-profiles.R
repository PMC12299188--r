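# Shared fixtures: analytic profiles with known parameters.

# output grid for IV bolus PBPK runs: dense over the venous mixing
# transient, coarse afterwards
iv_times <- function(t_end = 96) {
  c(seq(0, 0.2, by = 5e-4), seq(0.25, t_end, by = 0.05))
}

# mono-exponential IV profile C(t) = c0 * exp(-k t), times in hours
make_exp_profile <- function(c0 = 100, k = 0.5, times = c(0.5, 1, 2, 4, 8),
                             dose_mg = 1, bw_kg = 1, route = "iv_bolus",
                             id = "exp") {
  plasma_profile(times, c0 * exp(-k * times), dose_mg = dose_mg,
                 bw_kg = bw_kg, route = route, subject_id = id)
}

# independent evaluation of the weak-base (pKa < 7) tissue:plasma partition
# equation, written out directly from the composition table
oracle_kp <- function(tissue, logp, pka, fu, ph_p = 7.4, ph_iw = 7.0) {
  comp <- tissue_composition()
  r <- comp[comp$tissue == tissue, ]
  pl <- comp[comp$tissue == "plasma", ]
  p <- 10^logp
  x <- if (is.na(pka)) 1 else 1 + 10^(pka - ph_p)
  y <- if (is.na(pka)) 1 else 1 + 10^(pka - ph_iw)
  lip <- function(fnl, fnp) (p * fnl + (0.3 * p + 0.7) * fnp) / x
  resid <- max(0, 1 / fu - 1 - lip(pl$f_nl, pl$f_np))
  fu * (r$f_ew + (y / x) * r$f_iw + lip(r$f_nl, r$f_np) + r$alb_ratio * resid)
}
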