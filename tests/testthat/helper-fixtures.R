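# Shared fixtures: characterised defaults and small analytic oracles.

default_material <- function(...) material_model(...)
default_law <- function(...) stress_law(...)

# closed-form depolarization factor of a prolate spheroid (a > b = c),
# independent oracle for the quadrature
prolate_A_a <- function(a, b) {
  e <- sqrt(1 - (b / a)^2)
  (1 - e^2) / e^3 * (atanh(e) - e)
}

# homogeneous-ellipsoid Clausius-Mossotti factor (single material, no shell)
homogeneous_cm <- function(eps_p, eps_m, A1) {
  (eps_p - eps_m) / (3 * (eps_m + A1 * (eps_p - eps_m)))
}

# independent bisection for the equilibrium extension ratio on the
# small-deformation branch: lambda^2 - lambda^-2 = 2 sigma / mu
bisect_equilibrium <- function(sigma, mu, lo = 1, hi = 3, iters = 200) {
  f <- function(lam) lam^2 - lam^-2 - 2 * sigma / mu
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# invert the recovery relation to synthesise an exact SR(t) decay trace
sr_trace_from_tc <- function(t, t_c, sr0, sr_inf) {
  E <- exp(-t / t_c)
  sr_inf * ((sr0 + sr_inf) + E * (sr0 - sr_inf)) /
    ((sr0 + sr_inf) - E * (sr0 - sr_inf))
}

# synthetic step-profile track set at the given voltages (recycled)
make_track_set <- function(n, voltages = c(0.5, 1, 2), axis_sd = 0,
                           seed = 42, material = default_material(),
                           law = default_law(), on = 1, off = 1) {
  v <- rep_len(voltages, n)
  tracks <- vector("list", n)
  profiles <- vector("list", n)
  for (k in seq_len(n)) {
    profiles[[k]] <- make_step_profile(v[k], on, off)
    tracks[[k]] <- generate_track(
      material, profiles[[k]], law,
      noise = noise_spec(axis_sd = axis_sd, seed = seed + k))
  }
  list(tracks = tracks, profiles = profiles, voltages = v)
}
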