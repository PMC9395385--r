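# Independent oracles, deliberately re-derived rather than calling the
# package's own internals.

# Antoine vapour pressure (mmHg, degC convention), re-stated here.
oracle_antoine <- function(abc, t) 10^(abc[1] - abc[2] / (abc[3] + t))

# van Laar activity coefficients for a binary, component 1 first.
oracle_van_laar <- function(x1, a12, a21) {
  x2 <- 1 - x1
  d <- a12 * x1 + a21 * x2
  c(exp(a12 * (a21 * x2 / d)^2), exp(a21 * (a12 * x1 / d)^2))
}

# Brute-force Le Chatelier flash point: scan a 0.01 degC grid for the
# crossing of sum x_i gamma_i P_i(T)/P_i(T_fp,i) through 1 and return the
# linear interpolation between the bracketing grid points.
oracle_flash_point <- function(x, comps, gamma, lo = -50, hi = 150,
                               step = 0.01) {
  grid <- seq(lo, hi, by = step)
  lhs <- rep(0, length(grid))
  for (i in seq_along(comps)) {
    c_ <- comps[[i]]
    if (!isTRUE(c_$flammable)) next
    lhs <- lhs + x[i] * gamma[i] * oracle_antoine(c_$antoine, grid) /
      oracle_antoine(c_$antoine, c_$flash_point)
  }
  k <- which(lhs[-1] >= 1 & lhs[-length(lhs)] < 1)[1]
  stopifnot(!is.na(k))
  # linear interpolation inside the bracketing 0.01-degree cell
  grid[k] + step * (1 - lhs[k]) / (lhs[k + 1] - lhs[k])
}

# The case-study design/response rows, typed independently of the CSV.
oracle_gp <- function() {
  data.frame(
    P = c(24, 24, 21, 18, 24, 21, 25, 21, 21, 18, 21, 24, 18, 18, 21, 17,
          21, 21, 21, 21),
    T = c(60, 70, 58, 70, 60, 72, 65, 65, 65, 60, 65, 70, 70, 60, 65, 65,
          65, 65, 65, 65),
    W = c(30, 30, 20, 30, 10, 20, 20, 33, 20, 30, 20, 10, 10, 10, 7, 20,
          20, 20, 20, 20),
    yield = c(12.9, 15.9, 4.05, 6.26, 3.73, 7.87, 12.74, 11.8, 4.9, 2.23,
              5.61, 4.5, 2.47, 2.35, 3.18, 2.9, 5.8, 6.88, 6.9, 7.5),
    sol = c(2.4, 2.35, 0.2, 0.1, 0.3, 0.2, 1.0, 0.89, 0.4, 0.5, 0.3, 0.9,
            0.3, 0.1, 0.8, 0.5, 0.4, 0.5, 0.6, 0.3)
  )
}

# A small synthetic factor set distinct from the case study.
toy_factors <- function() {
  list(
    factor_spec("x1", "u", center = 0, step = 1, axial_low = -1.5,
                axial_high = 1.5),
    factor_spec("x2", "u", center = 10, step = 2, axial_low = 7,
                axial_high = 13),
    factor_spec("x3", "u", center = 100, step = 50, axial_low = 25,
                axial_high = 175)
  )
}

toy_design <- function(n_center = 3L)
  suppressWarnings(ccd_design(toy_factors(), n_center))
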