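# Independent oracles and small fixtures shared across the test files.

# Brute-force percent stretch: finite-difference arc length of the cap
# profile z(r) = sqrt(R^2 - r^2) - (R - h) across the full chord, divided
# by the chord. Independent of the closed form used by the package.
oracle_stretch <- function(a, h, n = 200001) {
  if (h == 0) return(0)
  R <- (a^2 + h^2) / (2 * h)
  r <- seq(-a, a, length.out = n)
  z <- sqrt(pmax(R^2 - r^2, 0)) - (R - h)
  arc <- sum(sqrt(diff(r)^2 + diff(z)^2))
  100 * (arc / (2 * a) - 1)
}

# Bisection inverse of the oracle (used to freeze derived apex heights).
oracle_height_for_stretch <- function(target, a) {
  stats::uniroot(function(h) oracle_stretch(a, h) - target,
                 lower = 1e-9, upper = a, tol = 1e-10)$root
}

# Least-squares circle fit through profile points (x, z): returns radius.
# Used as an independent check of the cap sphere radius.
oracle_circle_radius <- function(x, z) {
  A <- cbind(2 * x, 2 * z, 1)
  b <- x^2 + z^2
  sol <- qr.solve(A, b)
  sqrt(sol[3] + sol[1]^2 + sol[2]^2)
}

# Evaluate expr under a fixed seed (tests only).
with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

# A clean sampled sinusoid as a motion trace.
sine_trace <- function(freq_hz, fps, duration_s, amplitude = 1, phase = 0) {
  t <- seq(0, duration_s - 1 / fps, by = 1 / fps)
  motion_trace(amplitude * sin(2 * pi * freq_hz * t + phase), fps = fps)
}

# Small fast scene for imaging tests.
test_scene <- function(n = 96L, noise_sd = 0, ...) {
  scene_params(image_size_px = c(n, n), noise_sd = noise_sd, ...)
}
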