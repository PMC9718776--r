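## Shared fixtures for the test suite. Everything is generated in code;
## heavier objects are built once per test run.

default_truth <- ground_truth()

## Closed-form post-pulse cascade from arbitrary populations at time t0:
## each occupied state evolves down the remaining chain independently, so
## the solution is a superposition of Bateman chains (the independent
## oracle for the post-pulse Bloch dynamics).
post_pulse_cascade <- function(rho0, scheme, dt) {
  g <- c(scheme$gamma22, scheme$gamma33, scheme$gamma44)
  from2 <- bateman_cascade(rho0[2L], g, dt)
  from3 <- bateman_cascade(rho0[3L], c(g[2L], g[3L], 0), dt)
  from4 <- bateman_cascade(rho0[4L], c(g[3L], 0, 0), dt)
  cbind(
    rho22 = from2[, 1L],
    rho33 = from2[, 2L] + from3[, 1L],
    rho44 = from2[, 3L] + from3[, 2L] + from4[, 1L],
    rho55 = from2[, 4L] + from3[, 3L] + from4[, 2L] + rho0[5L])
}

## Exact Gaussian convolution of the piecewise-linear unit step with a
## single ramp from (a, 0) to (0, 1): the analytic smoothed-step oracle.
ramp_step_conv <- function(t, a, sigma) {
  dPhi <- pnorm(-t / sigma) - pnorm((a - t) / sigma)
  phi_s <- function(z) dnorm(z / sigma) / sigma
  pnorm(t / sigma) +
    (1 / (-a)) * ((t - a) * dPhi - sigma^2 * (phi_s(t) - phi_s(t - a)))
}

## Small uniform-grid trace wrapper for convolution tests.
make_trace <- function(t, y) list(t = t, rho = cbind(rho22 = y))
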