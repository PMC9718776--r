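#' Closed-form populations of the sequential decay cascade
#'
#' Analytic Bateman-chain solution for the incoherent cascade
#' 2 -> 3 -> 4 -> 5 with an initial population `initial_excited` placed in
#' state 2 at `t = 0` and rates \eqn{\Gamma_{22}, \Gamma_{33}, \Gamma_{44}}
#' (state 5 is terminal). Serves as the independent oracle for the
#' post-pulse dynamics of [integrate_bloch()]. Pairwise-equal (and fully
#' degenerate) rates are handled by the analytic limiting forms with
#' \eqn{t e^{-\Gamma t}} (and \eqn{t^2 e^{-\Gamma t}}) terms; rates closer
#' than a relative 1e-8 are treated as equal.
#'
#' @param initial_excited Population placed in state 2 at `t = 0`.
#' @param scheme A [level_scheme()], or a numeric vector
#'   `c(gamma22, gamma33, gamma44)` of non-negative rates in 1/ps (zero
#'   rates are allowed and mean a non-decaying state).
#' @param t Times in ps, all `>= 0`.
#' @return Matrix with columns `rho22`, `rho33`, `rho44`, `rho55`; rows sum
#'   to `initial_excited` at every time.
#' @examples
#' bateman_cascade(1, level_scheme(), t = c(0, 1, 10, 100))
#' bateman_cascade(1, c(2, 2, 0.5), t = 0:3)  # degenerate pair
#' @export
bateman_cascade <- function(initial_excited, scheme, t) {
  if (inherits(scheme, "level_scheme")) {
    g <- c(scheme$gamma22, scheme$gamma33, scheme$gamma44)
  } else {
    g <- as.numeric(scheme)
    if (length(g) != 3L || any(!is.finite(g)) || any(g < 0))
      stop("rates must be three finite non-negative numbers (1/ps)")
  }
  if (any(t < 0)) stop("'t' must be non-negative (cascade starts at t = 0)")
  N <- initial_excited
  g2 <- g[1L]; g3 <- g[2L]; g4 <- g[3L]

  eq <- function(a, b) abs(a - b) <= 1e-8 * max(a, b, 1e-300)
  e2 <- exp(-g2 * t); e3 <- exp(-g3 * t); e4 <- exp(-g4 * t)

  rho22 <- N * e2

  rho33 <- if (eq(g2, g3)) N * g2 * t * e2
           else N * g2 * (e2 - e3) / (g3 - g2)

  rho44 <-
    if (eq(g2, g3) && eq(g3, g4)) {
      N * g2^2 * t^2 / 2 * e2
    } else if (eq(g2, g3)) {              # g2 == g3 != g4
      d <- g4 - g2
      N * g2^2 * ((e4 - e2) / d^2 + t * e2 / d)
    } else if (eq(g3, g4)) {              # g3 == g4 != g2
      d <- g3 - g2
      N * g2 * g3 * ((e2 - e3) / d^2 - t * e3 / d)
    } else if (eq(g2, g4)) {              # g2 == g4 != g3
      d <- g3 - g2
      N * g2 * g3 * (t * e2 / d + (e3 - e2) / d^2)
    } else {
      N * g2 * g3 * (e2 / ((g3 - g2) * (g4 - g2)) +
                     e3 / ((g2 - g3) * (g4 - g3)) +
                     e4 / ((g2 - g4) * (g3 - g4)))
    }

  rho55 <- N - rho22 - rho33 - rho44      # mass balance, exact
  cbind(rho22 = rho22, rho33 = rho33, rho44 = rho44, rho55 = rho55)
}
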