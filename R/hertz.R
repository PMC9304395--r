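#' Hertz spherical-indentation force
#'
#' Force exerted by a rigid sphere of radius `R` indenting an isotropic
#' elastic half-space to depth `delta`:
#' \deqn{F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}.}
#'
#' @param delta Indentation depth(s), m (values below 0 give force 0).
#' @param E Young's modulus, Pa.
#' @param R Indenter radius, m.
#' @param nu Poisson ratio.
#' @return Force in N, same length as `delta`.
#' @examples
#' hertz_force(2e-6, E = 1000, R = 5.1e-6)  # ~1.14e-8 N
#' @export
hertz_force <- function(delta, E, R, nu = 0.5) {
  stopifnot(E >= 0, R > 0, nu >= 0, nu < 0.5 + 1e-8)
  d <- pmax(delta, 0)
  (4 / 3) * E / (1 - nu^2) * sqrt(R) * d^1.5
}

# Prefactor a such that F = a * delta^(3/2)
hertz_prefactor <- function(E, R, nu) (4 / 3) * E / (1 - nu^2) * sqrt(R)

#' Indentation depth at a given Hertz force
#'
#' Inverts the Hertz sphere model for the depth producing force `F`.
#'
#' @param F Force, N.
#' @param E Young's modulus, Pa.
#' @param R Indenter radius, m.
#' @param nu Poisson ratio.
#' @return Depth in m.
#' @export
hertz_depth <- function(F, E, R, nu = 0.5) {
  stopifnot(all(F >= 0), E > 0)
  (F / hertz_prefactor(E, R, nu))^(2 / 3)
}

# Solve the coupled piezo/indentation kinematics: for piezo travel s = z - z0
# past contact, the depth delta satisfies s = delta + F(delta)/k (the
# cantilever deflects by F/k). Monotone in delta; solved by vectorized Newton.
solve_indentation <- function(travel, E, R, nu, k) {
  a <- hertz_prefactor(E, R, nu)
  s <- pmax(travel, 0)
  delta <- s  # stiff-sample-free start; converges from above
  for (i in 1:60) {
    g  <- delta + a * delta^1.5 / k - s
    gp <- 1 + 1.5 * a * sqrt(delta) / k
    step <- g / gp
    delta <- pmax(delta - step, 0)
    if (max(abs(step)) < 1e-15) break
  }
  delta
}
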