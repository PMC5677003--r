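# Circular helpers shared across modules. Public angle unit is degrees of
# polar angle; densities and concentrations are radian-scale.

#' Wrap angular differences to (-180, 180]
#'
#' @param x Numeric vector of angles or angular differences, in degrees.
#' @return Numeric vector wrapped to the half-open interval (-180, 180].
#' @examples
#' wrap_deg(c(190, -181, 360, 179))
#' @export
wrap_deg <- function(x) {
  180 - ((180 - x) %% 360)
}

# wrap radians to (-pi, pi]
wrap_rad <- function(x) {
  pi - ((pi - x) %% (2 * pi))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# von Mises density at x radians, mean 0, concentration kappa (>= 0).
# exponentially-scaled Bessel keeps this stable for large kappa.
dvm_rad <- function(x, kappa) {
  exp(kappa * (cos(x) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

log_dvm_rad <- function(x, kappa) {
  kappa * (cos(x) - 1) - log(2 * pi) - log(besselI(kappa, 0, expon.scaled = TRUE))
}

# mean resultant length of VM(0, kappa): A1(kappa) = I1(kappa)/I0(kappa)
vm_A1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Fisher's approximation to A1^{-1}, used only for initialization.
vm_A1_inv <- function(R) {
  R <- pmin(pmax(R, 1e-8), 1 - 1e-8)
  ifelse(R < 0.53,
    2 * R + R^3 + 5 * R^5 / 6,
    ifelse(R < 0.85,
      -0.4 + 1.39 * R + 0.43 / (1 - R),
      1 / (R^3 - 4 * R^2 + 3 * R)
    )
  )
}

# von Mises sampler (Best & Fisher 1979 wrapped-Cauchy rejection).
# Returns radians in (-pi, pi]. kappa ~ 0 falls back to uniform.
rvm_rad <- function(n, kappa) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0L) {
      out[(got + 1L):(got + k)] <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      got <- got + k
    }
  }
  out
}

# von Mises quantile function on a fixed grid, vectorized over u. Used to
# transform common random numbers into VM(0, kappa) step directions so that
# Monte-Carlo likelihoods vary smoothly with kappa.
vm_quantile_rad <- function(u, kappa, n_grid = 2048L) {
  if (kappa < 1e-8) return((u - 0.5) * 2 * pi)
  th <- seq(-pi, pi, length.out = n_grid + 1L)
  dens <- dvm_rad(th, kappa)
  # trapezoid CDF, normalized to end exactly at 1
  h <- diff(th)
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * h))
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(cdf, th, xout = u, ties = "ordered")$y
}
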