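# SANDI forward model: closed-form compartment signals and the
# three-compartment spherical-mean signal.

the_root_cache <- new.env(parent = emptyenv())

j1_spherical_deriv <- function(x) {
  # d/dx [ sin(x)/x^2 - cos(x)/x ] = (x^2 - 2) sin(x)/x^3 + 2 cos(x)/x^2
  (x^2 - 2) * sin(x) / x^3 + 2 * cos(x) / x^2
}

#' Roots of the derivative of the first-order spherical Bessel function
#'
#' Returns the first `n_roots` strictly positive roots mu_m of
#' d/dx j1(x) = 0 (x = 0 excluded). These are the radial eigenvalues of
#' diffusion in an impermeable (reflecting) sphere; the m-th eigenmode of a
#' sphere of radius r has decay rate alpha_m^2 D with alpha_m = mu_m / r.
#' Results are cached.
#'
#' @param n_roots number of roots (>= 1).
#' @param tol root-finder tolerance.
#' @return Strictly increasing numeric vector of length `n_roots`.
#' @export
bessel_alpha_roots <- function(n_roots = 30, tol = 1e-12) {
  if (n_roots < 1) stop("n_roots must be >= 1")
  key <- "roots"
  have <- if (exists(key, envir = the_root_cache)) {
    get(key, envir = the_root_cache)
  } else numeric(0)
  if (length(have) < n_roots) {
    have <- vapply(seq_len(n_roots), function(m) {
      lo <- max(0.5, (m - 0.5) * pi - 1.6)
      hi <- (m + 0.6) * pi
      xs <- seq(lo, hi, length.out = 600)
      fs <- j1_spherical_deriv(xs)
      i <- which(diff(sign(fs)) != 0)[1]
      if (is.na(i)) stop("root finder failed to bracket a root")
      stats::uniroot(j1_spherical_deriv, c(xs[i], xs[i + 1]), tol = tol)$root
    }, numeric(1))
    assign(key, have, envir = the_root_cache)
  }
  have[seq_len(n_roots)]
}

#' Series configuration for the restricted-sphere signal
#'
#' @param n_roots number of series terms (>= 10).
#' @param root_tolerance root-finder tolerance.
#' @param convergence_tolerance the series is declared non-convergent when
#'   the last retained term exceeds this fraction of the series sum.
#' @return A list of class `gpd_config`.
#' @export
gpd_config <- function(n_roots = 30, root_tolerance = 1e-12,
                       convergence_tolerance = 1e-6) {
  if (n_roots < 10) stop("n_roots must be >= 10")
  structure(list(n_roots = n_roots, root_tolerance = root_tolerance,
                 convergence_tolerance = convergence_tolerance),
            class = "gpd_config")
}

#' Restricted-diffusion sphere signal (Gaussian phase distribution)
#'
#' Direction-averaged PGSE signal of spins confined to an impermeable
#' sphere, in the Gaussian-phase-distribution (Murday-Cotts) approximation:
#' \deqn{-\ln \tilde A = 2\gamma^2 g^2 \sum_m
#'   \frac{1}{\alpha_m^2(\alpha_m^2 r_s^2 - 2)}\left[
#'   \frac{2\delta}{\alpha_m^2 D} -
#'   \frac{2 + e^{-\alpha_m^2 D(\Delta-\delta)} - 2e^{-\alpha_m^2 D\delta}
#'        - 2e^{-\alpha_m^2 D\Delta} + e^{-\alpha_m^2 D(\Delta+\delta)}}
#'        {(\alpha_m^2 D)^2}\right]}
#' with \eqn{\alpha_m = \mu_m / r_s} and \eqn{\mu_m} the roots from
#' [bessel_alpha_roots()]. \eqn{(\gamma g)^2} is derived from b through the
#' rectangular-pulse PGSE relation, so the function takes b directly.
#'
#' The GPD form assumes the accumulated phase is Gaussian; at strong
#' restriction combined with strong weighting (large \eqn{r_s}, large b)
#' it overestimates the true signal — see [mc_sphere_signal()] for the
#' exact Monte-Carlo reference.
#'
#' @param r_s sphere (soma) radius, um.
#' @param D_is intrinsic diffusivity inside the sphere, um^2/ms.
#' @param b b-value(s), ms/um^2 (vectorised).
#' @param delta,Delta PGSE timings, ms.
#' @param config a [gpd_config()].
#' @return Attenuation(s) in (0, 1], same length as `b`.
#' @export
sphere_gpd_signal <- function(r_s, D_is = 3, b, delta = 8, Delta = 19,
                              config = gpd_config()) {
  if (!(r_s > 0)) stop("r_s must be > 0")
  if (!(D_is > 0)) stop("D_is must be > 0")
  if (any(b < 0)) stop("b must be >= 0")
  mu <- bessel_alpha_roots(config$n_roots, config$root_tolerance)
  a2D <- (mu / r_s)^2 * D_is              # 1/ms
  term <- 1 / ((mu / r_s)^2 * (mu^2 - 2)) *
    (2 * delta / a2D -
       (2 + exp(-a2D * (Delta - delta)) - 2 * exp(-a2D * delta) -
          2 * exp(-a2D * Delta) + exp(-a2D * (Delta + delta))) / a2D^2)
  s <- sum(term)
  if (s > 0 && abs(term[length(term)]) > config$convergence_tolerance * s) {
    stop("GPD series did not converge: increase n_roots")
  }
  gg2 <- b / (delta^2 * (Delta - delta / 3))  # (gamma g)^2 in 1/(um^2 ms^2)
  exp(-2 * gg2 * s)
}

#' Spherical mean of the stick (neurite) signal
#'
#' Powder average of \eqn{\exp(-b D_{in} \cos^2\theta)} over uniformly
#' distributed stick orientations:
#' \eqn{\sqrt{\pi/(4 b D_{in})}\,\mathrm{erf}(\sqrt{b D_{in}})},
#' with a Taylor series below `b * D_in = 1e-6` to avoid 0/0.
#'
#' @param b b-value(s), ms/um^2.
#' @param D_in parallel diffusivity inside the stick, um^2/ms.
#' @return Attenuation(s) in (0, 1].
#' @export
stick_spherical_mean <- function(b, D_in) {
  if (any(b < 0)) stop("b must be >= 0")
  if (!(D_in > 0)) stop("D_in must be > 0")
  x <- b * D_in
  out <- numeric(length(x))
  small <- x < 1e-6
  out[small] <- 1 - x[small] / 3 + x[small]^2 / 10 - x[small]^3 / 42
  xl <- x[!small]
  erf <- function(z) 2 * stats::pnorm(sqrt(2) * z) - 1
  out[!small] <- sqrt(pi / (4 * xl)) * erf(sqrt(xl))
  out
}

#' Directional stick signal
#'
#' \eqn{\exp(-b D_{in} (\mathbf{n} \cdot \mathbf{u})^2)} for gradient
#' direction n and stick orientation u (both unit vectors).
#'
#' @param b b-value (ms/um^2).
#' @param D_in parallel diffusivity (um^2/ms).
#' @param direction gradient direction, unit 3-vector or n x 3 matrix.
#' @param orientation stick orientation, unit 3-vector.
#' @return Signal value(s).
#' @export
stick_directional_signal <- function(b, D_in, direction, orientation) {
  if (is.null(dim(direction))) direction <- matrix(direction, ncol = 3)
  chk <- function(v) all(abs(sqrt(rowSums(v^2)) - 1) <= 1e-6)
  if (!chk(direction) || !chk(matrix(orientation, ncol = 3))) {
    stop("direction and orientation must be unit vectors")
  }
  ct <- as.vector(direction %*% orientation)
  exp(-b * D_in * ct^2)
}

#' Isotropic Gaussian (ball) signal
#'
#' @param b b-value(s), ms/um^2.
#' @param D_ec apparent extracellular diffusivity, um^2/ms.
#' @return \eqn{\exp(-b D_{ec})}.
#' @export
ball_signal <- function(b, D_ec) {
  if (any(b < 0)) stop("b must be >= 0")
  if (!(D_ec > 0)) stop("D_ec must be > 0")
  exp(-b * D_ec)
}

#' SANDI tissue parameters
#'
#' Assembles (vectors of) the five free SANDI parameters plus the fixed
#' intra-soma diffusivity into a validated tibble. The three T2-weighted
#' signal fractions must lie in [0, 1] and sum to 1 within 1e-9.
#'
#' @param f_in,f_is intra-neurite and intra-soma signal fractions.
#' @param f_ec extracellular fraction; defaults to `1 - f_in - f_is`.
#' @param r_s apparent soma radius, um (> 0).
#' @param D_in intra-neurite parallel diffusivity, um^2/ms (> 0).
#' @param D_ec extracellular apparent diffusivity, um^2/ms (> 0).
#' @param D_is intra-soma intrinsic diffusivity, um^2/ms (fixed at 3 in the
#'   standard model).
#' @return A tibble of class `sandi_params` with one row per parameter set.
#' @export
sandi_params <- function(f_in, f_is, f_ec = 1 - f_in - f_is, r_s, D_in, D_ec,
                         D_is = 3) {
  p <- tibble::tibble(f_in = f_in, f_is = f_is, f_ec = f_ec,
                      r_s = r_s, D_in = D_in, D_ec = D_ec, D_is = D_is)
  fr <- as.matrix(p[, c("f_in", "f_is", "f_ec")])
  if (any(fr < -1e-9) || any(fr > 1 + 1e-9)) {
    stop("fraction simplex violated: each signal fraction must lie in [0, 1]")
  }
  if (any(abs(rowSums(fr) - 1) > 1e-9)) {
    stop("fraction simplex violated: f_in + f_is + f_ec must equal 1")
  }
  if (any(p$r_s <= 0) || any(p$D_in <= 0) || any(p$D_ec <= 0) ||
      any(p$D_is <= 0)) {
    stop("r_s and all diffusivities must be > 0")
  }
  class(p) <- c("sandi_params", class(p))
  p
}

#' SANDI spherical-mean forward signal
#'
#' The direction-averaged, b0-normalised three-compartment signal
#' \deqn{\tilde S(b)/S_0 = f_{in}\tilde A_{in}(b D_{in}) +
#'   f_{is}\tilde A_{is}(b; D_{is}, r_s) + f_{ec} e^{-b D_{ec}}}
#' evaluated at each nonzero shell.
#'
#' @param params a [sandi_params()] tibble (n rows).
#' @param b nonzero shell b-values (ms/um^2); alternatively pass `shells`.
#' @param shells optional `shell_table`; its nonzero shell centres are used.
#' @param delta,Delta PGSE timings, ms.
#' @param config a [gpd_config()].
#' @return A `spherical_mean` object with an n x length(b) value matrix.
#' @export
sandi_signal <- function(params, b = NULL, shells = NULL,
                         delta = 8, Delta = 19, config = gpd_config()) {
  if (!inherits(params, "sandi_params")) {
    params <- do.call(sandi_params, as.list(params))
  }
  if (is.null(b)) {
    if (is.null(shells)) stop("provide either b or shells")
    b <- shell_bvalues(shells)
  }
  n <- nrow(params)
  # sphere attenuation depends on (r_s, D_is) per row
  A_is <- t(vapply(seq_len(n), function(i)
    sphere_gpd_signal(params$r_s[i], params$D_is[i], b, delta, Delta, config),
    numeric(length(b))))
  A_in <- t(vapply(seq_len(n), function(i)
    stick_spherical_mean(b, params$D_in[i]), numeric(length(b))))
  A_ec <- exp(-outer(params$D_ec, b))
  vals <- params$f_in * A_in + params$f_is * A_is + params$f_ec * A_ec
  spherical_mean(vals, b)
}
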