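# Rician noise synthesis, replicate-based noise-level estimation, and the
# noise-propagation (parameter-recovery) experiment.

#' Noise specification
#'
#' @param snr signal-to-noise ratio of the b = 0 signal (> 0).
#' @param seed optional integer seed.
#' @return List of class `noise_spec` with `snr`, `sigma = 1/snr`, `seed`.
#' @export
noise_spec <- function(snr = 50, seed = NULL) {
  if (!(snr > 0)) stop("snr must be > 0")
  structure(list(snr = snr, sigma = 1 / snr, seed = seed),
            class = "noise_spec")
}

#' Add Rician noise to normalised signals
#'
#' Magnitude-MRI noise model: \eqn{S_n = \sqrt{(S + N_r)^2 + N_i^2}} with
#' independent \eqn{N_r, N_i \sim N(0, \sigma^2)}. Signals are assumed
#' normalised to a b = 0 level of 1, so `sigma = 1/SNR`.
#'
#' @param signal numeric vector or matrix of non-negative signals.
#' @param sigma normalised noise level; a scalar, or (for matrix input) a
#'   vector with one level per column, e.g. shell-mean noise levels.
#' @param seed optional integer seed for reproducibility.
#' @return Noisy signals with the shape of `signal`.
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  if (any(sigma < 0)) stop("sigma must be >= 0")
  if (any(signal < 0, na.rm = TRUE)) stop("signal must be >= 0")
  with_seed(seed, {
    d <- dim(signal)
    if (!is.null(d) && length(sigma) == d[2]) {
      sig <- matrix(sigma, d[1], d[2], byrow = TRUE)
    } else if (length(sigma) == 1) {
      sig <- sigma
    } else if (length(sigma) == length(signal)) {
      sig <- sigma
    } else {
      stop("sigma must be scalar, one per column, or one per element")
    }
    nr <- stats::rnorm(length(signal)) * sig
    ni <- stats::rnorm(length(signal)) * sig
    out <- sqrt((signal + nr)^2 + ni^2)
    if (!is.null(d)) dim(out) <- d
    out
  })
}

#' Estimate the normalised noise level from b = 0 replicates
#'
#' Per-voxel coefficient of variation across b = 0 replicates, aggregated
#' by the median over voxels: \eqn{\hat\sigma = \mathrm{median}_v
#' (\mathrm{SD}_r S_{vr} / \mathrm{mean}_r S_{vr})}, SNR = 1 / sigma-hat.
#'
#' @param b0_volumes matrix, voxels x replicates (>= 3 replicates).
#' @return A [noise_spec()]; `snr = Inf` (with a warning) when the
#'   replicates are identical.
#' @export
estimate_noise_level <- function(b0_volumes) {
  b0_volumes <- as.matrix(b0_volumes)
  if (ncol(b0_volumes) < 3) stop("at least 3 b = 0 replicates are required")
  m <- rowMeans(b0_volumes)
  s <- apply(b0_volumes, 1, stats::sd)
  ok <- is.finite(m) & m > 0
  sigma <- stats::median(s[ok] / m[ok])
  if (sigma == 0) {
    warning("identical replicates: estimated noise level is 0 (SNR = Inf)")
    return(structure(list(snr = Inf, sigma = 0, seed = NULL),
                     class = "noise_spec"))
  }
  noise_spec(snr = 1 / sigma)
}

#' Noise-propagation experiment for the random-forest SANDI fit
#'
#' Draws tissue parameters uniformly from the stated ranges, simulates
#' spherical-mean signals on the acquisition protocol, adds Rician noise at
#' each SNR level, inverts with a random-forest regressor, and summarises
#' per-parameter recovery. Parameter draws are shared across SNR levels
#' (paired design); noise draws use independent substreams.
#'
#' @param protocol a `sandi_protocol` (default [connectome_protocol()]).
#' @param ranges named list of `c(lower, upper)` draw ranges; defaults:
#'   `D_ec` in `[0.5, 1.5]`, `D_in` in `[1, 2]` um^2/ms, `r_s` in `[5, 11]`
#'   um, `f_in` and `f_is` in `[0.1, 0.5]`.
#' @param n_iterations number of simulated signals per SNR level.
#' @param snr_levels SNR levels (default `c(1e10, 50)`: effectively
#'   noise-free, and the in vivo level).
#' @param model optional pre-trained `sandi_rf`; when `NULL` a regressor is
#'   trained per SNR level at the matching noise level (`train_matched =
#'   TRUE`) or once at `train_sigma`.
#' @param train_matched train at the matching sigma of each SNR level.
#' @param train_sigma training noise level used when `train_matched` is
#'   `FALSE`.
#' @param n_train,n_trees training-set size and forest size for the
#'   internally trained regressors.
#' @param seed master seed; expanded into substreams for parameter draws,
#'   noise, and training.
#' @return A tibble of class `sandi_recovery`: one row per parameter x SNR
#'   with `bias`, `rmse`, `r` (Pearson true vs estimated), `n`. The
#'   per-draw truth/estimates are attached as attribute `draws`.
#' @export
run_noise_propagation <- function(protocol = connectome_protocol(),
                                  ranges = list(D_ec = c(0.5, 1.5),
                                                D_in = c(1, 2),
                                                r_s = c(5, 11),
                                                f_in = c(0.1, 0.5),
                                                f_is = c(0.1, 0.5)),
                                  n_iterations = 1000,
                                  snr_levels = c(1e10, 50),
                                  model = NULL,
                                  train_matched = TRUE,
                                  train_sigma = 1 / 50,
                                  n_train = 2e4, n_trees = 50,
                                  seed = 1) {
  shells <- group_shells(protocol)
  bnz <- shell_bvalues(shells)
  pars <- with_seed(substream_seed(seed, 1), {
    draws <- lapply(ranges, function(rg)
      stats::runif(n_iterations, rg[1], rg[2]))
    # the stated ranges keep f_in + f_is <= 1 by construction, but guard
    bad <- draws$f_in + draws$f_is > 1
    while (any(bad)) {
      draws$f_in[bad] <- stats::runif(sum(bad), ranges$f_in[1], ranges$f_in[2])
      draws$f_is[bad] <- stats::runif(sum(bad), ranges$f_is[1], ranges$f_is[2])
      bad <- draws$f_in + draws$f_is > 1
    }
    sandi_params(f_in = draws$f_in, f_is = draws$f_is,
                 r_s = draws$r_s, D_in = draws$D_in, D_ec = draws$D_ec)
  })
  clean <- sandi_signal(pars, b = bnz, delta = protocol$delta,
                        Delta = protocol$Delta)
  out <- list(); draws_out <- list()
  for (li in seq_along(snr_levels)) {
    snr <- snr_levels[li]
    sigma <- 1 / snr
    noisy <- add_rician_noise(clean$values, sigma,
                              seed = substream_seed(seed, 100 + li))
    mdl <- model
    if (is.null(mdl)) {
      tr_sigma <- if (train_matched) sigma else train_sigma
      ts <- build_training_set(protocol = protocol, sigma = tr_sigma,
                               n_train = n_train,
                               seed = substream_seed(seed, 200 + li))
      mdl <- train_regressor(ts, n_trees = n_trees,
                             seed = substream_seed(seed, 300 + li))
    }
    est <- predict_params(mdl, spherical_mean(noisy, bnz))
    for (p in c("f_in", "f_is", "r_s", "D_in", "D_ec")) {
      err <- est[[p]] - pars[[p]]
      out[[length(out) + 1]] <- tibble::tibble(
        parameter = p, snr = snr,
        bias = mean(err), rmse = sqrt(mean(err^2)),
        r = stats::cor(pars[[p]], est[[p]]),
        n = n_iterations)
    }
    free <- c("f_in", "f_is", "r_s", "D_in", "D_ec")
    dw <- cbind(
      tibble::tibble(snr = snr, iteration = seq_len(n_iterations)),
      stats::setNames(as.data.frame(pars[free]), paste0("true_", free)),
      stats::setNames(as.data.frame(est[free]), paste0("est_", free)))
    draws_out[[li]] <- tibble::as_tibble(dw)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "draws") <- dplyr::bind_rows(draws_out)
  attr(res, "snr_levels") <- snr_levels
  class(res) <- c("sandi_recovery", class(res))
  res
}
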