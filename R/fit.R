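# Machine-learned SANDI inversion: labelled training set under the uniform
# priors, random-forest regression (one forest per parameter, as in the
# standard SANDI tooling), and voxel-wise prediction.

#' Uniform prior ranges for the SANDI fit
#'
#' @param D_ec,D_in,r_s,f_in,f_is `c(lower, upper)` bounds for the five
#'   free parameters (um^2/ms for diffusivities, um for `r_s`).
#' @param D_is fixed intra-soma diffusivity, um^2/ms.
#' @return A list of class `sandi_priors`.
#' @export
sandi_priors <- function(D_ec = c(0.25, 3), D_in = c(0.25, 3),
                         r_s = c(1, 12), f_in = c(0, 1), f_is = c(0, 1),
                         D_is = 3) {
  pr <- list(D_ec = D_ec, D_in = D_in, r_s = r_s, f_in = f_in, f_is = f_is)
  for (nm in names(pr)) {
    rg <- pr[[nm]]
    if (length(rg) != 2 || !(rg[1] < rg[2])) {
      stop(sprintf("prior for %s must be c(lower, upper) with lower < upper", nm))
    }
  }
  if (r_s[1] <= 0 || D_ec[1] <= 0 || D_in[1] <= 0) {
    stop("lower bounds of r_s, D_ec, D_in must be positive")
  }
  if (f_in[1] < 0 || f_in[2] > 1 || f_is[1] < 0 || f_is[2] > 1) {
    stop("fraction priors must lie within [0, 1]")
  }
  structure(c(pr, list(D_is = D_is)), class = "sandi_priors")
}

#' Simulate a labelled training set for the random-forest inversion
#'
#' Labels are drawn uniformly within the priors subject to
#' `f_in + f_is <= 1` (rejection sampling, so `f_ec >= 0`); features are
#' the noise-free forward spherical-mean signals with Rician noise added at
#' `sigma`, which may be a scalar or one value per shell (e.g. shell-mean
#' noise levels after direction averaging).
#'
#' @param priors a [sandi_priors()].
#' @param protocol a `sandi_protocol`; only its shell structure and timings
#'   are used.
#' @param sigma normalised Rician noise level(s) applied to the features.
#' @param n_train number of training samples (>= 1000; default 1e5).
#' @param seed integer seed.
#' @return List of class `sandi_training_set`: `features` (n x shells
#'   matrix), `labels` (tibble), `b`, `delta`, `Delta`, `sigma`, `priors`,
#'   `seed`.
#' @export
build_training_set <- function(priors = sandi_priors(),
                               protocol = connectome_protocol(),
                               sigma = 0, n_train = 1e5, seed = 1) {
  if (n_train < 1e3) stop("n_train must be >= 1000")
  shells <- group_shells(protocol)
  bnz <- shell_bvalues(shells)
  labels <- with_seed(substream_seed(seed, 1), {
    need <- n_train
    acc <- list()
    tried <- 0; kept <- 0
    while (need > 0) {
      m <- max(need * 2L, 1000L)
      d <- tibble::tibble(
        f_in = stats::runif(m, priors$f_in[1], priors$f_in[2]),
        f_is = stats::runif(m, priors$f_is[1], priors$f_is[2]),
        r_s  = stats::runif(m, priors$r_s[1], priors$r_s[2]),
        D_in = stats::runif(m, priors$D_in[1], priors$D_in[2]),
        D_ec = stats::runif(m, priors$D_ec[1], priors$D_ec[2]))
      ok <- d$f_in + d$f_is <= 1
      tried <- tried + m; kept <- kept + sum(ok)
      if (tried >= 1e4 && kept / tried < 0.01) {
        stop("rejection rate above 99%: priors leave almost no room for f_in + f_is <= 1")
      }
      d <- d[ok, , drop = FALSE]
      acc[[length(acc) + 1]] <- d
      need <- n_train - sum(vapply(acc, nrow, integer(1)))
    }
    utils::head(dplyr::bind_rows(acc), n_train)
  })
  pars <- sandi_params(f_in = labels$f_in, f_is = labels$f_is,
                       r_s = labels$r_s, D_in = labels$D_in,
                       D_ec = labels$D_ec, D_is = priors$D_is)
  clean <- sandi_signal(pars, b = bnz, delta = protocol$delta,
                        Delta = protocol$Delta)
  feats <- add_rician_noise(clean$values, sigma,
                            seed = substream_seed(seed, 2))
  structure(list(features = feats, labels = labels, b = bnz,
                 delta = protocol$delta, Delta = protocol$Delta,
                 sigma = sigma, priors = priors, seed = seed),
            class = "sandi_training_set")
}

#' Train the random-forest SANDI regressor
#'
#' One regression forest per free parameter (`f_in`, `f_is`, `r_s`,
#' `D_in`, `D_ec`), 200 trees each by default, on the 8 shell-mean
#' features. Tree hyperparameters other than the count are left at the
#' `ranger` defaults and recorded in the model object.
#'
#' @param training a `sandi_training_set`.
#' @param n_trees trees per forest (default 200).
#' @param seed integer seed (the fit is deterministic given the seed).
#' @return An object of class `sandi_rf` carrying the forests, the priors,
#'   the protocol fingerprint (shell b-values, delta, Delta), the training
#'   sigma and size, the seed, and out-of-bag R-squared per parameter.
#' @export
train_regressor <- function(training, n_trees = 200, seed = 1) {
  stopifnot(inherits(training, "sandi_training_set"))
  X <- as.data.frame(training$features)
  names(X) <- paste0("s", seq_along(training$b))
  if (nrow(X) != nrow(training$labels)) {
    stop("feature/label length mismatch")
  }
  if (any(!is.finite(as.matrix(X)))) stop("features must be finite")
  free <- c("f_in", "f_is", "r_s", "D_in", "D_ec")
  forests <- list(); oob <- numeric(0)
  for (i in seq_along(free)) {
    p <- free[i]
    df <- X
    df$y <- training$labels[[p]]
    fit <- ranger::ranger(y ~ ., data = df, num.trees = n_trees,
                          seed = substream_seed(seed, i),
                          num.threads = 1)
    forests[[p]] <- fit
    oob[p] <- fit$r.squared
  }
  structure(list(forests = forests,
                 priors = training$priors,
                 fingerprint = list(b = training$b, delta = training$delta,
                                    Delta = training$Delta),
                 sigma = training$sigma,
                 n_train = nrow(X), n_trees = n_trees, seed = seed,
                 oob_r_squared = oob),
            class = "sandi_rf")
}

#' @export
print.sandi_rf <- function(x, ...) {
  cat(sprintf(
    "<sandi_rf> %d trees/forest, trained on %d signals (sigma %s), shells: %s\n",
    x$n_trees, x$n_train, paste(signif(x$sigma, 3), collapse = "/"),
    paste(signif(x$fingerprint$b, 3), collapse = ", ")))
  cat("out-of-bag R^2:",
      paste(sprintf("%s=%.3f", names(x$oob_r_squared), x$oob_r_squared),
            collapse = ", "), "\n")
  invisible(x)
}

check_fingerprint <- function(model, b) {
  fp <- model$fingerprint$b
  if (length(b) != length(fp) || any(abs(b - fp) > 1e-6)) {
    stop("protocol fingerprint mismatch: model was trained on shells ",
         paste(signif(fp, 3), collapse = ", "), " but data has ",
         paste(signif(b, 3), collapse = ", "))
  }
  invisible(TRUE)
}

#' Predict SANDI parameters from spherical-mean signals
#'
#' Applies the five forests and derives the extracellular fraction from the
#' constraint `f_ec = 1 - f_is - f_in`, clipping to `[0, 1]` with a flag
#' when the constraint is violated.
#'
#' @param model a `sandi_rf`.
#' @param signals a `spherical_mean` object or a records x shells matrix
#'   matching the model fingerprint.
#' @return Tibble with columns `f_in`, `f_is`, `f_ec`, `r_s`, `D_in`,
#'   `D_ec`, `f_ec_clipped` (logical).
#' @export
predict_params <- function(model, signals) {
  stopifnot(inherits(model, "sandi_rf"))
  if (inherits(signals, "spherical_mean")) {
    check_fingerprint(model, signals$b)
    X <- signals$values
  } else {
    X <- as.matrix(signals)
    check_fingerprint(model, rep(model$fingerprint$b, length.out = ncol(X)))
  }
  if (any(!is.finite(X))) stop("non-finite inputs: flag and exclude such records before prediction")
  X <- as.data.frame(X)
  names(X) <- paste0("s", seq_along(model$fingerprint$b))
  pred <- lapply(model$forests, function(f)
    stats::predict(f, data = X, num.threads = 1)$predictions)
  f_ec_raw <- 1 - pred$f_is - pred$f_in
  clipped <- f_ec_raw < 0 | f_ec_raw > 1
  tibble::tibble(
    f_in = pred$f_in, f_is = pred$f_is,
    f_ec = pmin(pmax(f_ec_raw, 0), 1),
    r_s = pred$r_s, D_in = pred$D_in, D_ec = pred$D_ec,
    f_ec_clipped = clipped)
}

#' Fit SANDI maps for a masked DWI volume
#'
#' Computes spherical means per masked voxel and predicts parameter maps.
#' Voxels outside the mask, or with non-positive mean b = 0 signal, are
#' flagged invalid (`NA` in the maps, `FALSE` in `$valid`), never
#' zero-filled.
#'
#' @param dwi 4D array (x, y, z, volumes).
#' @param protocol matching `sandi_protocol`.
#' @param mask logical/numeric 3D array; voxels with value > 0 are fitted.
#' @param model a `sandi_rf` whose fingerprint matches the protocol shells.
#' @param affine optional 4 x 4 matrix carried through to the result.
#' @return List of class `sandi_maps`: one 3D array per metric (`f_in`,
#'   `f_is`, `f_ec`, `r_s`, `D_in`, `D_ec`), plus `valid`, `f_ec_clipped`,
#'   `affine`.
#' @export
fit_dataset <- function(dwi, protocol, mask, model, affine = NULL) {
  dd <- dim(dwi)
  if (length(dd) != 4) stop("dwi must be a 4D array")
  mask_idx <- which(as.logical(mask > 0))
  if (length(mask_idx) == 0) stop("empty mask")
  nvox <- prod(dd[1:3])
  mat <- matrix(dwi, nrow = nvox)[mask_idx, , drop = FALSE]
  shells <- group_shells(protocol)
  sm <- compute_spherical_mean(mat, protocol, shells)
  check_fingerprint(model, sm$b)
  est <- tibble::tibble(f_in = NA_real_, f_is = NA_real_, f_ec = NA_real_,
                        r_s = NA_real_, D_in = NA_real_, D_ec = NA_real_,
                        f_ec_clipped = NA)[rep(1, length(mask_idx)), ]
  if (any(sm$valid)) {
    est[sm$valid, ] <- predict_params(
      model, spherical_mean(sm$values[sm$valid, , drop = FALSE], sm$b))
  }
  maps <- lapply(sandi_metric_names(), function(p) {
    m <- array(NA_real_, dd[1:3])
    m[mask_idx] <- est[[p]]
    m
  })
  names(maps) <- sandi_metric_names()
  valid <- array(FALSE, dd[1:3]); valid[mask_idx] <- sm$valid
  clip <- array(NA, dd[1:3]); clip[mask_idx] <- est$f_ec_clipped
  structure(c(maps, list(valid = valid, f_ec_clipped = clip,
                         affine = affine)),
            class = "sandi_maps")
}
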