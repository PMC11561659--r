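# DTI and DKI scalar metrics fitted to the stated shell subsets by
# two-pass weighted linear least squares on the log signal.

select_shell_volumes <- function(protocol, shells_used, tolerance = 0.049) {
  sel <- lapply(shells_used, function(s) which(abs(protocol$b - s) <= tolerance))
  found <- lengths(sel) > 0
  if (!all(found)) {
    stop("protocol has no volumes at b = ",
         paste(shells_used[!found], collapse = ", "))
  }
  sort(unique(unlist(sel)))
}

dti_design <- function(b, dirs) {
  d <- cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
             2 * dirs[, 1] * dirs[, 2], 2 * dirs[, 1] * dirs[, 3],
             2 * dirs[, 2] * dirs[, 3])
  cbind(1, -b * d)
}

kurtosis_direction_design <- function(dirs) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  cbind(x^4, y^4, z^4,
        4 * x^3 * y, 4 * x^3 * z, 4 * x * y^3, 4 * y^3 * z,
        4 * x * z^3, 4 * y * z^3,
        6 * x^2 * y^2, 6 * x^2 * z^2, 6 * y^2 * z^2,
        12 * x^2 * y * z, 12 * x * y^2 * z, 12 * x * y * z^2)
}

dki_design <- function(b, dirs) {
  cbind(dti_design(b, dirs), (b^2 / 6) * kurtosis_direction_design(dirs))
}

# two-pass WLLS on ln(S): OLS, then weights = squared predicted signals
wlls_fit <- function(X, s) {
  y <- log(s)
  beta <- stats::lm.fit(X, y)$coefficients
  w <- exp(X %*% beta)^2
  unname(stats::lm.fit(X * sqrt(as.vector(w)),
                       y * sqrt(as.vector(w)))$coefficients)
}

tensor_scalars <- function(dvec) {
  Dm <- matrix(c(dvec[1], dvec[4], dvec[5],
                 dvec[4], dvec[2], dvec[6],
                 dvec[5], dvec[6], dvec[3]), 3, 3)
  ev <- eigen(Dm, symmetric = TRUE)
  l <- ev$values  # decreasing
  md <- mean(l)
  fa <- if (sum(l^2) > 0) {
    sqrt(1.5 * sum((l - md)^2) / sum(l^2))
  } else 0
  list(lambda = l, vectors = ev$vectors, MD = md, FA = fa,
       AD = l[1], RD = (l[2] + l[3]) / 2)
}

#' Fit the diffusion tensor (DTI) to the b = 0 and 0.8 ms/um^2 shells
#'
#' Two-pass weighted linear least squares on the log signal, followed by
#' eigen-decomposition. Only the stated shell subset is used; records with
#' non-positive signals on the subset are flagged invalid.
#'
#' @param dwi numeric matrix, records x volumes (use [fit_dataset()]-style
#'   masking upstream for image volumes).
#' @param protocol matching `sandi_protocol`.
#' @param shells_used b-values (ms/um^2) of the shells entering the fit;
#'   default `c(0, 0.8)`. The 0.05 ms/um^2 shell is excluded by default.
#' @param tolerance shell-matching tolerance (ms/um^2).
#' @return Tibble of class `tensor_fit`: tensor components (`Dxx` ...
#'   `Dyz`, um^2/ms), eigenvalues `lambda1 >= lambda2 >= lambda3`, `FA`,
#'   `MD`, `AD`, `RD`, `valid`.
#' @export
fit_dti <- function(dwi, protocol, shells_used = c(0, 0.8),
                    tolerance = 0.049) {
  if (is.null(dim(dwi))) dwi <- matrix(dwi, nrow = 1)
  vols <- select_shell_volumes(protocol, shells_used, tolerance)
  b <- protocol$b[vols]
  dirs <- protocol$directions[vols, , drop = FALSE]
  if (length(unique(apply(round(dirs[b > 0, , drop = FALSE], 6), 1,
                          paste, collapse = ","))) < 6) {
    stop("at least 6 unique nonzero-b directions are required")
  }
  X <- dti_design(b, dirs)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  fit_rows(dwi[, vols, drop = FALSE], X, kurtosis = FALSE)
}

#' Fit the diffusion kurtosis model (DKI) to the b <= 3.45 ms/um^2 shells
#'
#' Joint weighted linear least squares of
#' \eqn{\ln S = \ln S_0 - b D(n) + (b^2/6)\,\overline{D}^2 W(n)} over the
#' stated shell subset. `AK`/`RK` are apparent kurtoses along/perpendicular
#' to the principal tensor eigenvector; `MK` is the mean apparent kurtosis
#' over 256 quasi-uniform directions. Out-of-range kurtosis values are
#' reported as-is (flag downstream), never clamped.
#'
#' @inheritParams fit_dti
#' @param shells_used default `c(0, 0.8, 1.5, 2.4, 3.45)`.
#' @param n_mk_directions direction count for the numerical MK average.
#' @return Tibble of class `kurtosis_fit`: tensor scalars as in
#'   [fit_dti()] plus `AK`, `RK`, `MK`, `valid`.
#' @export
fit_dki <- function(dwi, protocol, shells_used = c(0, 0.8, 1.5, 2.4, 3.45),
                    tolerance = 0.049, n_mk_directions = 256) {
  if (is.null(dim(dwi))) dwi <- matrix(dwi, nrow = 1)
  vols <- select_shell_volumes(protocol, shells_used, tolerance)
  b <- protocol$b[vols]
  if (length(unique(round(b[b > 0], 3))) < 2) {
    stop("DKI requires at least 2 nonzero shells")
  }
  dirs <- protocol$directions[vols, , drop = FALSE]
  if (length(unique(apply(round(dirs[b > 0, , drop = FALSE], 6), 1,
                          paste, collapse = ","))) < 15) {
    stop("at least 15 unique nonzero-b directions are required")
  }
  X <- dki_design(b, dirs)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  fit_rows(dwi[, vols, drop = FALSE], X, kurtosis = TRUE,
           n_mk_directions = n_mk_directions)
}

fit_rows <- function(S, X, kurtosis, n_mk_directions = 256) {
  n <- nrow(S)
  mk_dirs <- if (kurtosis) fibonacci_directions(n_mk_directions)
  rows <- lapply(seq_len(n), function(i) {
    s <- S[i, ]
    if (any(!is.finite(s)) || any(s <= 0)) {
      r <- tibble::tibble(Dxx = NA_real_, Dyy = NA_real_, Dzz = NA_real_,
                          Dxy = NA_real_, Dxz = NA_real_, Dyz = NA_real_,
                          lambda1 = NA_real_, lambda2 = NA_real_,
                          lambda3 = NA_real_, FA = NA_real_, MD = NA_real_,
                          AD = NA_real_, RD = NA_real_, valid = FALSE)
      if (kurtosis) r <- tibble::add_column(r, AK = NA_real_, RK = NA_real_,
                                            MK = NA_real_, .before = "valid")
      return(r)
    }
    beta <- wlls_fit(X, s)
    dvec <- beta[2:7]
    sc <- tensor_scalars(dvec)
    r <- tibble::tibble(Dxx = dvec[1], Dyy = dvec[2], Dzz = dvec[3],
                        Dxy = dvec[4], Dxz = dvec[5], Dyz = dvec[6],
                        lambda1 = sc$lambda[1], lambda2 = sc$lambda[2],
                        lambda3 = sc$lambda[3], FA = sc$FA, MD = sc$MD,
                        AD = sc$AD, RD = sc$RD, valid = TRUE)
    if (kurtosis) {
      vvec <- beta[8:22]  # V_ijkl = MD^2 W_ijkl
      kapp <- function(dirs) {
        dn <- as.vector(dti_design(rep(1, nrow(dirs)), dirs)[, 2:7] %*%
                          dvec) * -1
        vn <- as.vector(kurtosis_direction_design(dirs) %*% vvec)
        vn / dn^2
      }
      e1 <- sc$vectors[, 1]
      # orthonormal frame around e1 for the radial average
      u <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      p1 <- u - sum(u * e1) * e1; p1 <- p1 / sqrt(sum(p1^2))
      p2 <- c(e1[2] * p1[3] - e1[3] * p1[2],
              e1[3] * p1[1] - e1[1] * p1[3],
              e1[1] * p1[2] - e1[2] * p1[1])
      ang <- seq(0, pi, length.out = 65)[-65]
      perp <- t(vapply(ang, function(a) cos(a) * p1 + sin(a) * p2,
                       numeric(3)))
      r <- tibble::add_column(r,
        AK = kapp(matrix(e1, 1, 3)),
        RK = mean(kapp(perp)),
        MK = mean(kapp(mk_dirs)), .before = "valid")
    }
    r
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c(if (kurtosis) "kurtosis_fit" else "tensor_fit", class(out))
  out
}
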