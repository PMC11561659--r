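# Acquisition protocol, shell grouping, spherical-mean computation, and
# DWI / gradient-table I/O.
#
# Unit conventions used throughout the package:
#   b          ms/um^2   (1 ms/um^2 = 1000 s/mm^2; FSL files use s/mm^2)
#   delta,Delta ms       (gradient duration / separation of a PGSE pair)
#   diffusivity um^2/ms
#   gradient    mT/m

#' Gyromagnetic ratio of the proton (rad s^-1 T^-1)
#' @keywords internal
GAMMA_PROTON <- 2.6752e8

#' Construct an acquisition protocol
#'
#' Bundles per-volume b-values and gradient directions with the PGSE timing
#' parameters. b-values are stored in ms/um^2; directions of b = 0 volumes
#' are zero vectors, all others must have unit norm.
#'
#' @param bval numeric vector of b-values (ms/um^2), one per volume.
#' @param bvec numeric matrix of gradient directions, `length(bval)` x 3
#'   (or 3 x n, auto-detected).
#' @param delta gradient duration delta (ms).
#' @param Delta diffusion time Delta (ms); must exceed `delta`.
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1).
#' @return An object of class `sandi_protocol`: a list with elements
#'   `b`, `directions`, `delta`, `Delta`, `gamma`.
#' @export
acquisition_protocol <- function(bval, bvec, delta = 8, Delta = 19,
                                 gamma = GAMMA_PROTON) {
  bval <- as.numeric(bval)
  if (any(!is.finite(bval)) || any(bval < 0)) {
    stop("all b-values must be finite and >= 0")
  }
  bvec <- orient_bvec(bvec, length(bval))
  if (!(delta > 0 && Delta > 0)) stop("timing parameters must be positive")
  if (!(delta < Delta)) stop("gradient duration delta must be < Delta")
  nz <- bval > 0
  nrm <- sqrt(rowSums(bvec^2))
  if (any(nz & nrm == 0)) {
    stop("direction norm 0 for a volume with b > 0")
  }
  if (any(abs(nrm[nz] - 1) > 1e-6)) {
    stop("every nonzero-b direction must have unit norm within 1e-6")
  }
  bvec[!nz, ] <- 0
  structure(
    list(b = bval, directions = bvec, delta = delta, Delta = Delta,
         gamma = gamma),
    class = "sandi_protocol"
  )
}

#' @export
print.sandi_protocol <- function(x, ...) {
  cat(sprintf(
    "<sandi_protocol> %d volumes (%d with b > 0), b in [%g, %g] ms/um^2, delta = %g ms, Delta = %g ms\n",
    length(x$b), sum(x$b > 0), min(x$b), max(x$b), x$delta, x$Delta))
  invisible(x)
}

# Accept n x 3 or 3 x n and return n x 3. The ambiguous 3 x 3 case is
# resolved by context: rows = volumes for in-memory matrices, component
# rows (FSL layout) for tables read from disk.
orient_bvec <- function(bvec, n, fsl = FALSE) {
  bvec <- as.matrix(bvec)
  if (!is.numeric(bvec)) stop("bvec must be numeric")
  if (fsl) {
    # file context: a 3 x 3 table is taken in the FSL layout (component rows)
    if (nrow(bvec) == 3 && ncol(bvec) == n) return(unname(t(bvec)))
    if (nrow(bvec) == n && ncol(bvec) == 3) return(unname(bvec))
  } else {
    if (nrow(bvec) == n && ncol(bvec) == 3) return(unname(bvec))
    if (nrow(bvec) == 3 && ncol(bvec) == n) return(unname(t(bvec)))
  }
  stop(sprintf("bvec dimensions %d x %d do not match %d volumes",
               nrow(bvec), ncol(bvec), n))
}

#' Read FSL-dialect bval/bvec files
#'
#' Whitespace-separated text files; the bvec file holds 3 rows (or 3
#' columns, auto-detected) matching the bval length. Values larger than
#' 50 are interpreted as s/mm^2 and divided by 1000, so both FSL-unit and
#' ms/um^2 tables load to the internal ms/um^2 convention. Directions are
#' renormalised to unit length.
#'
#' @param bval_path,bvec_path paths to the two text files.
#' @inheritParams acquisition_protocol
#' @return A [acquisition_protocol()] object.
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path, delta = 8, Delta = 19,
                             gamma = GAMMA_PROTON) {
  bval <- scan(bval_path, what = numeric(), quiet = TRUE)
  raw <- utils::read.table(bvec_path, header = FALSE)
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop("non-numeric entries in bvec file")
  bvec <- orient_bvec(raw, length(bval), fsl = TRUE)
  if (max(bval) > 50) bval <- bval / 1000  # s/mm^2 -> ms/um^2
  nrm <- sqrt(rowSums(bvec^2))
  if (any(bval > 0 & nrm == 0)) stop("direction norm 0 for a volume with b > 0")
  keep <- nrm > 0
  bvec[keep, ] <- bvec[keep, , drop = FALSE] / nrm[keep]
  acquisition_protocol(bval, bvec, delta = delta, Delta = Delta, gamma = gamma)
}

#' Write FSL-dialect bval/bvec files
#'
#' Inverse of [read_bvals_bvecs()]: b-values are written in s/mm^2 and
#' directions as three whitespace-separated rows.
#'
#' @param protocol a `sandi_protocol`.
#' @param bval_path,bvec_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_bvals_bvecs <- function(protocol, bval_path, bvec_path) {
  writeLines(paste(sprintf("%.10g", protocol$b * 1000), collapse = " "),
             bval_path)
  m <- t(protocol$directions)
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.15g", r), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Group volumes into b-shells
#'
#' Clusters the per-volume b-values into shells: sorted unique b-values are
#' split wherever consecutive values differ by more than `tolerance`. The
#' b = 0 shell (centre <= `tolerance`) is kept separate from the lowest
#' diffusion-weighted shell, so a 0.05 ms/um^2 shell survives alongside
#' true b = 0 volumes.
#'
#' @param protocol a `sandi_protocol`.
#' @param tolerance clustering tolerance in ms/um^2 (default 0.049, below
#'   the 0.05 ms/um^2 shell of the Connectome protocol).
#' @return A tibble of class `shell_table` with one row per shell:
#'   `shell` (index, b0 shell = 0), `b` (shell centre), `volumes`
#'   (list-column of volume indices), `n_dir` (member count), `is_b0`.
#' @export
group_shells <- function(protocol, tolerance = 0.049) {
  stopifnot(inherits(protocol, "sandi_protocol"))
  if (!(tolerance > 0)) stop("tolerance must be > 0")
  b <- protocol$b
  ord <- order(b)
  bs <- b[ord]
  brk <- c(0, which(diff(bs) > tolerance), length(bs))
  centres <- vapply(seq_len(length(brk) - 1), function(i)
    mean(bs[(brk[i] + 1):brk[i + 1]]), numeric(1))
  # ambiguity guard: chained values can drift a cluster wider than the
  # tolerance, leaving members closer to a neighbouring centre than to a
  # shell assignment anyone would trust
  for (i in seq_len(length(brk) - 1)) {
    memb <- bs[(brk[i] + 1):brk[i + 1]]
    if (any(abs(memb - centres[i]) > tolerance)) {
      stop("ambiguous shell clustering: a b-value lies more than the tolerance away from its shell centre")
    }
  }
  members <- lapply(seq_len(length(brk) - 1), function(i)
    sort(ord[(brk[i] + 1):brk[i + 1]]))
  is_b0 <- centres <= tolerance
  shell_idx <- cumsum(!is_b0)
  shell_idx[is_b0] <- 0L
  out <- tibble::tibble(
    shell = shell_idx,
    b = centres,
    volumes = members,
    n_dir = lengths(members),
    is_b0 = is_b0
  )
  class(out) <- c("shell_table", class(out))
  out
}

#' Nonzero shell b-values of a shell table
#' @param shells a `shell_table`.
#' @return Numeric vector of nonzero shell centres, ascending.
#' @export
shell_bvalues <- function(shells) {
  shells$b[!shells$is_b0]
}

#' Direction-averaged, b0-normalised signals per shell
#'
#' Computes the spherical mean (powder average) of a diffusion-weighted
#' signal: for each nonzero shell the arithmetic mean over member volumes,
#' divided by the mean over all b = 0 volumes. Voxels whose mean b = 0
#' signal is not positive are flagged invalid (`NA` values).
#'
#' @param dwi_values numeric vector (one voxel) or matrix
#'   (records x volumes) of signal values.
#' @param protocol a `sandi_protocol` (used for validation only).
#' @param shells a `shell_table` from [group_shells()]; must contain a
#'   b = 0 shell.
#' @return An object of class `spherical_mean`: list with `values`
#'   (records x shells matrix), `b` (nonzero shell b-values), `b0_mean`,
#'   and `valid` (logical per record).
#' @export
compute_spherical_mean <- function(dwi_values, protocol, shells) {
  if (is.null(dim(dwi_values))) dwi_values <- matrix(dwi_values, nrow = 1)
  if (ncol(dwi_values) != length(protocol$b)) {
    stop(sprintf("dwi has %d volumes but protocol has %d",
                 ncol(dwi_values), length(protocol$b)))
  }
  if (!any(shells$is_b0)) stop("at least one b = 0 volume is required")
  b0_idx <- unlist(shells$volumes[shells$is_b0])
  b0_mean <- rowMeans(dwi_values[, b0_idx, drop = FALSE])
  valid <- is.finite(b0_mean) & b0_mean > 0
  nz <- which(!shells$is_b0)
  vals <- vapply(nz, function(i)
    rowMeans(dwi_values[, shells$volumes[[i]], drop = FALSE]),
    numeric(nrow(dwi_values)))
  vals <- matrix(vals, nrow = nrow(dwi_values)) / b0_mean
  vals[!valid, ] <- NA_real_
  spherical_mean(vals, shells$b[nz], b0_mean = b0_mean, valid = valid)
}

#' Construct a spherical-mean signal object
#'
#' @param values records x shells matrix of b0-normalised shell means.
#' @param b nonzero shell b-values (ms/um^2), one per column.
#' @param b0_mean optional per-record b = 0 reference.
#' @param valid optional logical flag per record.
#' @return An object of class `spherical_mean`.
#' @export
spherical_mean <- function(values, b, b0_mean = NULL, valid = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != length(b)) stop("values must have one column per shell")
  if (is.null(valid)) valid <- apply(values, 1, function(r) all(is.finite(r)))
  structure(list(values = values, b = as.numeric(b), b0_mean = b0_mean,
                 valid = valid),
            class = "spherical_mean")
}

#' @export
print.spherical_mean <- function(x, ...) {
  cat(sprintf("<spherical_mean> %d record(s) x %d shells (b: %s)\n",
              nrow(x$values), length(x$b),
              paste(signif(x$b, 3), collapse = ", ")))
  invisible(x)
}

#' @export
as_tibble.spherical_mean <- function(x, ...) {
  tibble::tibble(
    record = rep(seq_len(nrow(x$values)), each = length(x$b)),
    b = rep(x$b, nrow(x$values)),
    value = as.vector(t(x$values))
  )
}

#' Gradient amplitude implied by a b-value
#'
#' Inverts the rectangular-pulse PGSE relation
#' b = gamma^2 g^2 delta^2 (Delta - delta/3).
#'
#' @param b b-value (ms/um^2).
#' @param delta,Delta PGSE timings (ms).
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1).
#' @return Gradient amplitude in mT/m.
#' @export
b_to_gradient <- function(b, delta = 8, Delta = 19, gamma = GAMMA_PROTON) {
  if (any(b < 0)) stop("b must be >= 0")
  if (!(delta > 0 && Delta > 0 && delta < Delta)) {
    stop("timing parameters must be positive with delta < Delta")
  }
  b_si <- b * 1e9                      # s/m^2
  d <- delta * 1e-3; D <- Delta * 1e-3 # s
  1000 * sqrt(b_si / (gamma^2 * d^2 * (D - d / 3)))  # mT/m
}

#' b-value implied by a gradient amplitude
#'
#' @param g gradient amplitude (mT/m).
#' @inheritParams b_to_gradient
#' @return b-value in ms/um^2.
#' @export
gradient_to_b <- function(g, delta = 8, Delta = 19, gamma = GAMMA_PROTON) {
  if (any(g < 0)) stop("g must be >= 0")
  if (!(delta > 0 && Delta > 0 && delta < Delta)) {
    stop("timing parameters must be positive with delta < Delta")
  }
  d <- delta * 1e-3; D <- Delta * 1e-3
  gamma^2 * (g / 1000)^2 * d^2 * (D - d / 3) / 1e9
}

#' Load a 4D DWI NIfTI with its gradient table
#'
#' @param nifti_path path to a 4D NIfTI file.
#' @param bval_path,bvec_path FSL gradient-table paths.
#' @inheritParams acquisition_protocol
#' @return List with `data` (4D array), `affine` (4 x 4 matrix from the
#'   header, untouched), `protocol`.
#' @export
load_dwi <- function(nifti_path, bval_path, bvec_path,
                     delta = 8, Delta = 19) {
  img <- RNifti::readNifti(nifti_path)
  dd <- dim(img)
  if (length(dd) != 4) stop("expected a 4D NIfTI volume")
  protocol <- read_bvals_bvecs(bval_path, bvec_path, delta = delta,
                               Delta = Delta)
  if (dd[4] != length(protocol$b)) {
    stop(sprintf("NIfTI has %d volumes but gradient table has %d entries",
                 dd[4], length(protocol$b)))
  }
  list(data = unclass(img)[, , , , drop = FALSE],
       affine = structure(RNifti::xform(img), class = "matrix"),
       protocol = protocol)
}

#' Write a 3D/4D array as NIfTI
#'
#' @param data numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param affine optional 4 x 4 voxel-to-world matrix.
#' @return Invisibly, `path`.
#' @export
write_dwi <- function(data, path, affine = NULL) {
  img <- RNifti::asNifti(data)
  if (!is.null(affine)) {
    RNifti::qform(img) <- structure(affine, code = 2L)
    RNifti::sform(img) <- structure(affine, code = 2L)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Quasi-uniform unit directions (spherical Fibonacci lattice)
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' The 8-shell Connectome acquisition protocol
#'
#' Builds the multi-shell protocol used throughout the package: nonzero
#' shells at b = 0.05, 0.35, 0.8, 1.5, 2.4, 3.45, 4.75 and 6 ms/um^2 with
#' 32 quasi-uniform directions below b = 2.3 ms/um^2 and 64 otherwise,
#' delta = 8 ms, Delta = 19 ms, and b = 0 volumes interspersed every 16
#' diffusion-weighted volumes.
#'
#' @param b0_every intersperse one b = 0 volume every this many DWIs
#'   (default 16, giving 24 b = 0 volumes).
#' @inheritParams acquisition_protocol
#' @return A `sandi_protocol`.
#' @export
connectome_protocol <- function(b0_every = 16, delta = 8, Delta = 19) {
  shells <- c(0.05, 0.35, 0.8, 1.5, 2.4, 3.45, 4.75, 6)
  ndir <- ifelse(shells < 2.3, 32L, 64L)
  b <- rep(shells, ndir)
  dirs <- do.call(rbind, lapply(ndir, fibonacci_directions))
  # intersperse b = 0 volumes every `b0_every` DWIs
  n <- length(b)
  out_b <- numeric(0); out_d <- NULL
  for (k in seq(1, n, by = b0_every)) {
    idx <- k:min(k + b0_every - 1, n)
    out_b <- c(out_b, 0, b[idx])
    out_d <- rbind(out_d, c(0, 0, 0), dirs[idx, , drop = FALSE])
  }
  acquisition_protocol(out_b, out_d, delta = delta, Delta = Delta)
}
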