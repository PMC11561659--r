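# Shared fixtures, built in code.

connectome_shell_bvalues <- function() c(0.05, 0.35, 0.8, 1.5, 2.4, 3.45, 4.75, 6)

# small multi-shell protocol for tensor tests: one b0 + dense directions on
# the requested shells
dense_protocol <- function(b_shells, n_dir = 32, n_b0 = 2) {
  dirs <- fibonacci_directions(n_dir)
  b <- c(rep(0, n_b0), rep(b_shells, each = n_dir))
  d <- rbind(matrix(0, n_b0, 3),
             dirs[rep(seq_len(n_dir), times = length(b_shells)), ])
  acquisition_protocol(b, d)
}

# tensor signal on a protocol from eigenvalues and a rotation
tensor_signal <- function(protocol, lambda, R = diag(3), s0 = 1) {
  D <- R %*% diag(lambda) %*% t(R)
  vapply(seq_along(protocol$b), function(i) {
    n <- protocol$directions[i, ]
    s0 * exp(-protocol$b[i] * drop(t(n) %*% D %*% n))
  }, numeric(1))
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}
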