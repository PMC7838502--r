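# Shared tiny fixtures, generated in code.

rand_unit_matrix <- function(n, m = n, seed = 1) {
  set.seed(seed)
  matrix(runif(n * m), n, m)
}

rand_rank2 <- function(n, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(2 * n), n, 2)
  B <- matrix(rnorm(2 * n), n, 2)
  M <- tcrossprod(A, B)
  M / max(abs(M))
}

checkerboard <- function(n) {
  outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 2)
}

# quick solver settings for small tests
fast_cfg <- function(...) {
  fusion_config(latlrr = list(tol = 1e-6, max_iter = 400), ...)
}
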