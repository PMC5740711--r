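# Shared fixture builders; everything is generated in code at test time.

toy_matrix <- function(m = 20, n = 10, seed = 1, mu = 7, sd = 1.5,
                       noise = 0.5) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    base <- rnorm(m, mu, sd)
    x <- base + matrix(rnorm(m * n, 0, noise), m, n)
    dimnames(x) <- list(sprintf("g%03d", seq_len(m)),
                        sprintf("s%02d", seq_len(n)))
    x
  })
}

toy_design <- function(x, n_A = ncol(x) %/% 2) {
  n <- ncol(x)
  group_design(setNames(rep(c("A", "B"), c(n_A, n - n_A)), colnames(x)))
}

# independent step-up BH oracle, written from the definition
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

expect_matrix_equal <- function(a, b, tol = 1e-10) {
  expect_equal(dim(a), dim(b))
  expect_lt(max(abs(a - b)), tol)
}
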