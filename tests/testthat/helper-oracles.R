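# Independent oracles kept deliberately separate from the package internals.

# Brute-force normal-equations solve of the full quadratic: explicit
# construction of the 6-column (k = 2) model matrix and solve(t(X) X, t(X) y).
normal_equations_fit <- function(coded, y) {
  x1 <- coded[, 1L]
  x2 <- coded[, 2L]
  X <- cbind(1, x1, x2, x1^2, x2^2, x1 * x2)
  colnames(X) <- c("b0", "b1", "b2", "b11", "b22", "b12")
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Brute-force argmax of a quadratic surface over a coded grid, evaluated by
# direct polynomial arithmetic (no package predict()).
grid_argmax <- function(beta, lo = -1, hi = 1, n = 201L) {
  ax <- seq(lo, hi, length.out = n)
  g <- expand.grid(x1 = ax, x2 = ax)
  val <- beta[["b0"]] + beta[["b1"]] * g$x1 + beta[["b2"]] * g$x2 +
    beta[["b11"]] * g$x1^2 + beta[["b22"]] * g$x2^2 +
    beta[["b12"]] * g$x1 * g$x2
  unlist(g[which.max(val), ])
}

# The study's two factors, shared across tests.
study_spec <- function() quebracho_spec()
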