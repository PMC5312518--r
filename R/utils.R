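# internal numerics shared across modules

.gl_cache <- new.env(parent = emptyenv())

# Gauss-Legendre nodes/weights on [-1, 1], cached by order
.gl_rule <- function(n) {
  key <- as.character(n)
  rule <- .gl_cache[[key]]
  if (is.null(rule)) {
    rule <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- rule
  }
  rule
}

# nodes/weights rescaled to [a, b]
.gl_nodes <- function(n, a, b) {
  rule <- .gl_rule(n)
  list(x = (b - a) / 2 * rule$x + (b + a) / 2, w = (b - a) / 2 * rule$w)
}

.is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.clamp01 <- function(u, eps = 1e-15) pmin(pmax(u, eps), 1 - eps)

# derive a valid 32-bit seed for replicate r of configuration d under root seed
.derive_seed <- function(root, d, r) {
  as.integer((as.double(root) * 1000003 + as.double(d) * 10007 + as.double(r)) %%
               2147483629)
}
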