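# Internal helpers shared across modules.

# Gauss-Legendre nodes/weights on [-1, 1], cached per order.
gl_nodes <- function(n = 64L) {
  key <- paste0("gl", n)
  if (is.null(.p4d[[key]])) {
    .p4d[[key]] <- pracma::gaussLegendre(n, -1, 1)
  }
  .p4d[[key]]
}

# Fixed-order Gauss-Legendre quadrature of f on [a, b].
gl_quad <- function(f, a, b, n = 64L) {
  if (b <= a) return(0)
  gl <- gl_nodes(n)
  h <- (b - a) / 2
  m <- (a + b) / 2
  h * sum(gl$w * f(m + h * gl$x))
}

# Run code with a temporary RNG seed, restoring global state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_domain <- function(...) {
  stop(structure(class = c("proton4d_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("proton4d_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(name, " must be a finite numeric scalar")
  if (positive && x <= 0) stop_domain(name, " must be > 0")
  invisible(x)
}
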