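# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Derive a reproducible per-component seed from a single master seed so that
# individual pipeline stages can be replayed in isolation. Kept below 2^31.
substream_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  offs <- sum(utf8ToInt(as.character(component)))
  as.integer((abs(seed) + 10007 * offs) %% 2147483629)
}

with_substream <- function(seed, component, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, component))
  expr
}

# Draw n positive values from a simple distribution spec, e.g.
# list(dist = "lognormal", meanlog = 0, sdlog = 0.5) or
# list(dist = "gamma", shape = 4, rate = 1).
draw_positive <- function(law, n) {
  stopifnot(is.list(law), !is.null(law$dist))
  x <- switch(law$dist,
    lognormal = stats::rlnorm(n, meanlog = law$meanlog, sdlog = law$sdlog),
    gamma     = stats::rgamma(n, shape = law$shape,
                              rate = if (is.null(law$rate)) 1 / law$scale else law$rate),
    uniform   = stats::runif(n, min = law$min, max = law$max),
    stop("unsupported distribution spec: ", law$dist)
  )
  if (any(x <= 0)) x <- pmax(x, .Machine$double.eps)
  x
}

is_psd <- function(m, tol = 1e-8) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(abs(ev), 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
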