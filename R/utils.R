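# internal helpers shared across modules

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All seeded generators go through this so identical (seed, config) pairs
# yield bit-identical output without disturbing the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_config("invalid config: '%s' must be a single positive number", name)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop_config("invalid config: '%s' must be a single non-negative number", name)
  }
  invisible(x)
}

# uniform-sampling check for time vectors; returns the common step
check_uniform_dt <- function(time, tol = 1e-6) {
  d <- diff(time)
  if (length(d) < 1L || any(!is.finite(d)) || any(d <= 0)) {
    stop("time vector must be strictly increasing", call. = FALSE)
  }
  dt <- stats::median(d)
  if (max(abs(d - dt)) > tol * dt) {
    stop("non-uniform sampling: resample upstream before analysis", call. = FALSE)
  }
  dt
}

# Mclust resolves its workers by name in the calling frame, so run it in a
# child of the mclust namespace rather than attaching the package.
mclust_fit <- function(x, G) {
  env <- new.env(parent = asNamespace("mclust"))
  assign(".x", x, envir = env)
  assign(".G", G, envir = env)
  eval(quote(Mclust(.x, G = .G, verbose = FALSE)), envir = env)
}

# FNV-1a 32-bit hash of a character scalar, for provenance records
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # the byte xor only touches the low 8 bits; keep h as a double and
    # split the modular multiply so intermediates stay below 2^53
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b %% 256)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
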