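# Shared fixtures, memoized so expensive protocol builds run once per
# test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

wide_protocol <- function() fixture("wide", protocol_wide_reduced)

narrow_protocol <- function() fixture("narrow", protocol_narrow)

wide_kernel <- function() fixture("wide_kd", function()
  protocol_kernel(wide_protocol()))

narrow_kernel <- function() fixture("narrow_kd", function()
  protocol_kernel(narrow_protocol()))

# small random smooth gradient waveform (Fourier series, fixed harmonics)
random_waveform <- function(n_harm = 4, tau = 5e-3, dt = 5e-6,
                            amp = 0.1) {
  n <- round(tau / dt)
  t <- (seq_len(n) - 1) * dt
  g <- sapply(1:3, function(a) {
    x <- numeric(n)
    for (h in seq_len(n_harm))
      x <- x + stats::rnorm(1) * sin(pi * h * t / tau) +
        stats::rnorm(1) * sin(2 * pi * h * t / tau)
    x
  })
  gradient_waveform(g * amp / max(abs(g)), dt)
}

# Brute-force NNLS oracle: enumerate all supports, solve the
# unconstrained least squares on each, keep the best feasible solution.
# Independent of the active-set route used by the package.
nnls_bruteforce <- function(K, y) {
  p <- ncol(K)
  stopifnot(p <= 12)
  best <- list(obj = sum(y^2), w = numeric(p))
  for (mask in 1:(2^p - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(p - 1))) > 0)
    Ks <- K[, sel, drop = FALSE]
    w <- tryCatch(qr.solve(crossprod(Ks), crossprod(Ks, y)),
                  error = function(e) NULL)
    if (is.null(w) || any(w < 0)) next
    obj <- sum((y - Ks %*% w)^2)
    if (obj < best$obj - 1e-12 * best$obj) {
      full <- numeric(p)
      full[sel] <- w
      best <- list(obj = obj, w = full)
    }
  }
  best
}
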