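#' Derive a reproducible child seed from a master seed
#'
#' Mixes the master seed with an arbitrary set of string/number tokens
#' (typically stage name and participant id) into an integer in
#' `[1, 2^31 - 2]`, so that every pipeline stage gets an independent yet fully
#' reproducible random stream.
#'
#' @param master integer master seed.
#' @param ... tokens (characters or numbers) identifying the consumer.
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(1, "simulate", 3)
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  h <- (abs(as.numeric(master)) %% m)
  tokens <- unlist(lapply(list(...), as.character))
  for (tok in tokens) {
    for (code in utf8ToInt(tok)) {
      h <- (h * 131 + code) %% m
    }
  }
  # final avalanche round so (master, master+1) do not give adjacent streams
  h <- (h * 48271) %% m
  as.integer(h %% (m - 2) + 1)
}

#' Hann window
#'
#' Symmetric Hann taper of length `n` (endpoints exactly zero).
#'
#' @param n window length in samples (>= 2).
#' @return numeric vector of length `n`.
#' @export
hann_window <- function(n) {
  stopifnot(n >= 2)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

# internal: stop with a consistent message when a scalar is out of range
.check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}
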