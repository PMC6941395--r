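#' Round half away from zero
#'
#' Commercial rounding: halves round away from zero, unlike [round()], which
#' rounds halves to even. Used for scenario allocations and for formatting
#' reported percentages, so that e.g. 1025.5 rounds to 1026.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(1025.5)   # 1026, not 1026 vs round()'s banker's rounding
#' round_half_up(0.4426, 3)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a reproducible sub-stream seed
#'
#' Maps a master seed plus an arbitrary key (e.g. scenario label, outcome
#' name, treatment arm) to a seed in `[1, 2^31 - 2]`. The mapping is a
#' base-31 polynomial hash of the key combined linearly with the master seed,
#' so every (scenario, outcome, arm) triple gets its own stream and adding a
#' new scenario never perturbs existing streams.
#'
#' @param master_seed integer master seed for the whole run.
#' @param ... key components; coerced to character and joined.
#' @return a single integer seed suitable for [set.seed()].
#' @export
stream_seed <- function(master_seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "\x1f")
  p <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% p
  s <- (abs(as.numeric(master_seed)) %% p * 48271 + h) %% p
  as.integer(s %% (p - 1) + 1)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# stop() with a classed condition so callers can test for specific failures.
abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "qwtsim_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
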