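#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so generators are pure functions of their seed
#' without clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage seed from a master seed and a tag
#'
#' Deterministic 31-bit hash so every pipeline stage and every plan gets its
#' own reproducible RNG stream from one master seed.
#'
#' @param master integer master seed.
#' @param tag character tag naming the consumer (e.g. `"plan3"`).
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, tag) {
  m <- 2147483647
  s <- as.double(master %% m)
  for (code in utf8ToInt(as.character(tag))) {
    s <- (s * 31 + code) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

stop_rotqa <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "rotqa_error")))
}

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      (strict && x <= lower) || (!strict && x < lower)) {
    stop_rotqa(sprintf("`%s` must be a finite number %s %s", name,
                       if (strict) ">" else ">=", lower), "rotqa_invalid_spec")
  }
  invisible(x)
}
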