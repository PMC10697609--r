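`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb
#' the caller's RNG stream. With `seed = NULL` the expression runs on the
#' current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stable per-participant seed derived from a session seed and an id
#'
#' Multiplicative string hash folded with the session seed modulo 2^31 - 1,
#' so derived seeds are platform-stable and valid `set.seed()` inputs.
#' @noRd
participant_seed <- function(seed, id) {
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(as.character(id))) h <- (h * 31 + code) %% m
  out <- (as.numeric(seed) %% m) * 48271 %% m
  out <- (out + h * 69621) %% m
  as.integer(out %% (m - 1) + 1)
}

stop_config <- function(field, msg) {
  stop(sprintf("configuration error in field '%s': %s", field, msg), call. = FALSE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

#' Four-letter condition code (PnLn, PnLw, PwLn, PwLw)
#' @noRd
cond_code <- function(prior_cond, lik_cond) {
  paste0("P", substr(prior_cond, 1, 1), "L", substr(lik_cond, 1, 1))
}

cond_codes <- function() c("PnLn", "PnLw", "PwLn", "PwLw")

cond_from_code <- function(code) {
  list(prior_cond = ifelse(substr(code, 2, 2) == "n", "narrow", "wide"),
       lik_cond   = ifelse(substr(code, 4, 4) == "n", "narrow", "wide"))
}
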