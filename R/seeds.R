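#' Derive a reproducible sub-seed from a master seed
#'
#' Counter-based splitting: every stochastic component (template generation,
#' per-member rendering, per-replicate noise, training) draws its own seed
#' from the master seed and a small set of integer tags, so any single
#' artifact can be regenerated in isolation. Uses a 32-bit mixing hash and
#' returns a value in \[1, 2^31 - 2\].
#'
#' @param master Integer master seed.
#' @param ... Further integer tags (e.g. family index, member index, level,
#'   replicate).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  tags <- c(as.numeric(master), as.numeric(unlist(list(...))))
  h <- 2166136261
  for (t in tags) {
    ## FNV-style mix in double arithmetic, kept exact below 2^53
    h <- (h * 16777619) %% 2147483629
    h <- (h + (t %% 2147483629) + 11) %% 2147483629
  }
  as.integer(h %% 2147483646) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
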