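#' Derive a named seed substream
#'
#' One top-level seed is fanned out into named substreams so components
#' (world generation, bootstrap splits, null models) can be re-run in
#' isolation reproducibly, and adding stages never perturbs earlier ones.
#' Derived seeds stay inside the 32-bit integer range.
#'
#' @param seed Integer master seed.
#' @param ... Tokens naming the substream (coerced to character).
#' @return A positive integer seed.
#' @export
derive_seed <- function(seed, ...) {
  tokens <- paste(c(seed, ...), collapse = ":")
  h <- 0
  for (v in utf8ToInt(tokens)) h <- (h * 131 + v) %% 2147483629
  as.integer((h + as.numeric(seed) * 7919) %% 2147483629 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
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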