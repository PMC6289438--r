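#' Derive a reproducible sub-seed from a base seed and labels
#'
#' Hashes a base seed together with an arbitrary sequence of labels
#' (strings or numbers) into an integer seed below 2^31. Used throughout
#' the package so that every stage, dog, month and chain draws from its
#' own stream: adding a dog or a stage never perturbs the draws of
#' another.
#'
#' @param seed integer base seed.
#' @param ... labels identifying the stream (coerced to character).
#' @return a positive integer seed.
#' @examples
#' derive_seed(1, "trial", "13102MA", "thoracic", 4)
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1
  parts <- vapply(list(...), function(p) paste(as.character(p), collapse = "/"),
                  character(1))
  h <- abs(seed) %% m
  for (b in utf8ToInt(paste(parts, collapse = "|"))) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards. Keeps every generator a pure function of its
# arguments.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
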