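# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible child seed from a master seed and labels
#'
#' Stable integer mixing (splitmix-style) of the master seed with the UTF-8
#' bytes of the labels; identical inputs give identical child seeds on every
#' platform, and distinct labels decorrelate the noise streams of different
#' (modality, size, repeat, slice) combinations.
#'
#' @param master Integer master seed.
#' @param ... Labels (coerced to character) identifying the consumer.
#' @return An integer in [0, 2^31 - 1].
#' @export
child_seed <- function(master, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.numeric(master) %% 2147483647
  for (b in utf8ToInt(labels)) {
    h <- (h * 69069 + b * 2654435761 + 1013904223) %% 2147483647
  }
  as.integer(h)
}

# stable content digest used in manifests and provenance fields
ctqa_digest <- function(x) rlang::hash(x)
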