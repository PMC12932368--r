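#' Derive a child seed from a root seed and a key
#'
#' Hierarchical seeding: every stochastic stage of the simulator draws its
#' seed deterministically from a root seed plus a string key (e.g.
#' `"genome/rep3"`), so that changing one stage does not perturb the random
#' streams of the others. The hash is a 31-bit multiplicative string hash,
#' exact in double-precision integer arithmetic.
#'
#' @param root integer root seed.
#' @param ... character or numeric components of the key; concatenated with
#'   `"/"`.
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' child_seed(42, "genome", 1) # deterministic
child_seed <- function(root, ...) {
  key <- paste(c(...), collapse = "/")
  h <- as.double(root) %% 2147483647
  for (ch in utf8ToInt(key)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% 2147483647L)
  expr
}
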