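#' Derive a reproducible child seed from a master seed
#'
#' All randomness in the package flows from one integer master seed. Child
#' streams (per subject, per volume, per replicate) get their own seeds via a
#' deterministic integer hash, so streams are independent of the order in
#' which they are consumed.
#'
#' @param seed Integer master seed.
#' @param ... Integer indices identifying the child stream (e.g. subject
#'   number, stage number).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in c(idx, 0)) {
    # multiplier small enough that the product stays exact in double precision
    h <- (69069 * (h + as.numeric(k) + 1)) %% 2147483647
    h <- (69069 * h + 12345) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

# Run expr with a local RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Logistic helpers used for the box-constrained NODDI refinement.
logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stopifnot_same_grid <- function(...) {
  dims <- lapply(list(...), dim)
  dims <- dims[!vapply(dims, is.null, logical(1))]
  if (length(dims) > 1 &&
      !all(vapply(dims[-1], identical, logical(1), dims[[1]]))) {
    stop("input volumes are not on the same grid", call. = FALSE)
  }
  invisible(TRUE)
}
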