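#' @importFrom rlang abort warn %||%
#' @importFrom stats cor rnorm runif setNames
#' @importFrom utils head modifyList write.csv
NULL

# Internal error helper with a stable class so callers can condition on it.
csb_stop <- function(msg, class) {
  abort(msg, class = c(class, "csbnet_error"))
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; channel-count arithmetic here uses
#' the convention that halves round up (e.g. `192 * 0.7 = 134.4 -> 134`,
#' `0.5 -> 1`).
#'
#' @param x Numeric vector (non-negative in all internal uses).
#' @return Integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

# One user-visible seed drives every stochastic component.  Distinct purposes
# get deterministically derived sub-seeds so that e.g. adding an augmentation
# step does not perturb weight initialization.  Kept below 2^31 - 1.
derive_seed <- function(seed, purpose) {
  offsets <- c(
    init = 101L, shuffle = 211L, dropout = 307L, augment = 401L,
    synth = 503L, split = 601L
  )
  off <- offsets[[purpose]]
  if (is.null(off)) csb_stop(paste0("unknown seed purpose: ", purpose), "csbnet_bad_seed")
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483629)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards.  With seed = NULL the current stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# scalar validators -----------------------------------------------------------

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    csb_stop(sprintf("`%s` must be a single integer >= %d", name, min),
             "csbnet_bad_config")
  }
  as.integer(x)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x >= 1) {
    csb_stop(sprintf("`%s` must be a single number in [0, 1)", name),
             "csbnet_bad_config")
  }
  as.numeric(x)
}
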