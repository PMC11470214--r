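# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed (if any) is restored afterwards so package functions never
# disturb the user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  # force the seed promise before snapshotting the RNG state: evaluating it
  # later could itself draw from (and then be rewound with) the saved state
  seed <- as.integer(seed)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed (< 2^31) from a master seed and a stage
# label, so every pipeline stage has its own documented random stream.
#' @noRd
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h * 7919 + 1) %% 2147483647)
}

#' @noRd
check_prob_vector <- function(p, what, tol = 1e-12) {
  if (any(!is.finite(p)) || any(p < 0))
    stop(what, " must be a vector of nonnegative probabilities", call. = FALSE)
  if (abs(sum(p) - 1) > tol)
    stop(what, " must sum to 1 (got ", format(sum(p), digits = 15), ")",
         call. = FALSE)
  invisible(p)
}

#' @noRd
check_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(what, " must be TRUE or FALSE", call. = FALSE)
  invisible(x)
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}
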