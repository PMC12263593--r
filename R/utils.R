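#' @importFrom stats .lm.fit cor pnorm pt p.adjust rnorm runif sd setNames
#' @importFrom utils read.table write.table packageVersion
NULL

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `expr`, then restores the caller's
#' RNG state, so seeded generators never perturb the global random stream.
#' A `NULL` seed evaluates `expr` with the current stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("seed must be a single integer")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

# deterministic fan-out of one master seed into per-stage sub-seeds,
# kept below 2^31 so they remain valid R integer seeds
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  offsets <- c(
    simulate = 101L, fc = 211L, select = 307L, similarity = 401L,
    stability = 503L, atlas = 601L, age = 701L, extra = 811L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(master) * 1009 + off) %% 2147483647)
}
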