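# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# round half away from zero (base round() goes to even)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards; keeps all randomness
# funnelled through explicit per-operation seeds
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x) && x >= 0

# Moore-Penrose pseudo-inverse via SVD; used when a log-rank covariance
# matrix is rank-deficient (e.g. a group exhausted before any event)
.pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d, 0)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
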