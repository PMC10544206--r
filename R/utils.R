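# internal helpers

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards
# so package functions never perturb the user's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

# rotate unit vector `dir` away from itself by `theta` radians around an
# azimuth `phi` in the plane orthogonal to `dir`
tilt_dir <- function(dir, theta, phi) {
  dir <- unit(dir)
  # orthonormal basis {e1, e2} of the plane orthogonal to dir
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(ref - sum(ref * dir) * dir)
  e2 <- c(
    dir[2] * e1[3] - dir[3] * e1[2],
    dir[3] * e1[1] - dir[1] * e1[3],
    dir[1] * e1[2] - dir[2] * e1[1]
  )
  unit(cos(theta) * dir + sin(theta) * (cos(phi) * e1 + sin(phi) * e2))
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
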