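## Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Scalar numeric argument check.
checkScalar <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strict && x <= min)
    stop(sprintf("'%s' must be greater than %g", name, min), call. = FALSE)
  if (!strict && x < min)
    stop(sprintf("'%s' must be at least %g", name, min), call. = FALSE)
  invisible(x)
}

## Bilinear interpolation of matrix `m` at fractional indices (xi, yi),
## returning 0 outside the grid. Used by the ray-driven projector. The
## matrix is zero-padded by one cell so all four neighbour lookups become
## unconditional linear indexing; query indices are clamped into the pad.
interpBilinear <- function(m, xi, yi) {
  nx <- nrow(m); ny <- ncol(m)
  mp <- matrix(0, nx + 2L, ny + 2L)
  mp[2:(nx + 1L), 2:(ny + 1L)] <- m
  xi <- pmin(pmax(xi, 0), nx + 1 - 1e-9)
  yi <- pmin(pmax(yi, 0), ny + 1 - 1e-9)
  ix <- floor(xi); iy <- floor(yi)
  fx <- xi - ix;  fy <- yi - iy
  ## padded linear index of the (ix, iy) cell
  i0 <- (ix + 1) + iy * (nx + 2)
  v00 <- mp[i0]
  v10 <- mp[i0 + 1]
  v01 <- mp[i0 + (nx + 2)]
  v11 <- mp[i0 + (nx + 3)]
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}

## Inclusive index range of width `w` centred on (possibly half-integer) `c`.
centerRange <- function(c, w, n) {
  lo <- as.integer(ceiling(c - w / 2))
  hi <- lo + as.integer(w) - 1L
  if (lo < 1L || hi > n) return(NULL)
  c(lo, hi)
}
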