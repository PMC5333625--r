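# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

# Run `expr` under `seed` without disturbing the caller's RNG state.
# seed = NULL means "use the RNG stream as-is".
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

assert_scalar_num <- function(x, name, lower = -Inf, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (x < lower) abort(sprintf("`%s` must be >= %g.", name, lower))
  invisible(x)
}

assert_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < lower) {
    abort(sprintf("`%s` must be an integer >= %d.", name, lower))
  }
  invisible(as.integer(x))
}

assert_df_cols <- function(df, cols, name = deparse(substitute(df))) {
  if (!is.data.frame(df)) abort(sprintf("`%s` must be a data frame.", name))
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing column(s): %s.", name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Bilinear sample of matrix `m` (rows = y, cols = x, 0-based pixel-center
# coordinates) at vectors x, y. Out-of-range queries return `fill`.
bilinear_sample <- function(m, x, y, fill = 0) {
  ny <- nrow(m); nx <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  inside <- x >= 0 & y >= 0 & x <= nx - 1 & y <= ny - 1
  # clamp so corner samples at the exact border still index validly
  x0c <- pmin(pmax(x0, 0), nx - 2L); y0c <- pmin(pmax(y0, 0), ny - 2L)
  fxc <- pmin(pmax(x - x0c, 0), 1); fyc <- pmin(pmax(y - y0c, 0), 1)
  i00 <- cbind(y0c + 1L, x0c + 1L)
  v <- (1 - fyc) * ((1 - fxc) * m[i00] + fxc * m[cbind(y0c + 1L, x0c + 2L)]) +
    fyc * ((1 - fxc) * m[cbind(y0c + 2L, x0c + 1L)] + fxc * m[cbind(y0c + 2L, x0c + 2L)])
  v[!inside] <- fill
  v
}
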