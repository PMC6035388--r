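#' @keywords internal
"_PACKAGE"

## composite trapezoid weights on an arbitrary increasing grid
trapz_weights <- function(t) {
  n <- length(t)
  if (n < 2L) stop("need at least two time points")
  w <- numeric(n)
  dt <- diff(t)
  w[1L] <- dt[1L] / 2
  w[n] <- dt[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (dt[-(n - 1L)] + dt[-1L]) / 2
  w
}

trapz <- function(t, y) sum(trapz_weights(t) * y)

## pixel-center coordinate grids for a mask matrix (0-based, x = col-1, y = row-1)
pixel_coords <- function(dim_yx) {
  list(
    x = matrix(rep(seq_len(dim_yx[2]) - 1, each = dim_yx[1]), dim_yx[1], dim_yx[2]),
    y = matrix(rep(seq_len(dim_yx[1]) - 1, times = dim_yx[2]), dim_yx[1], dim_yx[2])
  )
}

## bilinear interpolation of matrix `im` at 0-based (x, y); NA outside
bilinear <- function(im, x, y) {
  nr <- nrow(im); nc <- ncol(im)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= nc - 2 & y0 <= nr - 2
  ## clamp edge samples that sit exactly on the last row/column
  edge <- (x0 == nc - 1 & fx == 0) | (y0 == nr - 1 & fy == 0)
  ok <- ok | (x >= 0 & y >= 0 & x <= nc - 1 & y <= nr - 1)
  out <- rep(NA_real_, length(x))
  x0c <- pmin(pmax(x0, 0), nc - 2); y0c <- pmin(pmax(y0, 0), nr - 2)
  fxc <- x - x0c; fyc <- y - y0c
  i <- y0c + 1; j <- x0c + 1
  v <- (1 - fxc) * (1 - fyc) * im[cbind(i, j)] +
    fxc * (1 - fyc) * im[cbind(i, j + 1)] +
    (1 - fxc) * fyc * im[cbind(i + 1, j)] +
    fxc * fyc * im[cbind(i + 1, j + 1)]
  out[ok] <- v[ok]
  out
}

## Wald-Wolfowitz runs test on the signs of a numeric vector (zeros dropped).
## Returns two-sided p-value under the normal approximation.
runs_test <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0L || n2 == 0L) return(list(runs = 1L, p.value = if (n > 1) 0 else 1))
  r <- 1L + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (r - mu) / sqrt(v)
  list(runs = r, p.value = 2 * stats::pnorm(-abs(z)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
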