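#' Normalized auto- and cross-correlation of track signals
#'
#' Signals are mean-subtracted per track and correlations normalized by the
#' zero-lag energies, so the autocorrelation equals 1 at lag zero and all
#' values lie in [-1, 1]. A positive peak lag means the second signal lags
#' the first.
#'
#' @param x,y Numeric vectors (set `y = x` or omit for autocorrelation).
#' @param max_lag Maximum lag in frames.
#' @return Data frame with `lag` (-max_lag..max_lag) and `r`.
#' @export
xcorr_norm <- function(x, y = NULL, max_lag = 10L) {
  if (is.null(y)) y <- x
  if (length(x) != length(y)) {
    ## interpolate the shorter onto the longer grid
    n <- max(length(x), length(y))
    x <- stats::approx(seq_along(x), x, n = n)$y
    y <- stats::approx(seq_along(y), y, n = n)$y
  }
  x <- x - mean(x); y <- y - mean(y)
  n <- length(x)
  max_lag <- min(max_lag, n - 1L)
  denom <- sqrt(sum(x^2) * sum(y^2))
  r <- vapply(-max_lag:max_lag, function(l) {
    if (l >= 0) sum(x[1:(n - l)] * y[(1 + l):n]) else
      sum(x[(1 - l):n] * y[1:(n + l)])
  }, 0)
  if (denom == 0) r[] <- 0 else r <- r / denom
  data.frame(lag = -max_lag:max_lag, r = r)
}

#' Cohort correlation analysis over tracks
#'
#' Computes per-track normalized correlations for a named signal pair and
#' aggregates the cohort mean with a 95 percent confidence interval per lag.
#' Tracks shorter than `max_lag + 2` frames contribute truncated lags only.
#'
#' @param tracks A [track_cells()] result (or any list of data frames).
#' @param signal_x,signal_y Column names; `signal_y = NULL` gives the
#'   autocorrelation of `signal_x`.
#' @param max_lag Maximum lag in frames.
#' @param derivative Differentiate the signals (central differences) before
#'   correlating, the convention for change-vs-change coupling analyses.
#' @return List with `per_track` (lag x track matrix), `mean`, `ci_low`,
#'   `ci_high`, `lags`.
#' @export
correlate_tracks <- function(tracks, signal_x, signal_y = NULL, max_lag = 10L,
                             derivative = FALSE) {
  get_sig <- function(tr, nm) {
    v <- tr[[nm]]
    if (derivative) v <- central_diff(v)
    v
  }
  res <- lapply(tracks, function(tr) {
    if (nrow(tr) < max_lag + 2L) return(NULL)
    x <- get_sig(tr, signal_x)
    y <- if (is.null(signal_y)) NULL else get_sig(tr, signal_y)
    xcorr_norm(x, y, max_lag)$r
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0L) stop("no track long enough for the requested lags")
  m <- do.call(cbind, res)
  lags <- -max_lag:max_lag
  mu <- rowMeans(m)
  se <- apply(m, 1, stats::sd) / sqrt(ncol(m))
  list(per_track = m, lags = lags, mean = mu,
       ci_low = mu - 1.96 * se, ci_high = mu + 1.96 * se)
}

## central differences, same length as input (one-sided at the ends)
central_diff <- function(v) {
  n <- length(v)
  if (n < 3L) return(diff(c(v[1], v)))
  c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1])
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson correlations between static per-cell quantities (e.g.
#' import and export rates versus nuclear morphology), with two-sided
#' p-values from the t-distribution test of zero correlation.
#'
#' @param df Data frame of numeric columns (one row per cell).
#' @return List with matrices `r` and `p`.
#' @export
pearson_matrix <- function(df) {
  df <- df[vapply(df, is.numeric, TRUE)]
  k <- ncol(df)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(names(df), names(df)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(df[[i]], df[[j]])
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    ct <- stats::cor.test(df[[i]][ok], df[[j]][ok], method = "pearson")
    r[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
  }
  list(r = r, p = p)
}
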