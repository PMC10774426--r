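## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## maximal runs of TRUE in a logical vector -> data.frame(start, end) (indices,
## inclusive); NA counts as FALSE
runs_true <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

## trapezoidal integral of y over x (x increasing, same length)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (is.character(x) || is.factor(x)) {
    y <- sub("Z$", "", as.character(x))
    out <- as.POSIXct(strptime(y, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
    alt <- as.POSIXct(strptime(y, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
    out[is.na(out)] <- alt[is.na(out)]
    return(out)
  }
  as.POSIXct(x, tz = "UTC")
}

## linear interpolation of the time at which y first crosses level `lev`
## going upward, scanning samples i..j; returns NA if never crossed
first_upcross <- function(t, y, lev, i = 1L, j = length(y)) {
  idx <- seq.int(i, j)
  yy <- y[idx]
  tt <- t[idx]
  above <- which(yy >= lev)
  if (!length(above)) return(NA_real_)
  a <- above[1L]
  if (a == 1L) return(as.numeric(tt[1L]))
  y0 <- yy[a - 1L]; y1 <- yy[a]
  t0 <- as.numeric(tt[a - 1L]); t1 <- as.numeric(tt[a])
  if (!is.finite(y0) || y1 == y0) return(t1)
  t0 + (lev - y0) / (y1 - y0) * (t1 - t0)
}

## duration helper: seconds between two POSIXct
secs <- function(a, b) as.numeric(difftime(b, a, units = "secs"))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
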