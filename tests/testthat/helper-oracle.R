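# Independent straightforward re-implementations used as oracles in the
# property tests. Deliberately naive (scalar loops, no shared code with the
# package internals).

oracle_metrics <- function(m, o, c_ioa = 2) {
  n <- length(m)
  d <- numeric(n); ad <- numeric(n); sq <- numeric(n); in2 <- logical(n)
  for (i in seq_len(n)) {
    d[i] <- m[i] - o[i]
    ad[i] <- abs(d[i])
    sq[i] <- d[i]^2
    in2[i] <- o[i] > 0 && m[i] / o[i] >= 0.5 && m[i] / o[i] <= 2.0
  }
  obar <- sum(o) / n
  dev <- 0
  for (i in seq_len(n)) dev <- dev + abs(o[i] - obar)
  a <- sum(ad); b <- c_ioa * dev
  list(
    fac2 = sum(in2) / n,
    mb = sum(d) / n,
    mge = sum(ad) / n,
    nmb = sum(d) / sum(o),
    nmge = sum(ad) / sum(o),
    rmse = sqrt(sum(sq) / n),
    r = stats::cor(m, o),
    ioa = if (a <= b) 1 - a / b else b / a - 1)
}

oracle_ra <- function(lat, doy) {
  phi <- lat * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi / 365 * doy)
  dec <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  x <- -tan(phi) * tan(dec)
  if (x > 1) x <- 1
  if (x < -1) x <- -1
  ws <- acos(x)
  1440 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
}

oracle_es <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))

random_series_pair <- function(n = 12) {
  o <- runif(n, 0.5, 6)
  m <- pmax(o + rnorm(n, 0, 1), 0.01)
  list(m = m, o = o)
}

withr_local_tempfile <- function(ext, env = parent.frame()) {
  path <- tempfile(fileext = ext)
  withr::defer(unlink(path), envir = env)
  path
}
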