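# Shared fixtures: a compact phantom specification for unit tests (smaller
# grid than the default study conditions, same anatomy), and a cache so
# expensive registrations are computed once per test run.

tiny_spec <- function(...) {
  phantom_spec(
    shape = c(36L, 36L, 120L), resolution = 1.0,
    rootlet_z = c(`2` = 100, `3` = 87, `4` = 74, `5` = 61, `6` = 48,
                  `7` = 36, `8` = 24),
    disc_z = c(`3` = 94, `4` = 81, `5` = 68, `6` = 55, `7` = 42,
               `8` = 30),
    enlargement_z = 54,
    cord_z_range = c(6, 112),
    ...
  )
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_template <- function() cached("tiny_template", phantom_template(tiny_spec()))

# default-conditions template (the acceptance-scale bundle)
full_template <- function() cached("full_template", phantom_template())

# brute-force center of mass of one label, in world mm
brute_com <- function(labels, code) {
  idx <- which(labels$data == code, arr.ind = TRUE) - 1
  w <- vox_to_world(labels$affine, idx)
  colMeans(w)
}

# independent Fritsch-Carlson monotone cubic interpolant (test oracle for
# the landmark mapping; written from the published scheme, not via
# splinefun)
fc_monotone_eval <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  delta <- diff(y) / h
  m <- numeric(n)
  m[1] <- delta[1]; m[n] <- delta[n - 1]
  for (i in 2:(n - 1)) {
    m[i] <- if (delta[i - 1] * delta[i] <= 0) 0
            else (delta[i - 1] + delta[i]) / 2
  }
  for (i in seq_len(n - 1)) {
    if (delta[i] == 0) { m[i] <- 0; m[i + 1] <- 0; next }
    a <- m[i] / delta[i]; b <- m[i + 1] / delta[i]
    r <- a^2 + b^2
    if (r > 9) {
      t <- 3 / sqrt(r)
      m[i] <- t * a * delta[i]
      m[i + 1] <- t * b * delta[i]
    }
  }
  vapply(xout, function(xx) {
    if (xx <= x[1]) return(y[1] + m[1] * (xx - x[1]))
    if (xx >= x[n]) return(y[n] + m[n] * (xx - x[n]))
    i <- findInterval(xx, x)
    t <- (xx - x[i]) / h[i]
    h00 <- 2 * t^3 - 3 * t^2 + 1
    h10 <- t^3 - 2 * t^2 + t
    h01 <- -2 * t^3 + 3 * t^2
    h11 <- t^3 - t^2
    h00 * y[i] + h10 * h[i] * m[i] + h01 * y[i + 1] + h11 * h[i] * m[i + 1]
  }, numeric(1))
}

# smooth random z-only field from a few random sine components, bounded by
# `amplitude` mm, on the given grid
random_smooth_zfield <- function(grid, amplitude, seed) {
  g <- grid_of(grid)
  Z <- slice_z_world(g)
  set.seed(seed)
  ncomp <- 3L
  per <- runif(ncomp, 35, 90)
  pha <- runif(ncomp, 0, 2 * pi)
  amp <- runif(ncomp)
  prof <- rowSums(vapply(seq_len(ncomp), function(i)
    amp[i] * sin(2 * pi * Z / per[i] + pha[i]), numeric(length(Z))))
  prof <- prof / max(abs(prof)) * amplitude
  f <- zero_field(g)
  f$vectors[, , , 3] <- rep(prof, each = g$shape[1] * g$shape[2])
  f
}
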