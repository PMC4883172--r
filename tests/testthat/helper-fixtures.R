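# Shared fixtures, built in code at test time.

# small two-channel recording with a deterministic shape
fixture_recording <- function(n = 1000, rate = 500) {
  t <- (seq_len(n) - 1) / rate
  eeg_recording(
    cbind(T4 = 10 * sin(2 * pi * 3 * t), F8 = 5 * cos(2 * pi * 5 * t)),
    rate = rate
  )
}

# clean 100 Hz trace with V-shaped transients planted at known vertices
fixture_planted_trace <- function(n = 3000, rate = 100, depth = 60,
                                  vertices = c(500, 1000, 1500, 2000, 2500),
                                  noise_sd = 2, seed = 42) {
  withr::with_seed(seed, {
    x <- rnorm(n, sd = noise_sd)
    for (v in vertices) {
      tpl <- spike_template(depth, depth, 50, 50, rate)
      idx <- v - tpl$vertex_offset + seq_along(tpl$wave) - 1L
      x[idx] <- x[idx] + tpl$wave
    }
    list(x = x, vertices = vertices, rate = rate)
  })
}

# brute-force maximum-cardinality matching by full enumeration (n <= 10)
brute_force_match <- function(detections, markers, latency = 50) {
  lat_s <- latency / 1000
  nd <- length(detections); nm <- length(markers)
  if (!nd || !nm) return(0L)
  compat <- abs(outer(detections, markers, "-")) <= lat_s + 1e-12
  best <- 0L
  recurse <- function(i, used_m, count) {
    if (count + (nd - i + 1) <= best) return()
    if (i > nd) {
      best <<- max(best, count)
      return()
    }
    recurse(i + 1, used_m, count)        # leave detection i unmatched
    for (j in which(compat[i, ] & !used_m)) {
      used_m[j] <- TRUE
      recurse(i + 1, used_m, count + 1L)
      used_m[j] <- FALSE
    }
  }
  recurse(1L, logical(nm), 0L)
  best
}

# dense generalized eigendecomposition oracle for the LPP pencil,
# solved directly with eigen() on solve(B) %*% G
dense_gev_oracle <- function(G, B) {
  M <- solve(B, G)
  e <- eigen(M)
  ord <- order(Re(e$values))
  list(values = Re(e$values)[ord], vectors = Re(e$vectors)[, ord, drop = FALSE])
}
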