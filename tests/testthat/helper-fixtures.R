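# Shared fixtures built in code.

# Small deterministic cube with known values.
tiny_cube <- function(nl = 5, ns = 5, nb = 3, seed = 1) {
  withr::with_seed(seed, {
    spectral_cube(array(runif(nl * ns * nb), dim = c(nl, ns, nb)),
                  wavelengths = seq(500, by = 50, length.out = nb))
  })
}

# The 50-band planted dataset used throughout the selection tests.
planted_50 <- function(seed = 42) {
  spec <- planted_band_spec(
    informative_band_indices = c(5L, 12L, 20L, 31L, 44L),
    coefficients = c(2, -3, 2.5, 1.5, -2),
    noise_sd = 0.05, n_samples = 200L, n_bands = 50L, seed = seed)
  c(gen_spectra(spec), list(planted = spec$informative_band_indices))
}

# Independent NIPALS PLS1 oracle (deliberately a different algorithm from
# the package's SIMPLS implementation).
nipals_pls1_predict <- function(x, y, ncomp, newdata) {
  x <- as.matrix(x)
  xm <- colMeans(x); ym <- mean(y)
  E <- sweep(x, 2, xm); f <- y - ym
  W <- NULL; P <- NULL; qs <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f); w <- w / sqrt(sum(w^2))
    t <- E %*% w
    p <- crossprod(E, t) / sum(t^2)
    q <- sum(f * t) / sum(t^2)
    E <- E - t %*% t(p)
    f <- f - q * t
    W <- cbind(W, w); P <- cbind(P, p); qs[a] <- q
  }
  B <- W %*% solve(t(P) %*% W, qs)
  as.vector(sweep(as.matrix(newdata), 2, xm) %*% B) + ym
}
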