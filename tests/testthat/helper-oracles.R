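# Independent oracles and small fixtures used across the suite.

# NIPALS PLS1 with explicit X and y deflation: the reference implementation
# the kernel-algorithm fit is checked against.
nipals_pls1 <- function(X, y, a) {
  Xd <- sweep(X, 2L, colMeans(X))
  my <- mean(y)
  yd <- y - my
  n <- nrow(X); p <- ncol(X)
  T <- matrix(0, n, a); P <- matrix(0, p, a); W <- matrix(0, p, a)
  q <- numeric(a)
  for (k in seq_len(a)) {
    w <- drop(crossprod(Xd, yd))
    w <- w / sqrt(sum(w^2))
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    p_k <- drop(crossprod(Xd, t)) / tt
    q[k] <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, p_k)
    yd <- yd - t * q[k]
    T[, k] <- t; P[, k] <- p_k; W[, k] <- w
  }
  fitted <- sapply(seq_len(a), function(k)
    my + T[, seq_len(k), drop = FALSE] %*% q[seq_len(k)])
  list(T = T, P = P, W = W, q = q, fitted = matrix(fitted, ncol = a))
}

# brute-force balanced two-way ANOVA from explicit cell sums
brute_anova <- function(values, tissue, age) {
  tissue <- factor(tissue); age <- factor(age)
  gm <- mean(values)
  mt <- tapply(values, tissue, mean)
  ma <- tapply(values, age, mean)
  mc <- tapply(values, list(tissue, age), mean)
  nt <- table(tissue); na <- table(age); nc <- table(tissue, age)
  ss_t <- sum(nt * (mt - gm)^2)
  ss_a <- sum(na * (ma - gm)^2)
  ss_c <- sum(nc * (mc - outer(mt - gm, ma - gm, `+`) - gm)^2)
  ss_r <- sum((values - mc[cbind(tissue, age)])^2)
  df_t <- nlevels(tissue) - 1L
  df_a <- nlevels(age) - 1L
  df_c <- df_t * df_a
  df_r <- length(values) - nlevels(tissue) * nlevels(age)
  ms <- c(ss_t / df_t, ss_a / df_a, ss_c / df_c, ss_r / df_r)
  f <- ms[1:3] / ms[4]
  data.frame(effect = c("tissue", "age", "tissue:age", "residual"),
             sum_sq = c(ss_t, ss_a, ss_c, ss_r),
             df = c(df_t, df_a, df_c, df_r),
             mean_sq = ms,
             F = c(f, NA),
             p = c(stats::pf(f, c(df_t, df_a, df_c), df_r,
                             lower.tail = FALSE), NA))
}

# tiny cohort: coarse grid and few animals, for fast structural tests
small_config <- function(..., seed = 11L) {
  args <- utils::modifyList(list(grid_step = 4, n_bio = 3L, n_tech = 2L,
                                 seed = seed), list(...))
  do.call(cohort_config, args)
}

noise_free <- function(cfg) {
  cfg$noise_sd <- 0
  cfg$scale_jitter_sd <- 0
  cfg$bio_amplitude_sd <- 0
  cfg$baseline_coeffs_sd <- c(0, 0, 0)
  cfg
}

# deterministic single-band spectrum on a uniform grid
gaussian_spectrum <- function(a = 1, center = 1650, sigma = 10,
                              lo = 1500, hi = 1800, step = 2,
                              baseline = function(x) 0,
                              meta = list(sample_id = "g1",
                                          tissue = "cardiac",
                                          age_months = 6, bio_rep = 1,
                                          tech_rep = 1)) {
  x <- seq(lo, hi, by = step)
  ftir_spectrum(x, a * exp(-(x - center)^2 / (2 * sigma^2)) + baseline(x),
                meta)
}

meta_n <- function(i, tissue = "cardiac", age = 6) {
  list(sample_id = paste0("s", i), tissue = tissue, age_months = age,
       bio_rep = ((i - 1L) %% 10L) + 1L, tech_rep = ((i - 1L) %/% 10L) %% 3L + 1L)
}
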