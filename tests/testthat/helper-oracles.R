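# Independent oracles used by the tests. Each is written directly from
# the defining formula or by exhaustive enumeration, separately from the
# package implementation it checks.

# Tajima's D by exhaustive enumeration of all C(n, 2) sequence pairs.
oracle_tajima <- function(hap) {
  n <- nrow(hap)
  segregating <- apply(hap, 2, function(col) {
    k <- sum(col)
    k > 0 && k < n
  })
  s <- sum(segregating)
  pairs <- utils::combn(n, 2)
  diffs <- apply(pairs, 2, function(ij)
    sum(hap[ij[1], ] != hap[ij[2], ]))
  pi <- mean(diffs)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  d <- if (s == 0) NA_real_ else
    (pi - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
  list(s = s, pi = pi, d = d)
}

# Weir & Cockerham (1984) theta-hat, transcribed term by term for two
# populations from genotype dosages.
oracle_wc_fst <- function(dosages, labels) {
  gs <- split(dosages, labels)
  gs <- lapply(gs, function(x) x[!is.na(x)])
  r <- length(gs)
  n_i <- sapply(gs, length)
  p_i <- sapply(gs, function(x) mean(x) / 2)
  h_i <- sapply(gs, function(x) mean(x == 1))
  n_bar <- mean(n_i)
  n_c <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  p_bar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / sum(n_i)
  a <- (n_bar / n_c) * (s2 - (p_bar * (1 - p_bar) -
                                s2 * (r - 1) / r - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) * (p_bar * (1 - p_bar) -
                                  s2 * (r - 1) / r -
                                  h_bar * (2 * n_bar - 1) / (4 * n_bar))
  cc <- h_bar / 2
  a / (a + b + cc)
}

# Plain Hudson Fst from group allele frequencies.
oracle_hudson_fst <- function(p1, p2) {
  p1 <- unname(p1); p2 <- unname(p2)
  hw <- p1 * (1 - p1) + p2 * (1 - p2)
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  1 - hw / hb
}

# Two-locus genotype log-likelihood as a function of the alt-alt
# haplotype frequency, with allele frequencies fixed at their observed
# (MLE) values; maximised by grid search plus local refinement.
oracle_ld_haplotype_freq <- function(da, db) {
  ok <- !is.na(da) & !is.na(db)
  da <- da[ok]; db <- db[ok]
  n <- length(da)
  pa <- sum(da) / (2 * n); pb <- sum(db) / (2 * n)
  haps <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  loglik <- function(p11) {
    h <- c(p11, pa - p11, pb - p11, 1 - pa - pb + p11)
    if (any(h < -1e-12)) return(-Inf)
    h <- pmax(h, 0)
    ll <- 0
    for (i in seq_len(n)) {
      p <- 0
      for (x in 1:4) for (y in 1:4) {
        if (haps[x, 1] + haps[y, 1] == da[i] &&
            haps[x, 2] + haps[y, 2] == db[i])
          p <- p + h[x] * h[y]
      }
      if (p <= 0) return(-Inf)
      ll <- ll + log(p)
    }
    ll
  }
  lo <- max(0, pa + pb - 1); hi <- min(pa, pb)
  grid <- seq(lo, hi, length.out = 2001)
  vals <- vapply(grid, loglik, numeric(1))
  best <- grid[which.max(vals)]
  opt <- stats::optimize(loglik, lower = max(lo, best - 2e-3),
                         upper = min(hi, best + 2e-3), maximum = TRUE,
                         tol = 1e-10)
  opt$maximum
}

# OLS by the normal equations, with classical standard errors.
oracle_ols <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- unname(sqrt(diag(xtx_inv) * sigma2))
  t_stat <- as.numeric(beta) / se
  list(beta = as.numeric(beta), se = se, t_stat = unname(t_stat),
       p = unname(2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)))
}

# Small clean-panel cohort spec: unlinked SNPs relocated outside the
# block spans so the contiguous-run rule can recover both blocks whole.
clean_panel_spec <- function(seed = 1L, ...) {
  u <- default_unlinked_snps()
  u$pos <- c(3590000, 3591000, 3610000, 3571000, 3580000, 3581000)
  cohort_spec(seed = seed, unlinked_snps = u, ...)
}

# Single-ancestry balanced-sex spec used in effect-recovery simulations.
recovery_spec <- function(seed, n_per_sex = 100L, effect_rsp = -100,
                          hap_freq = 0.5) {
  cohort_spec(
    groups = data.frame(ancestry = "SYN", sex = c("M", "F"),
                        n = c(n_per_sex, n_per_sex),
                        stringsAsFactors = FALSE),
    blocks = default_blocks()["H2"],
    haplotype_freqs = list(H2 = list(
      SYN = c(a = 1 - hap_freq, b = hap_freq))),
    biva_model = list(
      SYN_M = list(mean = c(rsp = 370, xcsp = 45), sds = c(60, 7),
                   corr = 0.7),
      SYN_F = list(mean = c(rsp = 470, xcsp = 50), sds = c(80, 9),
                   corr = 0.7)),
    effect = list(block = "H2", hap = "b", sex = "F",
                  per_copy = c(rsp = effect_rsp, xcsp = 0)),
    unlinked_snps = NULL,
    seed = seed)
}

# Random 0/1 haplotype matrix with at least one segregating site.
random_hap_matrix <- function(n, s_max = 10) {
  repeat {
    s <- sample(s_max, 1)
    m <- matrix(rbinom(n * s, 1, runif(1, 0.2, 0.8)), n, s)
    k <- colSums(m)
    if (any(k > 0 & k < n)) return(m)
  }
}
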