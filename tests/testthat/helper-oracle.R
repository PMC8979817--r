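# Independent direct-formula oracle for the beta-binomial Wald test.
# Written as plain scalar loops, before and independently of the
# package's vectorized implementation; the two must agree to 1e-10.
oracle_bb_wald <- function(meth_a, tot_a, meth_b, tot_b,
                           stratum = rep("all", nrow(meth_a)),
                           prior_weight = 20) {
  n <- nrow(meth_a)
  mu_a <- mu_b <- phi_raw <- numeric(n)
  n_use <- integer(n)
  testable <- logical(n)
  for (i in seq_len(n)) {
    ma <- meth_a[i, ]; ta <- tot_a[i, ]
    mb <- meth_b[i, ]; tb <- tot_b[i, ]
    Ta <- sum(ta); Tb <- sum(tb)
    mu_a[i] <- if (Ta > 0) sum(ma) / Ta else NA_real_
    mu_b[i] <- if (Tb > 0) sum(mb) / Tb else NA_real_
    testable[i] <- sum(ta >= 1) >= 2 && sum(tb >= 1) >= 2
    n_use[i] <- sum(ta >= 1) + sum(tb >= 1)
    phis <- numeric(0)
    for (g in 1:2) {
      m <- if (g == 1) ma else mb
      t <- if (g == 1) ta else tb
      mu <- if (g == 1) mu_a[i] else mu_b[i]
      v <- mu * (1 - mu)
      for (k in seq_along(t)) {
        if (t[k] >= 2 && !is.na(v) && v > 0) {
          b <- m[k] / t[k]
          r <- (b - mu)^2 / v
          phis <- c(phis, (r - 1 / t[k]) / (1 - 1 / t[k]))
        }
      }
    }
    phi_raw[i] <- if (length(phis))
      min(max(mean(phis), 0), 0.99) else NA_real_
  }
  global_med <- stats::median(phi_raw[testable], na.rm = TRUE)
  if (!is.finite(global_med)) global_med <- 0
  phi <- wald <- p <- d <- numeric(n)
  for (i in seq_len(n)) {
    med <- stats::median(phi_raw[testable & stratum == stratum[i]],
                         na.rm = TRUE)
    if (!is.finite(med)) med <- global_med
    phi[i] <- if (is.na(phi_raw[i])) med else
      (n_use[i] * phi_raw[i] + prior_weight * med) /
        (n_use[i] + prior_weight)
    phi[i] <- min(max(phi[i], 1e-6), 0.99)
    var_g <- function(m, t, mu) {
      T <- sum(t)
      if (T == 0) return(NA_real_)
      v <- mu * (1 - mu)
      acc <- 0
      for (k in seq_along(t))
        acc <- acc + t[k] * v * (1 + (t[k] - 1) * phi[i])
      acc / T^2
    }
    va <- var_g(meth_a[i, ], tot_a[i, ], mu_a[i])
    vb <- var_g(meth_b[i, ], tot_b[i, ], mu_b[i])
    se <- sqrt(va + vb)
    d[i] <- mu_b[i] - mu_a[i]
    wald[i] <- if (is.na(se)) NA_real_
      else if (se > 0) d[i] / se
      else if (d[i] == 0) 0 else sign(d[i]) * Inf
    p[i] <- 2 * stats::pnorm(-abs(wald[i]))
  }
  data.frame(mu_a = mu_a, mu_b = mu_b, diff = d, phi = phi,
             wald = wald, p = p, testable = testable)
}

# Brute-force all-pairs interval overlap on 0-based half-open tables
brute_overlap_flags <- function(regions, features, min_bp = 1) {
  vapply(seq_len(nrow(regions)), function(i) {
    any(features$chrom == regions$chrom[i] &
          pmin(features$end, regions$end[i]) -
          pmax(features$start, regions$start[i]) >= min_bp)
  }, logical(1))
}

# Brute-force per-bp state assignment: walk every base of the region,
# look up its state, pick the label with the most bases (ties to the
# lowest state index in `levels`)
brute_state_assignment <- function(regions, states, levels) {
  vapply(seq_len(nrow(regions)), function(i) {
    bases <- seq.int(regions$start[i], regions$end[i] - 1)
    labs <- rep(NA_character_, length(bases))
    for (k in seq_len(nrow(states))) {
      if (states$chrom[k] != regions$chrom[i]) next
      inside <- bases >= states$start[k] & bases < states$end[k]
      labs[inside] <- states$label[k]
    }
    labs <- labs[!is.na(labs)]
    if (!length(labs)) return(NA_character_)
    cnt <- table(labs)
    best <- names(cnt)[cnt == max(cnt)]
    best[order(match(best, levels))][1]
  }, character(1))
}

# random small interval table
random_regions <- function(n, chroms = c("chrA", "chrB"), span = 10000,
                           max_len = 400) {
  start <- sample.int(span, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  df <- data.frame(chrom = sample(chroms, n, replace = TRUE),
                   start = start, end = start + len,
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start), , drop = FALSE]
}
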