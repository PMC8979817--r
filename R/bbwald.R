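#' Beta-binomial Wald test on pooled methylation proportions
#'
#' The workhorse shared by the CpG-level and region-level stages. For
#' each unit (a CpG, or a region with per-sample aggregated counts) the
#' two group means are estimated as pooled proportions
#' `mu_g = sum(n_meth) / sum(n_total)`; the overdispersion `phi` of the
#' beta-binomial count model is estimated by method of moments on the
#' squared beta residuals and shrunk toward the stratum-wide median with
#' data weight equal to the number of usable samples and a fixed prior
#' weight; the Wald statistic is `(mu_b - mu_a) / SE` with
#' `SE^2 = sum_g v_g * (T_g + phi * (S_g - T_g)) / T_g^2`, where
#' `v_g = mu_g (1 - mu_g)`, `T_g = sum(n_total)` and `S_g = sum(n_total^2)`
#' over the samples of group g (the exact variance of the pooled
#' estimator under a shared beta-binomial dispersion). Two-sided p-values
#' come from the standard normal.
#'
#' Under the beta-binomial model a sample with total t has
#' `Var(beta) = v * ((1 - phi)/t + phi)`, so each squared standardized
#' residual yields the moment estimate
#' `phi_i = (r_i - 1/t_i) / (1 - 1/t_i)`; these are averaged over samples
#' with `t >= 2` in both groups and clamped to `[0, 0.99]`.
#'
#' A unit is testable when both groups have at least two samples with
#' `n_total >= 1`. Degenerate `SE = 0` with a non-zero difference (one
#' group all unmethylated, the other fully methylated) yields an
#' infinite statistic and p = 0; `SE = 0` with zero difference yields
#' statistic 0 and p = 1.
#'
#' @param meth_a,tot_a,meth_b,tot_b numeric matrices (units x samples)
#'   of methylated and total counts for the two groups.
#' @param stratum factor/character of length units; the dispersion
#'   median is computed within each stratum (chromosomes at the CpG
#'   stage, a single stratum at the region stage).
#' @param prior_weight weight of the median-dispersion prior in the
#'   shrinkage (default 20 pseudo-samples).
#' @return A `data.table` with columns `n_a`, `n_b` (usable samples),
#'   `mu_a`, `mu_b`, `diff`, `phi_raw`, `phi`, `se`, `wald`, `p`,
#'   `testable`, plus pooled sums `m_a`, `t_a`, `m_b`, `t_b`.
#' @export
bb_wald <- function(meth_a, tot_a, meth_b, tot_b,
                    stratum = rep("all", nrow(as.matrix(meth_a))),
                    prior_weight = 20) {
  meth_a <- as.matrix(meth_a); tot_a <- as.matrix(tot_a)
  meth_b <- as.matrix(meth_b); tot_b <- as.matrix(tot_b)
  n_units <- nrow(meth_a)

  T_a <- rowSums(tot_a); M_a <- rowSums(meth_a)
  T_b <- rowSums(tot_b); M_b <- rowSums(meth_b)
  mu_a <- ifelse(T_a > 0, M_a / T_a, NA_real_)
  mu_b <- ifelse(T_b > 0, M_b / T_b, NA_real_)
  n_a <- rowSums(tot_a >= 1)
  n_b <- rowSums(tot_b >= 1)
  testable <- n_a >= 2 & n_b >= 2

  phi_piece <- function(meth, tot, mu) {
    v <- mu * (1 - mu)
    use <- tot >= 2 & !is.na(v) & v > 0
    b <- ifelse(tot > 0, meth / tot, NA_real_)
    r <- (b - mu)^2 / v
    phi_i <- (r - 1 / tot) / (1 - 1 / tot)
    phi_i[!use] <- NA_real_
    list(sum = rowSums(phi_i, na.rm = TRUE), n = rowSums(use))
  }
  pa <- phi_piece(meth_a, tot_a, mu_a)
  pb <- phi_piece(meth_b, tot_b, mu_b)
  n_phi <- pa$n + pb$n
  phi_raw <- ifelse(n_phi > 0, (pa$sum + pb$sum) / n_phi, NA_real_)
  phi_raw <- pmin(pmax(phi_raw, 0), 0.99)

  stratum <- as.character(stratum)
  med_by <- tapply(phi_raw[testable], stratum[testable],
                   median, na.rm = TRUE)
  global_med <- median(phi_raw[testable], na.rm = TRUE)
  if (!is.finite(global_med)) global_med <- 0
  phi_med <- unname(med_by[stratum])
  phi_med[!is.finite(phi_med)] <- global_med

  n_use <- n_a + n_b
  phi <- ifelse(is.na(phi_raw), phi_med,
                (n_use * phi_raw + prior_weight * phi_med) /
                  (n_use + prior_weight))
  phi <- pmin(pmax(phi, 1e-6), 0.99)

  v_a <- mu_a * (1 - mu_a); v_b <- mu_b * (1 - mu_b)
  S_a <- rowSums(tot_a^2); S_b <- rowSums(tot_b^2)
  var_a <- ifelse(T_a > 0, v_a * (T_a + phi * (S_a - T_a)) / T_a^2, NA_real_)
  var_b <- ifelse(T_b > 0, v_b * (T_b + phi * (S_b - T_b)) / T_b^2, NA_real_)
  se <- sqrt(var_a + var_b)
  diff <- mu_b - mu_a

  wald <- ifelse(se > 0, diff / se,
                 ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- 2 * pnorm(-abs(wald))

  data.table::data.table(
    n_a = n_a, n_b = n_b, mu_a = mu_a, mu_b = mu_b, diff = diff,
    phi_raw = phi_raw, phi = phi, se = se, wald = wald, p = p,
    testable = testable,
    m_a = M_a, t_a = T_a, m_b = M_b, t_b = T_b)
}
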