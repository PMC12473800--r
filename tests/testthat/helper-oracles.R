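# Independent oracles, written against the definitions rather than the
# package implementation, used to cross-check the computational kernels.

# Exact two-sided rank-sum p-value by full enumeration of all group
# assignments (tie-free data). Statistic: rank sum of the first group.
oracle_rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  all_w <- apply(utils::combn(n1 + n2, n1), 2, function(ii) sum(r[ii]))
  # symmetric null: two-sided p doubles the smaller tail, capped at 1
  p_low <- mean(all_w <= w_obs)
  p_high <- mean(all_w >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# SRI by direct transliteration of its definition: n_i averaged over the
# two orderings, W = sum(n_i) / sum of positions, SRI = W / S * 100.
oracle_sri <- function(cf_rank, igeo_rank = cf_rank) {
  s <- length(cf_rank)
  total_n <- 0
  for (i in seq_len(s)) total_n <- total_n + (cf_rank[i] + igeo_rank[i]) / 2
  denom <- 0
  for (i in seq_len(s)) denom <- denom + i
  w <- total_n / denom
  w / s * 100
}

# Geometric mean via the log-mean route (explicit loop, no exp/mean
# composition shared with the implementation).
oracle_geomean <- function(v) {
  acc <- 0
  for (x in v) acc <- acc + log(x)
  exp(acc / length(v))
}

# Single-expression chronic daily dose oracles (mg/kg/day).
oracle_cdd_ing <- function(cm, IR, ED, EF, ABW, AET, CFU) {
  (cm * IR * ED * EF * CFU) / (ABW * AET)
}
oracle_cdd_inh <- function(cm, IHR, ED, EF, ABW, AET, PEF) {
  (cm * IHR * ED * EF) / (ABW * AET * PEF)
}
oracle_cdd_derm <- function(cm, SA, SAF, DAF, ED, EF, ABW, AET, CFU) {
  (cm * SA * SAF * DAF * ED * EF * CFU) / (ABW * AET)
}

# Build an exposure_profile-shaped list with arbitrary parameter values
# (fields mirror the package's profile contract).
make_profile <- function(ABW, IR, IHR, SA, SAF, ED, EF_days, AET_nc,
                         AET_ca, PEF, CFU, daf = c(default = 0.001)) {
  structure(list(ABW = ABW, IR = IR, IHR = IHR, SA = SA, SAF = SAF,
                 ED = ED, EF_days = EF_days, AET_nc = AET_nc,
                 AET_ca = AET_ca, PEF = PEF, CFU = CFU,
                 receptor = "test", DAF = daf),
            class = "exposure_profile")
}

random_profile <- function() {
  ed <- runif(1, 1, 60)
  make_profile(ABW = runif(1, 10, 90), IR = runif(1, 50, 300),
               IHR = runif(1, 5, 25), SA = runif(1, 1000, 8000),
               SAF = runif(1, 0.01, 0.5), ED = ed,
               EF_days = runif(1, 100, 365), AET_nc = ed * 365,
               AET_ca = runif(1, ed, 80) * 365, PEF = runif(1, 1e8, 1e10),
               CFU = 1e-6,
               daf = c(As = runif(1, 0.001, 0.1), default = 0.001))
}

# All permutations of 1..n as rows of a matrix (recursive construction).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  unname(out)
}

# Small two-zone sample table with hand-enterable values.
toy_samples <- function() {
  tibble::tibble(
    site = rep(c("U1", "U2", "L1", "L2"), each = 2),
    zone = rep(c("upper", "upper", "lower", "lower"), each = 2),
    month = rep(c("February", "March"), 4),
    replicate = 1L,
    As = c(1.5, 2.5, 2.0, 3.0, 10, 14, 20, 26),
    Cd = c(0.1, 0.1, 0.2, 0.2, 0.3, 0.5, 0.6, 0.8),
    Pb = c(10, 14, 8, 12, 20, 28, 30, 38),
    Zn = c(30, 50, 40, 60, 90, 110, 120, 140),
    Fe = c(9000, 9400, 8800, 9200, 9800, 10200, 10400, 10800))
}
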