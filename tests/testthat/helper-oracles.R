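# Independent oracles and small fixture builders shared across tests.

# Quick abund builder from a numeric matrix (auto ids when unnamed).
tiny_abund <- function(values, stage = "raw") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("m%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  abund(values, stage = stage)
}

# Minimal metadata tibble for a set of sample ids.
tiny_meta <- function(sample_id, group, run_day = "day1",
                      gestational_age = NA_real_, storage = NA_real_,
                      maternal_age = NA_real_, ethnicity = NA_character_,
                      smoker = NA, replicate_group = NA_character_) {
  tibble::tibble(sample_id = sample_id, group = group,
                 gestational_age = gestational_age, run_day = run_day,
                 storage_time_months = storage, maternal_age = maternal_age,
                 ethnicity = ethnicity, smoker = smoker,
                 replicate_group = replicate_group)
}

# Exact two-sided Mann-Whitney p by brute-force enumeration of all
# C(n1+n2, n1) assignments of the pooled (tie-free) values to group A.
mw_enumeration_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(a); n2 <- length(b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  u_all <- apply(sets, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Two-sided Fisher p by full hypergeometric enumeration with choose()
# arithmetic (same minimum-likelihood two-sided rule, with the customary
# 1 + 1e-7 relative tolerance on "as extreme").
fisher_enumeration_p <- function(tab) {
  k <- tab[1, 1]
  n_in <- sum(tab[1, ])
  K <- sum(tab[, 1])
  N <- sum(tab)
  support <- max(0, K - (N - n_in)):min(n_in, K)
  logp <- lchoose(n_in, support) + lchoose(N - n_in, K - support) -
    lchoose(N, K)
  probs <- exp(logp)
  p_obs <- probs[support == k]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided binomial tail at null p = 1/2 via arbitrary-precision
# rational arithmetic (Python fractions); sums P(X = i) over all i with
# P(X = i) <= P(X = k).
binom_half_exact_p <- function(k, n) {
  code <- sprintf(paste0(
    "from fractions import Fraction\nfrom math import comb\n",
    "n=%d;k=%d\n",
    "pk=Fraction(comb(n,k),2**n)\n",
    "tot=sum(Fraction(comb(n,i),2**n) for i in range(n+1) ",
    "if Fraction(comb(n,i),2**n)<=pk)\n",
    "print(tot.numerator, tot.denominator)\n"), n, k)
  out <- system2("python", "-", stdout = TRUE, input = code)
  parts <- as.numeric(strsplit(out, " ")[[1]])
  parts[1] / parts[2]
}
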