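# Shared fixtures and independent oracles. Oracles deliberately avoid
# the code paths they check: the binomial oracle sums the probability
# mass combinatorially, the logistic oracle is a hand-rolled
# Newton-Raphson, and the Cox oracle optimises a naively coded Breslow
# partial likelihood.

make_evidence <- function(participant_id = "P1", gene = "DNMT3A",
                          hgvs_p = "p.R882H", chrom = "2", pos = 25234001L,
                          ref = "C", alt = "T", dp = 50L, ad = 10L,
                          f1r2 = 5L, f2r1 = 5L,
                          context = "ACGTACGTACG",
                          consequence = "missense") {
  data.frame(participant_id = participant_id, gene = gene, hgvs_p = hgvs_p,
             chrom = chrom, pos = pos, ref = ref, alt = alt,
             dp = as.integer(dp), ad = as.integer(ad),
             f1r2 = as.integer(f1r2), f2r1 = as.integer(f2r1),
             vaf = ad / dp, context = context, consequence = consequence,
             stringsAsFactors = FALSE)
}

make_phenotypes <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(participant_id = sprintf("P%04d", seq_len(n)),
             sex = sample(c("F", "M"), n, replace = TRUE),
             age_baseline = runif(n, 40, 71),
             tert_dosage = rbinom(n, 2, 0.3),
             stringsAsFactors = FALSE)
}

# Exact two-sided binomial p at p0 = 0.5 by combinatorial summation:
# sum the probability of every outcome no more likely than the observed
# one (point masses from log-binomial coefficients).
binom_two_sided_oracle <- function(ad, dp) {
  logp <- lchoose(dp, 0:dp) - dp * log(2)
  sum(exp(logp[logp <= logp[ad + 1] + 1e-12]))
}

# Newton-Raphson logistic regression (intercept + covariates) with
# step-halving on the log-likelihood for stability on small samples.
irls_logistic_oracle <- function(X, y, iter = 100) {
  X <- cbind(1, X)
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  beta <- rep(0, ncol(X))
  ll <- loglik(beta)
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- pmax(mu * (1 - mu), 1e-10)
    step <- solve(t(X) %*% (W * X), t(X) %*% (y - mu))
    for (h in 0:30) {
      cand <- beta + step / 2^h
      if (loglik(cand) >= ll - 1e-12) break
    }
    beta <- cand
    if (max(abs(step / 2^h)) < 1e-12) break
    ll <- loglik(beta)
  }
  drop(beta)
}

# Negative Breslow log partial likelihood for one covariate, coded from
# the definition (loop over event times, sum over the risk set).
cox_negloglik_oracle <- function(beta, time, status, x) {
  ll <- 0
  for (i in which(status == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  -ll
}

# Analysis table straight from the generator's latent truth.
truth_table <- function(bundle) {
  st <- truth_status(bundle)
  build_analysis_table(bundle$participants, st$chip, st$mca)
}
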