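# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests themselves write
# to tempdir().

# A hand-built tract set: one subject, two haplotypes over [1, 1000].
# hap 1: afr on [1, 400], eur on [401, 1000]; hap 2: eas throughout.
tiny_tracts <- function() {
  data.table::data.table(
    subject_id = "S0001",
    hap = c(1L, 1L, 2L),
    start = c(1, 401, 1),
    end = c(400, 1000, 1000),
    pop = c("afr", "eur", "eas")
  )
}

# A long-format local-ancestry table for one subject with explicit dosages.
la_table <- function(pos, afr, eas, eur, subject_id = "S0001") {
  data.table::data.table(
    subject_id = subject_id,
    marker_id = paste0("m", seq_along(pos)),
    pos = pos, dos_afr = afr, dos_eas = eas, dos_eur = eur
  )
}

# Expand 2x2 carrier-by-status counts into aligned status/dose vectors.
counts_to_vectors <- function(case_carrier, case_non, ctrl_carrier, ctrl_non) {
  list(
    status = rep(c(1L, 1L, 0L, 0L),
                 c(case_carrier, case_non, ctrl_carrier, ctrl_non)),
    dose = rep(c(1L, 0L, 1L, 0L),
               c(case_carrier, case_non, ctrl_carrier, ctrl_non))
  )
}

# Small default-structure cohort for end-to-end tests.
small_cohort <- function(n = 250, seed = 42, ...) {
  simulate_cohort(sim_params(n_subjects = n, seed = seed, ...))
}

# Independent HWE oracle: absolute conditional probabilities of every
# heterozygote configuration given the allele counts, from the closed-form
# expression with explicit normalising constant.
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  hets <- seq(min(n_a, n_b) %% 2, min(n_a, n_b), by = 2)
  logp <- lfactorial(n) + lfactorial(n_a) + lfactorial(n_b) -
    lfactorial(2 * n) + hets * log(2) -
    lfactorial((n_a - hets) / 2) - lfactorial(hets) -
    lfactorial((n_b - hets) / 2)
  p <- exp(logp)
  stopifnot(abs(sum(p) - 1) < 1e-8)  # the distribution must be proper
  obs <- p[hets == n_ab]
  min(1, sum(p[p <= obs + 1e-12]))
}

# Exhaustive two-group permutation p-value: every distinct assignment of
# group-1 positions, equal weight.
exhaustive_perm_p <- function(values, labels) {
  labels <- as.factor(labels)
  n1 <- sum(labels == levels(labels)[1])
  n <- length(values)
  obs <- mean(values[labels == levels(labels)[1]]) -
    mean(values[labels != levels(labels)[1]])
  sets <- utils::combn(n, n1)
  stats <- apply(sets, 2, function(ix) {
    mean(values[ix]) - mean(values[-ix])
  })
  mean(abs(stats) >= abs(obs) - 1e-12)
}

# O(n^2) Kendall tau-b oracle with explicit tie corrections.
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  ty <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}
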