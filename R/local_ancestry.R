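#' Mean local-ancestry dosage in a window around a position
#'
#' Unweighted arithmetic mean, per population, of dosages at all markers
#' whose position lies in `[center - halfwidth, center + halfwidth]`
#' (closed), per subject. The default 1 kb half-width reproduces averaging
#' "1 kb up- and downstream" of a focal variant.
#'
#' @param la Local-ancestry table from [read_local_ancestry()] (columns
#'   `subject_id`, `pos`, `dos_afr`, `dos_eas`, `dos_eur`).
#' @param center_pos Window centre (bp).
#' @param halfwidth Window half-width (bp), default 1000.
#' @return data.table: `subject_id`, `afr`, `eas`, `eur` (window means),
#'   `n_markers_in_window`.
#' @export
window_mean <- function(la, center_pos, halfwidth = 1000) {
  la <- as.data.table(la)
  lo <- center_pos - halfwidth
  hi <- center_pos + halfwidth
  w <- la[pos >= lo & pos <= hi]
  if (nrow(w) == 0) {
    stop("no markers in window [", format(lo, scientific = FALSE), ", ",
         format(hi, scientific = FALSE), "]")
  }
  out <- w[, .(afr = mean(dos_afr), eas = mean(dos_eas), eur = mean(dos_eur),
               n_markers_in_window = .N), by = subject_id]
  setorder(out, subject_id)
  out[]
}

#' Normed difference of two dosages
#'
#' `(a - b) / (a + b)`: a signed, scale-free contrast in `[-1, 1]`.
#' Undefined when both dosages are zero; returned as `NA` with a warning.
#'
#' @param a,b Nonnegative dosages (vectorised).
#' @return numeric in `[-1, 1]` (NA where `a + b == 0`).
#' @export
normed_difference <- function(a, b) {
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    stop("dosages must be nonnegative")
  }
  s <- a + b
  out <- (a - b) / s
  if (any(s == 0, na.rm = TRUE)) {
    warning("normed difference undefined where both dosages are 0; returning NA")
    out[s == 0] <- NA_real_
  }
  out
}

#' Per-group dosage means and normed-difference summaries
#'
#' For each population: the two group means and their difference. For each
#' ordered population pair: group means of the per-subject normed
#' differences and their difference. (Per-subject normed differences are
#' averaged within groups; the normed difference of the group means is an
#' alternative summary that agrees closely when within-group spread is
#' moderate, but only the per-subject version admits a subject-relabelling
#' permutation null.)
#'
#' @param win Window means from [window_mean()].
#' @param labels Two-level factor/character grouping, aligned with `win`
#'   rows.
#' @param pops Population column names inside `win`.
#' @return data.frame: `measure` (population or "pair_a_b"), `mean_<g1>`,
#'   `mean_<g2>`, `difference` (group1 - group2).
#' @export
group_summary <- function(win, labels, pops = c("afr", "eas", "eur")) {
  win <- as.data.table(win)
  stopifnot(nrow(win) == length(labels))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  if (any(table(labels) == 0)) stop("both groups must be non-empty")
  g1 <- levels(labels)[1]
  g2 <- levels(labels)[2]

  rows <- list()
  for (p in pops) {
    m1 <- mean(win[[p]][labels == g1])
    m2 <- mean(win[[p]][labels == g2])
    rows[[p]] <- data.frame(measure = p, m1 = m1, m2 = m2,
                            difference = m1 - m2)
  }
  prs <- utils::combn(pops, 2, simplify = FALSE)
  for (pr in prs) {
    nd <- normed_difference(win[[pr[1]]], win[[pr[2]]])
    m1 <- mean(nd[labels == g1], na.rm = TRUE)
    m2 <- mean(nd[labels == g2], na.rm = TRUE)
    rows[[paste(pr, collapse = "_")]] <- data.frame(
      measure = paste0("pair_", pr[1], "_", pr[2]),
      m1 = m1, m2 = m2, difference = m1 - m2)
  }
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("mean_", c(g1, g2))
  rownames(out) <- NULL
  out
}

#' Two-group permutation test on a difference of means
#'
#' The observed statistic is `mean(group1) - mean(group2)`. The null is
#' generated by Monte-Carlo relabelling without replacement, preserving
#' group sizes; the two-sided p-value counts permuted statistics whose
#' absolute value reaches the observed absolute value. The point estimate
#' uses the add-one estimator `(n_exceed + 1) / (n_perm + 1)`; the display
#' string mirrors the "<1/n_perm" convention when no permutation exceeds
#' the observed statistic.
#'
#' @param values Numeric per-subject statistic.
#' @param labels Two-level grouping aligned with `values`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer; when supplied the RNG is seeded for a
#'   reproducible null.
#' @return list of class `permutation_result`: `statistic_name`,
#'   `observed`, `n_perm`, `n_exceed`, `p_point`, `p_report`, `seed`.
#' @export
permutation_test <- function(values, labels, n_perm = 10000, seed = NULL) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  idx1 <- which(labels == levels(labels)[1])
  n1 <- length(idx1)
  n <- length(values)
  if (n1 == 0 || n1 == n) stop("both groups must be non-empty")
  if (!is.null(seed)) set.seed(seed)

  total <- sum(values)
  obs <- sum(values[idx1]) / n1 - (total - sum(values[idx1])) / (n - n1)
  s1 <- vapply(seq_len(n_perm),
               function(i) sum(values[sample.int(n, n1)]), numeric(1))
  perm <- s1 / n1 - (total - s1) / (n - n1)
  n_exceed <- sum(abs(perm) >= abs(obs) - 1e-12)
  p_point <- (n_exceed + 1) / (n_perm + 1)
  p_report <- if (n_exceed == 0) {
    sprintf("<%.2E", 1 / n_perm)
  } else {
    sprintf("%.2E", p_point)
  }
  structure(
    list(statistic_name = "difference_of_group_means", observed = obs,
         n_perm = n_perm, n_exceed = n_exceed, p_point = p_point,
         p_report = p_report, seed = seed),
    class = "permutation_result"
  )
}

#' Kendall's tau-b with tie correction
#'
#' Rank correlation with the tau-b tie correction; the p-value comes from
#' the tie-corrected normal approximation (`stats::cor.test`,
#' `exact = FALSE`). All-tied input has no defined tau and is reported
#' missing.
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @return list: `tau`, `p`.
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("tau undefined for all-tied input")
    return(list(tau = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE)
  )
  list(tau = unname(ct$estimate), p = ct$p.value)
}
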