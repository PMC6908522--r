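## Significance Analysis of Microarrays: moderated d-statistic
## d_i = (mean_case - mean_ctrl) / (s_i + s0), with the fudge factor s0
## chosen to minimize the coefficient of variation of d's spread across
## the range of s, a pooled permutation null over group relabelings, and
## Storey q-values.

#' Pooled standard error per feature
#'
#' `s_i = sqrt(a * (SS_case + SS_ctrl))` with
#' `a = (1/n1 + 1/n2) / (n1 + n2 - 2)` and `SS` the within-group sums of
#' squared deviations. With `s0 = 0`, `delta_mean / s` is the classical
#' pooled two-sample t-statistic.
#'
#' @param values feature x sample numeric matrix.
#' @param case logical vector marking case columns.
#' @return numeric vector of pooled standard errors.
#' @export
pooled_se <- function(values, case) {
  n1 <- sum(case); n2 <- sum(!case)
  if (n1 < 2 || n2 < 2) stop_stats("each group needs at least 2 samples")
  ss <- function(x) rowSums((x - rowMeans(x))^2)
  a <- (1 / n1 + 1 / n2) / (n1 + n2 - 2)
  sqrt(a * (ss(values[, case, drop = FALSE]) + ss(values[, !case, drop = FALSE])))
}

## numerator and s for one labeling, via matrix products (fast under permutation)
sam_components <- function(values, case) {
  list(delta = rowMeans(values[, case, drop = FALSE]) -
         rowMeans(values[, !case, drop = FALSE]),
       s = pooled_se(values, case))
}

#' Estimate the SAM fudge factor s0
#'
#' Candidate values are the quantiles of `s` at `alpha = 0, 0.05, ...,
#' 1`. Features are split into 100 equal-count bins by `s`; for each
#' candidate, the spread of `d(alpha) = delta / (s + s0_alpha)` within
#' each bin is measured by the scaled median absolute deviation, and the
#' candidate minimizing the coefficient of variation of those bin-wise
#' MADs is chosen (smallest `alpha` on ties).
#'
#' @param delta per-feature mean differences (the d numerator).
#' @param s per-feature pooled standard errors.
#' @param n_windows number of equal-count s-bins (collapsed when there
#'   are fewer features).
#' @return the fudge factor `s0`, with the selected quantile level in
#'   attribute `alpha`.
#' @export
estimate_s0 <- function(delta, s, n_windows = 100) {
  m <- length(s)
  if (m < 100) warning("estimate_s0: fewer than 100 features; s0 is unstable")
  if (sd(s) == 0) {
    warning("estimate_s0: all standard errors identical; using s0 = 0")
    return(structure(0, alpha = 0))
  }
  alphas <- seq(0, 1, by = 0.05)
  cand <- quantile(s, alphas, names = FALSE, type = 7)
  nb <- min(n_windows, max(2, floor(m / 5)))
  bin <- ceiling(rank(s, ties.method = "first") / (m / nb))
  cv <- vapply(cand, function(s0) {
    d <- delta / (s + s0)
    mads <- tapply(d, bin, mad)
    mu <- mean(mads)
    if (!is.finite(mu) || mu == 0) return(Inf)
    sd(mads) / mu
  }, numeric(1))
  k <- which.min(cv)          # which.min takes the first (smallest alpha) on ties
  structure(cand[k], alpha = alphas[k])
}

#' SAM moderated statistics for one study
#'
#' @param study a normalized (glog2) `ExpressionStudy`.
#' @param s0 fudge factor; `"auto"` estimates it with [estimate_s0()].
#' @return list with `d`, `s`, `delta_mean`, `direction`
#'   (`sign(delta_mean)`), and the `s0` used.
#' @export
sam_statistics <- function(study, s0 = "auto") {
  case <- unname(study$group) == "case"
  cmp <- sam_components(study$values, case)
  if (identical(s0, "auto")) s0 <- as.numeric(estimate_s0(cmp$delta, cmp$s))
  if (!is.numeric(s0) || s0 < 0) stop_config("s0 must be a non-negative number")
  zero <- cmp$s + s0 == 0
  if (any(zero & cmp$delta != 0))
    stop_stats("zero denominator (s + s0 = 0) for feature(s): %s",
               paste(head(names(which(zero & cmp$delta != 0)), 5), collapse = ", "))
  d <- ifelse(cmp$s + s0 == 0, 0, cmp$delta / (cmp$s + s0))
  list(d = d, s = cmp$s, delta_mean = cmp$delta,
       direction = sign(cmp$delta), s0 = s0)
}

## B distinct case-assignments (as logical matrix columns), identity
## excluded when possible; exhaustive when the total count is small.
permutation_labels <- function(case, B, seed) {
  n <- length(case)
  n1 <- sum(case)
  total <- choose(n, n1)
  id_key <- paste(which(case), collapse = ",")
  if (total - 1 <= B) {
    all_sets <- combn(n, n1)
    keys <- apply(all_sets, 2, paste, collapse = ",")
    keep <- keys != id_key
    if (sum(keep) < B)
      message(sprintf("only %d distinct permutations available; B reduced from %d",
                      sum(keep), B))
    sets <- all_sets[, keep, drop = FALSE]
  } else {
    sets <- with_seed(seed, {
      seen <- character(0)
      out <- matrix(NA_integer_, n1, 0)
      while (ncol(out) < B) {
        need <- B - ncol(out)
        draw <- replicate(need + 5, sort(sample.int(n, n1)))
        keys <- apply(draw, 2, paste, collapse = ",")
        ok <- !duplicated(keys) & !keys %in% c(seen, id_key)
        out <- cbind(out, draw[, ok, drop = FALSE])
        seen <- c(seen, keys[ok])
      }
      out[, seq_len(B), drop = FALSE]
    })
  }
  apply(sets, 2, function(ix) seq_len(n) %in% ix)
}

#' Permutation p-values for SAM d-statistics
#'
#' Group labels are permuted `B` times (distinct relabelings, identity
#' excluded when possible; exhaustive enumeration when fewer than `B`
#' distinct relabelings exist). The null is pooled across features:
#' `p_i = (1 + #\{(b, j): |d_j(b)| >= |d_i|\}) / (1 + m * B)`. The `+1`
#' smoothing avoids zero p-values.
#'
#' @param study normalized `ExpressionStudy`.
#' @param s0 fudge factor (fixed across permutations).
#' @param B requested number of permutations (warn below 200, error below 50
#'   is not raised — B is reduced only by exhaustion).
#' @param seed integer seed for the permutation draw.
#' @return list with `p` (per-feature p-values), `null_abs_d`
#'   (feature x B matrix of null `|d|`), and `B` actually used.
#' @export
permutation_pvalues <- function(study, s0, B = 1000, seed = 1L) {
  if (B < 50) stop_config("B must be at least 50")
  if (B < 200) warning("fewer than 200 permutations; p-value resolution is coarse")
  case <- unname(study$group) == "case"
  obs <- sam_statistics(study, s0 = s0)
  labels <- permutation_labels(case, B, seed)
  v <- study$values
  v2 <- v^2
  n <- ncol(v)
  tot <- rowSums(v); tot2 <- rowSums(v2)
  n1 <- sum(case); n2 <- n - n1
  a <- (1 / n1 + 1 / n2) / (n1 + n2 - 2)
  null_abs <- apply(labels, 2, function(g) {
    s1 <- v %*% g; s2 <- v2 %*% g
    m1 <- s1 / n1
    m0 <- (tot - s1) / n2
    ss1 <- s2 - n1 * m1^2
    ss0 <- (tot2 - s2) - n2 * m0^2
    s <- sqrt(a * pmax(ss1 + ss0, 0))
    abs(drop(m1 - m0)) / (s + s0)
  })
  null_abs[!is.finite(null_abs)] <- 0     # 0/0 features under permutation
  m <- nrow(v); Bu <- ncol(labels)
  ## count null |d| >= observed |d| with a small tolerance: the group-swap
  ## relabeling reproduces each observed |d| exactly in real arithmetic,
  ## and the tie must not be lost to floating-point noise
  null_sorted <- sort(as.numeric(null_abs))
  exceed <- length(null_sorted) -
    findInterval(abs(obs$d) - 1e-9, null_sorted)
  p <- (1 + exceed) / (1 + m * Bu)
  names(p) <- rownames(v)
  list(p = p, null_abs_d = null_abs, B = Bu)
}

#' Storey q-values
#'
#' `pi0 = min(1, #\{p > lambda\} / (m (1 - lambda)))` (no flooring), and
#' `q_(i) = min_\{j >= i\} pi0 * m * p_(j) / j` (step-up monotonicity).
#' With `pi0 = 1` this reduces to Benjamini-Hochberg adjusted p-values.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param lambda tuning parameter for the null-proportion estimate.
#' @param pi0 optional fixed null proportion; `pi0 = 1` reduces the
#'   q-values to Benjamini-Hochberg adjusted p-values.
#' @return list with `q` (same order as `p`) and `pi0`.
#' @export
storey_q <- function(p, lambda = 0.5, pi0 = NULL) {
  if (any(p < 0 | p > 1 | !is.finite(p)))
    stop_stats("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  o <- order(p)
  q_sorted <- rev(cummin(rev(pi0 * m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  list(q = q, pi0 = pi0)
}

#' Run the full SAM analysis on one study
#'
#' Computes moderated statistics, a pooled permutation null, Storey
#' q-values, and DEG calls at `q < q_threshold`. The study-level FDR of
#' the called set is estimated as
#' `pi0 * median_b #\{j: |d_j(b)| >= cutoff\} / n_called` with `cutoff`
#' the smallest `|d|` among called features; when it exceeds
#' `fdr_ceiling` the call set is kept but flagged non-conforming.
#'
#' @param study normalized `ExpressionStudy` (glog2 scale).
#' @param q_threshold q-value call threshold.
#' @param fdr_ceiling study-level FDR conformance ceiling.
#' @param B number of permutations.
#' @param seed seed for the permutation draw.
#' @param s0 `"auto"` or a fixed fudge factor.
#' @return an object of class `SamResult`: `table` (data frame with
#'   feature, d, s, delta_mean, direction, p_perm, q, called) plus
#'   study-level `s0`, `pi0`, `n_permutations`, `fdr_at_call`,
#'   `fdr_conforms`.
#' @export
sam_analysis <- function(study, q_threshold = 0.01, fdr_ceiling = 0.15,
                         B = 1000, seed = 1L, s0 = "auto") {
  if (study$scale != "glog2")
    warning(sprintf("study '%s' is not glog2-normalized; SAM assumes stabilized variance",
                    study$study_id))
  stat <- sam_statistics(study, s0 = s0)
  perm <- permutation_pvalues(study, s0 = stat$s0, B = B, seed = seed)
  st <- storey_q(perm$p)
  called <- st$q < q_threshold
  if (any(called)) {
    cutoff <- min(abs(stat$d[called]))
    null_counts <- colSums(perm$null_abs_d >= cutoff)
    fdr_at_call <- st$pi0 * median(null_counts) / sum(called)
  } else fdr_at_call <- 0
  structure(list(
    table = data.frame(
      feature = study_features(study), d = unname(stat$d),
      s = unname(stat$s), delta_mean = unname(stat$delta_mean),
      direction = as.integer(unname(stat$direction)),
      p_perm = unname(perm$p), q = st$q, called = unname(called),
      stringsAsFactors = FALSE),
    study_id = study$study_id, disease_class = study$disease_class,
    s0 = stat$s0, pi0 = st$pi0, n_permutations = perm$B,
    q_threshold = q_threshold, fdr_at_call = fdr_at_call,
    fdr_conforms = fdr_at_call <= fdr_ceiling
  ), class = "SamResult")
}

#' @export
print.SamResult <- function(x, ...) {
  cat(sprintf(
    "SamResult '%s' (%s): %d features, s0=%.4g, pi0=%.3f, B=%d; %d called at q<%g (est. FDR %.3f%s)\n",
    x$study_id, x$disease_class, nrow(x$table), x$s0, x$pi0,
    x$n_permutations, sum(x$table$called), x$q_threshold, x$fdr_at_call,
    if (x$fdr_conforms) "" else ", NON-CONFORMING"))
  invisible(x)
}

#' Split called features by direction
#'
#' @param sam a `SamResult`.
#' @return list with character vectors `up` and `down`.
#' @export
call_degs <- function(sam) {
  tab <- sam$table
  list(up = tab$feature[tab$called & tab$direction > 0],
       down = tab$feature[tab$called & tab$direction < 0])
}
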