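#' Genome-wide rank-based p-values
#'
#' Fractional ranks with inclusive ties: lower tail
#' `p_i = #\{j : v_j <= v_i\} / N`, upper tail with `>=`. Computed over the
#' `N` non-missing values; missing in, missing out.
#'
#' @param values numeric vector.
#' @param tail `"lower"` (small values interesting) or `"upper"`.
#' @return p-values in `(0, 1]`, same length as `values`.
#' @export
rank_pvalues <- function(values, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least 2 non-missing values")
  v <- values[ok]
  n <- length(v)
  cnt <- if (tail == "lower") {
    vapply(v, function(x) sum(v <= x), 0L)
  } else {
    vapply(v, function(x) sum(v >= x), 0L)
  }
  out <- rep(NA_real_, length(values))
  out[ok] <- cnt / n
  out
}

# One C-step of FAST-MCD: given (mu, S), keep the h points with smallest
# Mahalanobis distance and recompute (mu, S).
c_step <- function(x, mu, S, h) {
  d2 <- stats::mahalanobis(x, mu, S)
  sel <- order(d2)[seq_len(h)]
  xs <- x[sel, , drop = FALSE]
  list(mu = colMeans(xs), S = stats::cov(xs), subset = sel)
}

#' Robust correlation via FAST-MCD
#'
#' Minimum covariance determinant correlation of the columns of
#' `stat_matrix`, estimated on up to `sample_rows` uniformly subsampled
#' complete rows: `h = floor(mcd_alpha * n)`; 500 random `(T+1)`-subsets,
#' two C-steps each, the best 10 iterated to convergence; reweighting with
#' the chi-square(T) 0.975 cutoff; the reweighted covariance is returned as a
#' correlation matrix. Falls back to Spearman rank correlation (with a
#' warning) if the best subset is singular.
#'
#' @param stat_matrix numeric matrix, windows x statistics.
#' @param mcd_alpha subset fraction in (0.5, 1].
#' @param sample_rows row subsample cap.
#' @param seed subsampling/search seed.
#' @param nsamp number of random starts.
#' @return T x T correlation matrix.
#' @export
robust_correlation <- function(stat_matrix, mcd_alpha = 0.75,
                               sample_rows = 50000, seed = 1L, nsamp = 500) {
  x <- as.matrix(stat_matrix)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  t_stats <- ncol(x)
  if (nrow(x) < 10 * t_stats)
    stop("need at least 10 complete rows per statistic for MCD")
  set.seed(seed)
  if (nrow(x) > sample_rows)
    x <- x[sample.int(nrow(x), sample_rows), , drop = FALSE]
  n <- nrow(x)
  h <- floor(mcd_alpha * n)

  spearman <- function() {
    warning("singular MCD subset; falling back to Spearman correlation",
            call. = FALSE)
    stats::cor(x, method = "spearman")
  }
  nonsingular <- function(S) {
    ev <- tryCatch(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) NA)
    all(is.finite(ev)) && min(ev) > max(ev) * 1e-12 && max(ev) > 0
  }

  trials <- vector("list", nsamp)
  for (k in seq_len(nsamp)) {
    sub <- sample.int(n, t_stats + 1L)
    xs <- x[sub, , drop = FALSE]
    mu <- colMeans(xs); S <- stats::cov(xs)
    tries <- 0L
    while (!nonsingular(S) && length(sub) < n && tries < 50L) {
      sub <- c(sub, sample(setdiff(seq_len(n), sub), 1L))
      xs <- x[sub, , drop = FALSE]
      mu <- colMeans(xs); S <- stats::cov(xs)
      tries <- tries + 1L
    }
    if (!nonsingular(S)) next
    for (it in 1:2) {
      st <- c_step(x, mu, S, h)
      mu <- st$mu; S <- st$S
      if (!nonsingular(S)) break
    }
    if (nonsingular(S))
      trials[[k]] <- list(mu = mu, S = S, det = determinant(S)$modulus)
  }
  trials <- Filter(Negate(is.null), trials)
  if (!length(trials)) return(spearman())
  dets <- vapply(trials, function(z) as.numeric(z$det), 0)
  best <- trials[order(dets)[seq_len(min(10L, length(trials)))]]

  final <- NULL
  for (cand in best) {
    mu <- cand$mu; S <- cand$S
    prev_det <- Inf
    for (it in 1:100) {
      if (!nonsingular(S)) break
      st <- c_step(x, mu, S, h)
      mu <- st$mu; S <- st$S
      d <- as.numeric(determinant(S)$modulus)
      if (!is.finite(d) || prev_det - d < 1e-12) break
      prev_det <- d
    }
    if (nonsingular(S)) {
      d <- as.numeric(determinant(S)$modulus)
      if (is.null(final) || d < final$det)
        final <- list(mu = mu, S = S, det = d)
    }
  }
  if (is.null(final)) return(spearman())

  # consistency scaling, then reweighting at the chi-square 0.975 cutoff
  d2 <- stats::mahalanobis(x, final$mu, final$S)
  S_raw <- final$S * stats::median(d2) / stats::qchisq(0.5, t_stats)
  d2 <- stats::mahalanobis(x, final$mu, S_raw)
  w <- d2 <= stats::qchisq(0.975, t_stats)
  if (sum(w) <= t_stats) return(spearman())
  S_rw <- stats::cov(x[w, , drop = FALSE])
  if (!nonsingular(S_rw)) return(spearman())
  R <- stats::cov2cor(S_rw)
  dimnames(R) <- list(colnames(stat_matrix), colnames(stat_matrix))
  R
}

#' De-correlated composite of multiple signals
#'
#' `DCMS_i = sum_t logit(1 - p_it) / sum_s |r_st|`, i.e. each statistic's
#' log-odds against its rank p-value, down-weighted by that statistic's total
#' absolute correlation (the diagonal `r_tt = 1` included). P-values are
#' clamped to `[1/(2N), 1 - 1/(2N)]` before the log. Rows with any missing
#' p-value get `NA`.
#'
#' @param p_matrix windows x statistics matrix of rank p-values, columns
#'   aligned with `correlation`.
#' @param correlation T x T correlation matrix (from
#'   [robust_correlation()]).
#' @return numeric vector of DCMS scores.
#' @export
dcms_scores <- function(p_matrix, correlation) {
  p <- as.matrix(p_matrix)
  if (ncol(p) != ncol(correlation))
    stop("p_matrix columns do not match the correlation matrix")
  n <- sum(stats::complete.cases(p))
  eps <- 1 / (2 * n)
  pc <- pmin(pmax(p, eps), 1 - eps)
  w <- 1 / rowSums(abs(correlation))
  as.numeric(log((1 - pc) / pc) %*% w)
}

#' Calibrate DCMS scores against a robust normal fit
#'
#' Location by intercept-only Huber M-estimation (tuning constant 1.345,
#' iterated to 1e-8), scale by the normalized MAD; the p-value of window i is
#' the upper normal tail `1 - Phi((DCMS_i - mu) / sigma)`, and windows with
#' `p < threshold` are flagged significant.
#'
#' @param scores DCMS scores (NA allowed: untested windows).
#' @param threshold significance threshold on the p-value.
#' @return data frame (dcms, p, significant) with attributes `mu`, `sigma`.
#' @export
dcms_calibrate <- function(scores, threshold = 0.01) {
  ok <- !is.na(scores)
  x <- scores[ok]
  if (length(x) < 50) stop("need at least 50 scores to calibrate")
  sigma <- stats::mad(x)
  if (sigma == 0) stop("degenerate scores: zero MAD")
  k <- 1.345
  mu <- stats::median(x)
  for (it in 1:200) {
    r <- (x - mu) / sigma
    w <- ifelse(abs(r) < 1e-12, 1, pmin(1, k / abs(r)))
    mu_new <- sum(w * x) / sum(w)
    if (abs(mu_new - mu) < 1e-8) { mu <- mu_new; break }
    mu <- mu_new
  }
  p <- rep(NA_real_, length(scores))
  p[ok] <- stats::pnorm((x - mu) / sigma, lower.tail = FALSE)
  out <- data.frame(dcms = scores, p = p,
                    significant = !is.na(p) & p < threshold)
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  out
}

#' Full DCMS scan over a per-window statistic table
#'
#' Combines windowed nucleotide diversity, Tajima's D and mean absolute iHS:
#' genome-wide rank p-values per statistic (sweep-consistent tails: pi lower,
#' D lower, mean |iHS| upper), robust correlation of the raw statistics,
#' DCMS scoring on complete rows, and robust-normal significance calling.
#'
#' @param stats_table data frame with columns `chrom`, `start`, `end`, `pi`,
#'   `tajima_d`, `mean_abs_ihs` (e.g. assembled by [window_stats()]).
#' @param tails named character vector of per-statistic tails.
#' @param p_threshold significance threshold.
#' @param mcd_alpha,sample_rows,seed passed to [robust_correlation()].
#' @return `stats_table` with added columns `p_pi`, `p_tajima_d`,
#'   `p_mean_abs_ihs`, `dcms`, `p_dcms`, `significant`; the correlation
#'   matrix and calibration (mu, sigma) are attached as attributes.
#' @export
dcms_scan <- function(stats_table,
                      tails = c(pi = "lower", tajima_d = "lower",
                                mean_abs_ihs = "upper"),
                      p_threshold = 0.01, mcd_alpha = 0.75,
                      sample_rows = 50000, seed = 1L) {
  stat_cols <- names(tails)
  stopifnot(all(stat_cols %in% names(stats_table)))
  X <- as.matrix(stats_table[, stat_cols])
  P <- sapply(stat_cols, function(sc) rank_pvalues(X[, sc], tails[[sc]]))
  R <- robust_correlation(X, mcd_alpha = mcd_alpha,
                          sample_rows = sample_rows, seed = seed)
  scores <- dcms_scores(P, R)
  calib <- dcms_calibrate(scores, threshold = p_threshold)
  out <- stats_table
  out[paste0("p_", stat_cols)] <- as.data.frame(P)
  out$dcms <- scores
  out$p_dcms <- calib$p
  out$significant <- calib$significant
  attr(out, "correlation") <- R
  attr(out, "mu") <- attr(calib, "mu")
  attr(out, "sigma") <- attr(calib, "sigma")
  out
}
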