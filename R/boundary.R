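## Single-changepoint estimation on binomial conversion profiles.
##
## The boundary ("tipping point") between the exposed upstream chromatin
## and the protected gene-body chromatin is formalized as the changepoint
## of a two-regime binomial model: conversion counts x_i ~ Bin(n_i, p_up)
## for positions up to the changepoint and Bin(n_i, p_down) after it. The
## estimator is an exhaustive likelihood scan over all candidate
## changepoints (profiles are ~2 kb, so O(n) cumulative-sum evaluation of
## all splits is immediate). Significance is reported two ways: a
## chi-square (df = 2) approximation to the likelihood-ratio test against
## the one-regime model, and an optional permutation null. Because the
## statistic is maximized over candidates, the chi-square p-value is
## anticonservative; the permutation p-value is exact under
## exchangeability and is the one to use for calibrated inference.

.binll <- function(x, n) {
  ## log-likelihood of pooled Bernoulli counts at their MLE, 0*log(0) = 0
  p <- x / n
  t1 <- ifelse(x > 0, x * log(p), 0)
  t2 <- ifelse(n - x > 0, (n - x) * log(1 - p), 0)
  t1 + t2
}

.scan_llr <- function(x, n) {
  ## max two-regime log-likelihood gain over all splits 1..(m-1)
  cx <- cumsum(x); cn <- cumsum(n)
  m <- length(x)
  k <- seq_len(m - 1L)
  ll2 <- .binll(cx[k], cn[k]) + .binll(cx[m] - cx[k], cn[m] - cn[k])
  ll1 <- .binll(cx[m], cn[m])
  list(llr = ll2 - ll1, ll1 = ll1)
}

#' Detect a chromatin boundary in a conversion profile
#'
#' Fits a single-changepoint two-regime binomial model to per-position
#' (converted, depth) counts and returns the maximum-likelihood boundary:
#' the first profiled position of the downstream regime. By default both
#' strands are pooled (each position carries one strand's counts in this
#' assay: C positions the top strand, G positions the bottom strand).
#' Candidates within one log-likelihood unit of the optimum are flagged as
#' a plateau and the leftmost is reported.
#'
#' @param profile a `conversion_profile` (NA-rate positions are skipped).
#' @param search_interval optional `c(start, end)`; only changepoints whose
#'   downstream regime starts inside it are considered.
#' @param min_side minimum informative positions required on each side of
#'   any candidate (default 10).
#' @param strand "pooled" (default), "top" or "bottom".
#' @param n_perm number of permutation-null replicates for the permutation
#'   p-value (default 0 = chi-square approximation only).
#' @param perm_seed RNG seed for the permutation null.
#' @return list of class `boundary_call`: `position` (first downstream
#'   position), `p_up_hat`, `p_down_hat`, `log_likelihood_ratio` (natural
#'   log), `p_value` (chi-square, df 2), `p_value_perm` (NA unless
#'   `n_perm > 0`), `n_positions_used`, `plateau`, `candidates`.
#' @export
detect_boundary <- function(profile, search_interval = NULL, min_side = 10L,
                            strand = c("pooled", "top", "bottom"),
                            n_perm = 0L, perm_seed = 1L) {
  strand <- match.arg(strand)
  df <- as.data.frame(profile)
  if (strand != "pooled") df <- df[df$strand == strand, , drop = FALSE]
  df <- df[!is.na(df$rate) & df$depth > 0L, , drop = FALSE]
  df <- df[order(df$pos), , drop = FALSE]
  m <- nrow(df)
  x <- df$n_converted; n <- df$depth
  k <- seq_len(max(m - 1L, 0L))
  ok <- k >= min_side & (m - k) >= min_side
  if (!is.null(search_interval)) {
    stopifnot(length(search_interval) == 2L)
    ## candidate k puts the boundary at the first downstream position
    bpos <- df$pos[k + 1L]
    ok <- ok & bpos >= search_interval[1] & bpos <= search_interval[2]
  }
  if (m < 2L * min_side || !any(ok))
    stop("too few informative positions (", m, ") for boundary detection")
  sc <- .scan_llr(x, n)
  llr <- ifelse(ok, sc$llr, -Inf)
  best <- which.max(llr)
  plateau_set <- which(llr >= llr[best] - 1)
  kstar <- min(plateau_set)           # leftmost within 1 LL unit
  plateau <- length(plateau_set) > 1L
  up <- seq_len(kstar); dn <- (kstar + 1L):m
  obs <- llr[kstar]
  p_chisq <- pchisq(2 * max(obs, 0), df = 2L, lower.tail = FALSE)
  p_perm <- NA_real_
  if (n_perm > 0L) {
    set.seed(perm_seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      i <- sample.int(m)
      pllr <- .scan_llr(x[i], n[i])$llr
      pllr <- ifelse(ok, pllr, -Inf)  # same candidate restriction
      if (max(pllr) >= obs) exceed <- exceed + 1L
    }
    p_perm <- (1 + exceed) / (n_perm + 1)
  }
  structure(list(position = df$pos[kstar + 1L],
                 last_upstream = df$pos[kstar],
                 p_up_hat = sum(x[up]) / sum(n[up]),
                 p_down_hat = sum(x[dn]) / sum(n[dn]),
                 log_likelihood_ratio = obs,
                 p_value = p_chisq,
                 p_value_perm = p_perm,
                 n_positions_used = m,
                 plateau = plateau,
                 strand = strand,
                 search_interval = search_interval),
            class = "boundary_call")
}

#' @export
print.boundary_call <- function(x, ...) {
  cat("<boundary_call> downstream regime starts at", x$position, "\n",
      sprintf(" p_up = %.4f  p_down = %.4f  logLR = %.2f  p(chisq) = %.3g\n",
              x$p_up_hat, x$p_down_hat, x$log_likelihood_ratio, x$p_value))
  if (!is.na(x$p_value_perm))
    cat(sprintf(" p(permutation) = %.3g\n", x$p_value_perm))
  invisible(x)
}

#' Regime summaries around a boundary
#'
#' Max/mean/min of non-NA conversion rates in upstream and downstream
#' windows, the summaries behind statements like "conversion reached 20%
#' upstream and dropped below 5% downstream".
#'
#' @param profile a `conversion_profile`.
#' @param boundary_position first position of the downstream regime.
#' @param windows optional list with `upstream = c(start, end)` and
#'   `downstream = c(start, end)`; defaults to everything on each side of
#'   the boundary.
#' @return list of class `regime_summary`: `upstream_max`, `upstream_mean`,
#'   `downstream_min`, `downstream_mean`, `windows`, `n_upstream`,
#'   `n_downstream`.
#' @export
regime_summary <- function(profile, boundary_position, windows = NULL) {
  df <- as.data.frame(profile)
  df <- df[!is.na(df$rate), , drop = FALSE]
  if (is.null(windows))
    windows <- list(upstream = c(min(df$pos), boundary_position - 1L),
                    downstream = c(boundary_position, max(df$pos)))
  pick <- function(w) {
    r <- df$rate[df$pos >= w[1] & df$pos <= w[2]]
    if (length(r) == 0L)
      stop("window [", w[1], ", ", w[2], "] contains no informative positions")
    r
  }
  up <- pick(windows$upstream); dn <- pick(windows$downstream)
  structure(list(upstream_max = max(up), upstream_mean = mean(up),
                 downstream_min = min(dn), downstream_mean = mean(dn),
                 windows = windows,
                 n_upstream = length(up), n_downstream = length(dn)),
            class = "regime_summary")
}
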