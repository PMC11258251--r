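# Independent brute-force oracles. These deliberately use the slowest,
# most literal formulation of each definition so they share no code path
# with the package implementation.

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = ".")

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Enumerate every (left-arm start i, arm length a, loop length l) placement
# and keep those satisfying the IR definition: arms pair with <= max_mismatch
# mismatches, outermost and innermost pairs match, and the annotation is
# maximal (no single complementary-pair extension outward with the same
# loop, nor inward with the loop shrunk by two while >= min_loop).
oracle_find_irs <- function(s, min_arm, max_loop, max_mismatch = 0,
                            min_loop = 3) {
  b <- strsplit(s, "")[[1]]
  L <- length(b)
  pairs_ok <- function(p, q) b[q] == ORACLE_COMP[b[p]]
  rows <- list()
  for (i in seq_len(L)) {
    amax <- floor((L - i + 1 - min_loop) / 2)
    if (amax < min_arm) next
    for (a in min_arm:amax) {
      for (l in min_loop:max_loop) {
        j <- i + a + l              # right arm start
        if (j + a - 1 > L) next
        k <- 1:a
        # pair k: left base i+k-1 with right base j+a-k
        m <- pairs_ok(i + k - 1, j + a - k)
        if (!m[1] || !m[a]) next                     # terminal pairs
        if (sum(!m) > max_mismatch) next
        # outward: add pair (i-1, j+a)
        if (i - 1 >= 1 && j + a <= L && pairs_ok(i - 1, j + a)) next
        # inward: add pair (i+a, j-1), loop becomes l-2
        if (l - 2 >= min_loop && pairs_ok(i + a, j - 1)) next
        rows[[length(rows) + 1]] <- c(left_start = i, left_end = i + a - 1,
                                      loop_start = i + a, loop_end = j - 1,
                                      right_start = j, right_end = j + a - 1,
                                      arm_length = a, loop_length = l,
                                      mismatches = sum(!m),
                                      pairing_score = a - sum(!m))
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(left_start = integer(0), arm_length = integer(0),
                      loop_length = integer(0)))
  df <- as.data.frame(do.call(rbind, rows))
  df[order(df$left_start, -df$arm_length), , drop = FALSE]
}

# Exhaustive enumeration of nested pairings (recursion over "base i is
# unpaired, or pairs with some k"), no dynamic programming reuse.
oracle_fold_max <- function(s, min_loop = 3, wobble = FALSE) {
  b <- strsplit(s, "")[[1]]
  can_pair <- function(x, y) {
    wc <- paste0(x, y) %in% c("AT", "TA", "CG", "GC")
    if (wobble) wc <- wc || paste0(x, y) %in% c("GT", "TG")
    wc
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (can_pair(b[i], b[k])) {
        inner <- if (k - 1L >= i + 1L) rec(i + 1L, k - 1L) else 0L
        outer <- if (j >= k + 1L) rec(k + 1L, j) else 0L
        best <- max(best, 1L + inner + outer)
      }
    }
    best
  }
  rec(1L, nchar(s))
}

# Exhaustive offset x orientation x mode scan for one read. Returns every
# minimum-mismatch placement (below the mismatch budget).
oracle_align_read <- function(read, refseq, max_mismatch_frac = 0.1) {
  L <- nchar(refseq)
  n <- nchar(read)
  collapse <- function(x, m) if (m == "CT") gsub("C", "T", x) else gsub("G", "A", x)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  out <- list()
  for (o in c("fwd", "rc")) for (m in c("CT", "GA")) {
    d <- collapse(if (o == "fwd") read else rc, m)
    r <- collapse(refseq, m)
    dch <- strsplit(d, "")[[1]]
    rch <- strsplit(r, "")[[1]]
    for (st in 1:(L - n + 1)) {
      mm <- sum(dch != rch[st:(st + n - 1)])
      out[[length(out) + 1]] <- data.frame(
        ref_start = st, orientation = o, mode = m, n_mismatch = mm,
        stringsAsFactors = FALSE)
    }
  }
  all <- do.call(rbind, out)
  all <- all[all$n_mismatch <= floor(max_mismatch_frac * n), , drop = FALSE]
  if (nrow(all) == 0) return(all)
  all[all$n_mismatch == min(all$n_mismatch), , drop = FALSE]
}

# Direct O(m^2) two-regime binomial likelihood scan (reference
# implementation for the changepoint estimator).
oracle_boundary_scan <- function(x, n) {
  ll <- function(xs, ns) {
    p <- sum(xs) / sum(ns)
    s <- 0
    if (sum(xs) > 0) s <- s + sum(xs) * log(p)
    if (sum(ns - xs) > 0) s <- s + sum(ns - xs) * log(1 - p)
    s
  }
  m <- length(x)
  vapply(1:(m - 1), function(k)
    ll(x[1:k], n[1:k]) + ll(x[(k + 1):m], n[(k + 1):m]) - ll(x, n),
    numeric(1))
}

# Synthetic binomial conversion profile with a known changepoint.
make_profile <- function(m, boundary_index, p_up, p_down, depth,
                         start_pos = 1L) {
  pos <- start_pos:(start_pos + m - 1L)
  p <- ifelse(seq_len(m) < boundary_index, p_up, p_down)
  n <- rep(depth, m)
  x <- rbinom(m, n, p)
  df <- data.frame(pos = pos, strand = "top", rate = 100 * x / n,
                   depth = n, n_converted = x, stringsAsFactors = FALSE)
  class(df) <- c("conversion_profile", "data.frame")
  df
}
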