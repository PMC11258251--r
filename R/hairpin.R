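## Nussinov-style base-pair maximization.
##
## The hairpin readout needed here is qualitative (a wild-type IR folds, a
## stem mutant does not), so a pairing-maximization surrogate is used
## instead of a thermodynamic folder: maximize the number of nested
## Watson-Crick pairs subject to a minimum loop size.

.pair_ok <- function(a, b, wobble) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
        (a == "C" & b == "G") | (a == "G" & b == "C")
  if (wobble)
    wc <- wc | (a == "G" & b == "T") | (a == "T" & b == "G")
  wc
}

#' Maximum nested base pairing of a sequence (Nussinov)
#'
#' Dynamic program maximizing the number of nested base pairs `(i, j)` with
#' `j - i > min_loop`. Watson-Crick pairs only by default; `wobble = TRUE`
#' additionally allows G-T pairs. Pseudoknots are excluded by construction.
#'
#' @param seq base string (or [nucleotide_sequence()]).
#' @param min_loop minimum number of unpaired bases enclosed by a pair
#'   (default 3).
#' @param wobble allow G-T wobble pairs (default FALSE).
#' @return list of class `hairpin_fold`: `pairs` (two-column matrix of
#'   paired positions, i < j), `n_pairs`, `min_loop`.
#' @export
fold_hairpin <- function(seq, min_loop = 3L, wobble = FALSE) {
  s <- .bases_of(seq)
  n <- nchar(s)
  if (n < min_loop + 2L)
    stop("sequence too short to fold: ", n, " nt < min_loop + 2")
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  D <- matrix(0L, n, n)
  for (span in seq.int(min_loop + 1L, n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- max(D[i + 1L, j], D[i, j - 1L])
      if (.pair_ok(b[i], b[j], wobble))
        best <- max(best, D[i + 1L, j - 1L] + 1L)
      if (j - i > 1L) {
        k <- seq.int(i + 1L, j - 1L)
        best <- max(best, max(D[cbind(i, k)] + D[cbind(k + 1L, j)]))
      }
      D[i, j] <- best
    }
  }
  pairs <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j || D[i, j] == 0L) next
    if (D[i, j] == D[i + 1L, j]) { stack[[length(stack) + 1L]] <- c(i + 1L, j); next }
    if (D[i, j] == D[i, j - 1L]) { stack[[length(stack) + 1L]] <- c(i, j - 1L); next }
    if (j - i > min_loop && .pair_ok(b[i], b[j], wobble) &&
        D[i, j] == D[i + 1L, j - 1L] + 1L) {
      pairs <- rbind(pairs, c(i, j))
      stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L)
      next
    }
    for (k in seq.int(i + 1L, j - 1L)) {
      if (D[i, j] == D[i, k] + D[k + 1L, j]) {
        stack[[length(stack) + 1L]] <- c(i, k)
        stack[[length(stack) + 1L]] <- c(k + 1L, j)
        break
      }
    }
  }
  structure(list(pairs = pairs, n_pairs = D[1L, n], min_loop = min_loop),
            class = "hairpin_fold")
}

#' @export
print.hairpin_fold <- function(x, ...) {
  cat("<hairpin_fold>", x$n_pairs, "pairs (min_loop =", x$min_loop, ")\n")
  invisible(x)
}
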