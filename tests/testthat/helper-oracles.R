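# Independent oracles used by the property tests.

# Brute-force maximum-weight non-crossing pairing by exhaustive recursion
# (no memoization, no shared code with fold_hairpin).
brute_pair_weight <- function(a, b) {
  key <- paste0(a, b)
  w <- c(GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1)[key]
  if (is.na(w)) 0 else unname(w)
}

brute_force_fold <- function(bases, i = 1L, j = length(bases), min_loop = 3L) {
  if (j - i <= min_loop) return(0)
  best <- brute_force_fold(bases, i, j - 1L, min_loop)
  for (k in i:(j - min_loop - 1L)) {
    w <- brute_pair_weight(bases[k], bases[j])
    if (w > 0) {
      left <- if (k - 1L >= i) brute_force_fold(bases, i, k - 1L, min_loop)
              else 0
      best <- max(best,
                  left + brute_force_fold(bases, k + 1L, j - 1L, min_loop) + w)
    }
  }
  best
}

# Naive per-base coverage by looping over fragments and bases.
naive_span_coverage <- function(frags, L) {
  v <- numeric(L)
  for (i in seq_len(nrow(frags))) {
    idx <- (frags$start[i] + 1):frags$end[i]
    v[idx] <- v[idx] + 1
  }
  v
}

# Dot-bracket sanity: balanced, non-crossing, pair count, min-loop spacing.
check_dot_bracket <- function(db, n_pairs, min_loop = 3L) {
  chars <- strsplit(db, "")[[1]]
  stack <- integer(0)
  pairs <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (!length(stack)) return(FALSE)
      opener <- stack[length(stack)]
      stack <- stack[-length(stack)]
      inner <- if (opener + 1L <= i - 1L) chars[(opener + 1L):(i - 1L)]
               else character(0)
      if (i - opener - 1L < min_loop && !any(inner %in% c("(", ")")))
        return(FALSE)  # hairpin loop too tight
      pairs <- pairs + 1L
    }
  }
  length(stack) == 0L && pairs == n_pairs
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
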