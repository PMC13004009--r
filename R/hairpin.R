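# Candidate microRNA precursor discovery: broad-peak detection on a
# single-strand coverage track, 100-bp window extraction, and secondary
# structure by a weighted maximum-pairing (Nussinov-style) dynamic program.
# The DP score is a stability surrogate with a consistent ordering, not a
# nearest-neighbor free energy; fold_hairpin_rnafold() is an optional
# adapter to an external thermodynamic folder.

#' Detect broad coverage peaks of hairpin-precursor width
#'
#' Finds maximal runs where the smoothed signal stays at or above a
#' threshold and keeps runs whose width falls in `[w_min, w_max]` — the
#' scale of ~50-bp broad peaks characteristic of short hairpin precursors in
#' nascent 3'-end data, as opposed to single-base pause spikes. Each
#' accepted run is reported with a 100-bp extraction window centered on the
#' run midpoint (clipped at chromosome edges).
#'
#' Smoothing is a centered moving average of width `smooth_w` with
#' shrinking windows at chromosome edges (no padding bias).
#'
#' @param track A single-strand `coverage_track`.
#' @param theta Signal threshold (> 0) applied to the smoothed track.
#' @param w_min,w_max Accepted run widths in bp (defaults 30 and 80).
#' @param smooth_w Smoothing window in bp (default 5).
#' @param window Extraction window size in bp (default 100).
#' @return data.frame with columns `chrom`, `start`, `end`, `width`,
#'   `summit`, `mean_signal`, `window_start`, `window_end` (all coordinates
#'   0-based half-open).
#' @export
detect_broad_peaks <- function(track, theta, w_min = 30, w_max = 80,
                               smooth_w = 5, window = 100) {
  stopifnot(inherits(track, "coverage_track"))
  if (theta <= 0) stop("'theta' must be > 0")
  if (w_min < 1 || w_max < w_min) stop("invalid width bounds")
  out <- list()
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    L <- length(v)
    if (!L) next
    sm <- moving_average(v, smooth_w)
    r <- rle(sm >= theta)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths          # 0-based run starts
    keep <- r$values & r$lengths >= w_min & r$lengths <= w_max
    for (idx in which(keep)) {
      s <- starts[idx]; e <- ends[idx]
      mid <- s + (e - s) %/% 2
      ws <- max(0L, mid - window %/% 2)
      we <- min(L, ws + window)
      ws <- max(0L, we - window)        # keep full width when clipping
      seg <- v[(s + 1):e]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = s, end = e, width = e - s,
        summit = s + which.max(seg) - 1L,
        mean_signal = mean(seg),
        window_start = ws, window_end = we,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               width = integer(0), summit = integer(0),
               mean_signal = numeric(0), window_start = integer(0),
               window_end = integer(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

moving_average <- function(v, w) {
  if (w <= 1) return(v)
  n <- length(v)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w %/% 2L
  cs <- c(0, cumsum(v))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# pairing weights: G:C = 3, A:U = 2, G:U = 1 (hydrogen-bond counts)
pair_weights <- function() {
  w <- matrix(0L, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                        c("A", "C", "G", "U")))
  w["G", "C"] <- w["C", "G"] <- 3L
  w["A", "U"] <- w["U", "A"] <- 2L
  w["G", "U"] <- w["U", "G"] <- 1L
  w
}

#' Fold an RNA sequence into its maximum-weight hairpin structure
#'
#' Computes the maximum-weight non-crossing base pairing of the sequence by
#' dynamic programming, with pair weights G:C = 3, A:U = 2, G:U = 1 and a
#' minimum hairpin loop of `min_loop` unpaired bases between any paired
#' positions. The traceback yields a dot-bracket (Vienna) string; the score
#' is the total pair weight and is reported negated as a pseudo-energy so
#' that more stable structures are more negative, mirroring how free
#' energies are tabulated. T is converted to U on input.
#'
#' This is a maximum-pairing model: it orders candidates by base-pairing
#' potential consistently, but its score is not a free energy in kcal/mol.
#'
#' @param sequence RNA (or DNA) string over A/C/G/U(T).
#' @param min_loop Minimum unpaired bases closing a hairpin loop (default 3).
#' @return Object of class `hairpin_call`: list with `sequence` (RNA),
#'   `dot_bracket`, `score`, `pseudo_energy` (= -score), `n_pairs`.
#' @examples
#' fold_hairpin("GGGAAACCC")  # (((...))) score 9
#' @export
fold_hairpin <- function(sequence, min_loop = 3) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("'sequence' must be a single string")
  seq_rna <- chartr("acgut", "ACGUU", chartr("T", "U", sequence))
  bases <- strsplit(seq_rna, "")[[1]]
  if (length(bases) && any(!bases %in% c("A", "C", "G", "U")))
    stop(sprintf("invalid character(s) in sequence: %s",
                 paste(unique(bases[!bases %in% c("A", "C", "G", "U")]),
                       collapse = ", ")))
  n <- length(bases)
  if (n < min_loop + 2) {
    return(structure(list(sequence = seq_rna,
                          dot_bracket = strrep(".", n),
                          score = 0, pseudo_energy = 0, n_pairs = 0L),
                     class = "hairpin_call"))
  }
  W <- pair_weights()[bases, bases, drop = FALSE]

  # M[i, j + 1] holds N[i, j], the best score on s[i..j]; M[i, i] = N[i, i-1] = 0
  M <- matrix(0, n, n + 1L)
  for (len in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - len)) {
      j <- i + len
      best <- M[i, j]                   # j unpaired: N[i, j-1]
      ks <- i:(j - min_loop - 1L)
      pk <- ks[W[ks, j] > 0]
      if (length(pk)) {
        cand <- M[i, pk] + M[cbind(pk + 1L, j)] + W[pk, j]
        best <- max(best, cand)
      }
      M[i, j + 1L] <- best
    }
  }

  db <- rep(".", n)
  n_pairs <- 0L
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i <= min_loop) next
    score <- M[i, j + 1L]
    if (score == M[i, j]) {             # j unpaired
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
      next
    }
    ks <- i:(j - min_loop - 1L)
    for (k in ks[W[ks, j] > 0]) {
      if (M[i, k] + M[k + 1L, j] + W[k, j] == score) {
        db[k] <- "("; db[j] <- ")"
        n_pairs <- n_pairs + 1L
        if (k - 1L >= i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
        stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
        break
      }
    }
  }
  score <- M[1, n + 1L]
  structure(list(sequence = seq_rna,
                 dot_bracket = paste(db, collapse = ""),
                 score = score, pseudo_energy = -score, n_pairs = n_pairs),
            class = "hairpin_call")
}

#' @export
print.hairpin_call <- function(x, ...) {
  cat(sprintf("<hairpin_call> %d nt, score %g (pseudo-energy %g), %d pairs\n",
              nchar(x$sequence), x$score, x$pseudo_energy, x$n_pairs))
  cat(x$sequence, "\n", x$dot_bracket, "\n", sep = "")
  invisible(x)
}

#' Fold and score candidate precursor windows against a reference hairpin
#'
#' Extracts each peak's 100-bp window sequence from the genome, folds it
#' with [fold_hairpin()], and flags candidates whose pairing score reaches
#' at least a fraction `phi` of the reference hairpin's score (default the
#' full reference score) — the reference playing the role of a known
#' precursor whose stability sets the bar. Output is sorted by score,
#' most stable first.
#'
#' @param peaks data.frame from [detect_broad_peaks()].
#' @param genome Sequences: a `mini_genome`, `DNAStringSet`, named character
#'   vector, or FASTA path.
#' @param reference_hairpin Reference RNA/DNA sequence whose folded score is
#'   the nomination threshold.
#' @param phi Fraction of the reference score required to pass (default 1).
#' @param min_loop Passed to [fold_hairpin()].
#' @return data.frame with the peak columns plus `sequence`, `dot_bracket`,
#'   `score`, `pseudo_energy`, `n_pairs`, `passes`.
#' @export
nominate_candidates <- function(peaks, genome, reference_hairpin,
                                phi = 1.0, min_loop = 3) {
  seqs <- if (inherits(genome, "mini_genome"))
    genome$sequences else as_dna_set(genome)
  ref <- fold_hairpin(reference_hairpin, min_loop = min_loop)
  if (!nrow(peaks)) {
    out <- peaks
    out$sequence <- character(0); out$dot_bracket <- character(0)
    out$score <- numeric(0); out$pseudo_energy <- numeric(0)
    out$n_pairs <- integer(0); out$passes <- logical(0)
    return(out)
  }
  calls <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    chrom <- peaks$chrom[i]
    if (!chrom %in% names(seqs))
      stop(sprintf("peak chromosome '%s' not in genome", chrom))
    L <- Biostrings::width(seqs)[match(chrom, names(seqs))]
    ws <- peaks$window_start[i]
    we <- peaks$window_end[i]
    if (we > L) {
      warning(sprintf("window %s:%d-%d clipped at chromosome end (%d bp)",
                      chrom, ws, we, L))
      we <- L
    }
    seq_chr <- as.character(Biostrings::subseq(seqs[[chrom]], ws + 1, we))
    calls[[i]] <- fold_hairpin(seq_chr, min_loop = min_loop)
  }
  out <- peaks
  out$sequence <- vapply(calls, `[[`, "", "sequence")
  out$dot_bracket <- vapply(calls, `[[`, "", "dot_bracket")
  out$score <- vapply(calls, `[[`, numeric(1), "score")
  out$pseudo_energy <- -out$score
  out$n_pairs <- vapply(calls, `[[`, integer(1), "n_pairs")
  out$passes <- out$score >= phi * ref$score
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fold with an external thermodynamic engine (optional adapter)
#'
#' Calls the `RNAfold` executable, if present on the PATH, to obtain a
#' nearest-neighbor minimum free energy structure in kcal/mol for a
#' sequence. This is an optional cross-check for candidates triaged by
#' [fold_hairpin()]; none of the package's own statistics depend on it.
#'
#' @param sequence RNA/DNA string.
#' @return list with `structure` (dot-bracket) and `mfe` (kcal/mol), or
#'   `NULL` (with a message) when `RNAfold` is unavailable.
#' @export
fold_hairpin_rnafold <- function(sequence) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    message("RNAfold not found on PATH; returning NULL")
    return(NULL)
  }
  out <- system2(exe, args = "--noPS", input = chartr("T", "U", sequence),
                 stdout = TRUE, stderr = FALSE)
  if (length(out) < 2) stop("unexpected RNAfold output")
  m <- regmatches(out[2],
                  regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\)", out[2]))[[1]]
  if (length(m) != 3L) stop("cannot parse RNAfold output line: ", out[2])
  list(structure = m[2], mfe = as.numeric(m[3]))
}
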