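# Independent brute-force oracles used to cross-check the detectors.

# Naive SSR scan: for every motif length and start position, count copies by
# stepping forward; keep maximal runs meeting the threshold whose motif is
# not a power of a shorter motif.  Deliberately position-by-position, unlike
# the package's regex scan.
oracle_ssrs <- function(seq, cfg = ssr_config()) {
  n <- nchar(seq)
  rows <- list()
  for (m in 1:6) {
    i <- 1L
    while (i + m - 1L <= n) {
      motif <- substr(seq, i, i + m - 1L)
      if (grepl("[^ACGT]", motif)) { i <- i + 1L; next }
      copies <- 1L
      while (substr(seq, i + copies * m, i + (copies + 1L) * m - 1L) == motif)
        copies <- copies + 1L
      if (copies >= cfg[m]) {
        ## maximal on the left?
        left <- if (i - m >= 1L) substr(seq, i - m, i - 1L) else ""
        power <- FALSE
        for (d in seq_len(m - 1L)) {
          if (m %% d == 0L &&
              strrep(substr(motif, 1L, d), m %/% d) == motif) power <- TRUE
        }
        if (left != motif && !power) {
          rows[[length(rows) + 1L]] <- data.frame(
            motif = motif, motif_len = m, copies = copies, start = i,
            end = i + copies * m - 1L)
        }
        i <- i + copies * m
      } else {
        i <- i + 1L
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(motif = character(0L), motif_len = integer(0L),
                         copies = integer(0L), start = integer(0L),
                         end = integer(0L))
  out <- out[order(out$start, out$motif_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Naive perfect-tandem scan: for each period and start, extend the span while
# s[x] == s[x + m]; keep maximal spans, then apply the same fundamental-period
# containment rule as the detector.
oracle_tandems <- function(seq, max_period = 500L, min_array_len = 25L) {
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(x)
  rows <- list()
  for (m in seq_len(min(max_period, n - 1L))) {
    i <- 1L
    while (i <= n - m) {
      if (x[i] == x[i + m]) {
        j <- i
        while (j <= n - m && x[j] == x[j + m]) j <- j + 1L
        span <- (j - i) + m
        if (span >= max(min_array_len, 2L * m)) {
          rows[[length(rows) + 1L]] <- data.frame(
            period = m, copies = span / m, start = i, end = i + span - 1L,
            array_len = span)
        }
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(period = integer(0L), copies = numeric(0L),
                      start = integer(0L), end = integer(0L),
                      array_len = integer(0L)))
  out <- do.call(rbind, rows)
  out <- out[order(out$period, out$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (i == 1L) next
    prior <- which(keep[seq_len(i - 1L)] &
                     out$period[seq_len(i - 1L)] < out$period[i])
    if (any(out$start[prior] <= out$start[i] &
              out$end[prior] >= out$end[i]))
      keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Pi oracle through ape: mean pairwise raw distance with the matching
# deletion rule (an independent implementation of the Nei-Li average).
oracle_pi_ape <- function(rows) {
  m <- do.call(rbind, strsplit(tolower(rows), "", fixed = TRUE))
  bin <- ape::as.DNAbin(m)
  d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE)
  mean(d, na.rm = TRUE)
}

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}
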