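## Repeat detection: microsatellites (SSRs), perfect tandem arrays, and
## dispersed forward/palindromic repeats.

#' SSR minimum-copy thresholds
#'
#' Default thresholds follow the common plastome setting: 10 copies for
#' mononucleotide motifs, 5 for di-, 4 for tri-, and 3 for tetra-, penta-
#' and hexanucleotide motifs.
#'
#' @param mono,di,tri,tetra,penta,hexa minimum copy number per motif length.
#' @return named integer vector of length 6 (element i = threshold for
#'   motif length i).
#' @export
ssr_config <- function(mono = 10L, di = 5L, tri = 4L, tetra = 3L,
                       penta = 3L, hexa = 3L) {
  cfg <- c(mono = mono, di = di, tri = tri, tetra = tetra, penta = penta,
           hexa = hexa)
  stopifnot(all(cfg >= 2L))
  as.integer(cfg)
}

## is motif a whole-number repetition of a shorter motif?
#' @noRd
is_motif_power <- function(motif) {
  m <- nchar(motif)
  if (m == 1L) return(FALSE)
  for (d in seq_len(m - 1L)) {
    if (m %% d != 0L) next
    if (strrep(substr(motif, 1L, d), m %/% d) == motif) return(TRUE)
  }
  FALSE
}

#' Find simple sequence repeats (microsatellites)
#'
#' Exhaustive left-to-right scan for maximal perfect repeat runs of motifs
#' of 1-6 bp meeting the per-motif-length copy thresholds.  Runs whose motif
#' is itself a repetition of a shorter motif are reported once, at the
#' shortest period.  Motifs are reported as they occur on the forward strand
#' at the run's leftmost phase.
#'
#' @param seq DNA string (or [plastome()]).
#' @param cfg thresholds from [ssr_config()].
#' @param ir optional `ir_partition` used to label each record with its
#'   region context (LSC/SSC/IR).
#' @return data frame with columns `motif`, `motif_len`, `copies`, `start`,
#'   `end`, and `region` (NA without `ir`), sorted by `start`.
#' @export
find_ssrs <- function(seq, cfg = ssr_config(), ir = NULL) {
  if (inherits(seq, "plastome")) seq <- seq$sequence
  stopifnot(nchar(seq) > 0L)
  rows <- list()
  for (m in 1:6) {
    need <- cfg[m]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", m, need - 1L)
    mt <- gregexpr(pat, seq, perl = TRUE)[[1L]]
    if (mt[1L] == -1L) next
    len <- attr(mt, "match.length")
    for (h in seq_along(mt)) {
      full_copies <- len[h] %/% m
      start <- as.integer(mt[h])
      motif <- substr(seq, start, start + m - 1L)
      if (is_motif_power(motif)) next
      rows[[length(rows) + 1L]] <- data.frame(
        motif = motif, motif_len = m, copies = full_copies,
        start = start, end = start + full_copies * m - 1L)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(motif = character(0L), motif_len = integer(0L),
                         copies = integer(0L), start = integer(0L),
                         end = integer(0L))
  out <- out[order(out$start, out$motif_len), , drop = FALSE]
  out$region <- if (is.null(ir)) rep(NA_character_, nrow(out)) else
    region_label(out$start, ir)
  rownames(out) <- NULL
  out
}

#' @noRd
region_label <- function(pos, ir) {
  L <- ir$genome_len
  vapply(pos, function(p) {
    if (circ_contains(ir$lsc, p, L)) "LSC"
    else if (circ_contains(ir$ssc, p, L)) "SSC"
    else "IR"
  }, character(1L))
}

#' Find perfect tandem repeat arrays
#'
#' Reports every maximal perfect tandem array with period up to
#' `max_period` and total array length of at least `min_array_len`
#' (fractional final copies count toward the array length).  Arrays that
#' are also SSRs (period <= 6) are still reported; arrays wholly contained
#' in an array of smaller period (e.g. the period-2 reading of a
#' homopolymer) are suppressed so each array is reported at its fundamental
#' period.
#'
#' @param seq DNA string (or [plastome()]).
#' @param max_period maximum period in bp (default 500).
#' @param min_array_len minimum total array length in bp (default 25).
#' @return data frame with `period`, `copies` (fractional), `start`, `end`,
#'   `array_len`, sorted by `start`.
#' @export
find_tandem_repeats <- function(seq, max_period = 500L, min_array_len = 25L) {
  if (inherits(seq, "plastome")) seq <- seq$sequence
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(x)
  rows <- list()
  for (m in seq_len(min(max_period, L - 1L))) {
    eq <- x[seq_len(L - m)] == x[(m + 1L):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & (r$lengths + m) >= max(min_array_len, 2L * m))
    for (i in keep) {
      span <- r$lengths[i] + m
      rows[[length(rows) + 1L]] <- data.frame(
        period = m, copies = span / m, start = starts[i],
        end = starts[i] + span - 1L, array_len = span)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(period = integer(0L), copies = numeric(0L),
                      start = integer(0L), end = integer(0L),
                      array_len = integer(0L)))
  out <- do.call(rbind, rows)
  out <- out[order(out$period, out$start), , drop = FALSE]
  ## fundamental-period dedup: drop arrays contained in a smaller-period array
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (i == 1L) next
    prior <- which(keep[seq_len(i - 1L)] & out$period[seq_len(i - 1L)] < out$period[i])
    if (any(out$start[prior] <= out$start[i] & out$end[prior] >= out$end[i]))
      keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find dispersed (forward and palindromic) repeats
#'
#' Reports maximal exact repeated pairs of length at least `min_len`, on the
#' same strand (`forward`) or between the forward strand and the reverse
#' complement (`palindromic`).  Copies must not overlap.  When an
#' `ir_partition` is supplied, pairs whose two copies each lie at least 90%
#' within the annotated IRs (the IRb/IRa self-match) are excluded.
#'
#' @param seq DNA string (or [plastome()]).
#' @param ir optional `ir_partition` for IR-pair exclusion.
#' @param min_len minimum repeat length in bp (default 30).
#' @return data frame with `kind`, `length`, `pos1`, `pos2`, `identity`.
#' @export
find_dispersed_repeats <- function(seq, ir = NULL, min_len = 30L) {
  if (inherits(seq, "plastome")) seq <- seq$sequence
  L <- nchar(seq)
  k <- as.integer(min_len)
  empty <- data.frame(kind = character(0L), length = integer(0L),
                      pos1 = integer(0L), pos2 = integer(0L),
                      identity = numeric(0L))
  if (L < k) return(empty)
  km_f <- kmers(seq, k)
  rows <- list()

  ## ---- forward pairs: duplicate k-mers within the forward strand ----
  o <- order(km_f, method = "radix")
  so <- km_f[o]
  r <- rle(so)
  ends <- cumsum(r$lengths)
  grp_ii <- integer(0L); grp_jj <- integer(0L)
  for (g in which(r$lengths >= 2L & r$lengths <= 200L)) {
    pos <- sort(o[(ends[g] - r$lengths[g] + 1L):ends[g]])
    pr <- utils::combn(pos, 2L)
    grp_ii <- c(grp_ii, pr[1L, ]); grp_jj <- c(grp_jj, pr[2L, ])
  }
  if (length(grp_ii) > 0L) {
    d <- grp_jj - grp_ii
    for (dv in unique(d)) {
      us <- sort(unique(grp_ii[d == dv]))
      runs <- split(us, cumsum(c(1L, diff(us) != 1L)))
      for (run in runs) {
        i0 <- run[1L]
        len <- run[length(run)] - i0 + k
        j0 <- i0 + dv
        if (j0 < i0 + len) next  # overlapping copies (tandem territory)
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "forward", length = len, pos1 = i0, pos2 = j0,
          identity = 1)
      }
    }
  }

  ## ---- palindromic pairs: forward strand vs reverse complement ----
  rc <- revcomp(seq)
  hits <- positions_of(km_f, kmers(rc, k), cap = 200L)
  n_hits <- lengths(hits)
  if (sum(n_hits) > 0L) {
    ii <- rep(seq_along(km_f), n_hits)
    jj <- unlist(hits)
    d <- jj - ii
    for (dv in unique(d)) {
      us <- sort(unique(ii[d == dv]))
      runs <- split(us, cumsum(c(1L, diff(us) != 1L)))
      for (run in runs) {
        i0 <- run[1L]
        len <- run[length(run)] - i0 + k
        j0 <- i0 + dv
        pos2 <- L - j0 - len + 2L
        if (pos2 <= i0) next          # mirror duplicate (or self-overlap)
        if (pos2 < i0 + len) next     # overlapping copies
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "palindromic", length = len, pos1 = i0, pos2 = pos2,
          identity = 1)
      }
    }
  }

  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- unique(out)
  if (!is.null(ir)) {
    in_ir <- function(pos, len) {
      iv1 <- ir$irb; iv2 <- ir$ira
      ov <- function(iv) {
        ## overlap of [pos, pos+len-1] with circular interval iv
        s <- iv[1L]; e <- if (iv[2L] >= iv[1L]) iv[2L] else iv[2L] + L
        a <- pos; b <- pos + len - 1L
        max(0L, min(b, e) - max(a, s) + 1L) +
          max(0L, min(b, e - L) - max(a, s - L) + 1L)
      }
      (ov(iv1) + ov(iv2)) / len >= 0.9
    }
    drop <- vapply(seq_len(nrow(out)), function(i)
      in_ir(out$pos1[i], out$length[i]) && in_ir(out$pos2[i], out$length[i]),
      logical(1L))
    out <- out[!drop, , drop = FALSE]
  }
  out <- out[order(out$pos1, out$pos2), , drop = FALSE]
  rownames(out) <- NULL
  out
}
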