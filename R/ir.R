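## Inverted-repeat detection and the quadripartite partition.
##
## The IR pair is found by an internal maximal reverse-complement repeat
## search: shared k-mers between the (doubled, to honour circularity) genome
## and its reverse complement are chained along antidiagonals, merged across
## small gaps (substitutions), extended exactly at both ends, and scored by
## per-base identity.  Candidate copy lengths are constrained to a window
## (18-32 kb by default) and the longest qualifying pair defines the
## partition LSC-IRb-SSC-IRa.

#' @noRd
abort_cond <- function(class, msg, data = NULL) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1L), data = data)))
}

## circular interval length for 1-based inclusive (start, end) on a circle
#' @noRd
circ_len <- function(start, end, L) ((end - start) %% L) + 1L

#' Detect the inverted-repeat pair and partition the genome
#'
#' @param seq circular genome DNA string (or a [plastome()]).
#' @param min_len,max_len admissible IR copy length window in bp
#'   (defaults 18000 and 32000).
#' @param min_identity identity floor for the two copies (default 0.995).
#' @param k seed k-mer length (default 31).
#' @param stride seed sampling stride along the genome (default 7).
#' @return an `ir_partition`: list with `lsc`, `irb`, `ssc`, `ira` (each
#'   `c(start, end)`, 1-based inclusive, `start > end` meaning the interval
#'   wraps the origin), `junctions` (named vector JLB/JSB/JSA/JLA, each the
#'   coordinate of the last base of the upstream region), `identity`, and
#'   `genome_len`.
#' @export
detect_inverted_repeats <- function(seq, min_len = 18000L, max_len = 32000L,
                                    min_identity = 0.995, k = 31L,
                                    stride = 7L) {
  if (inherits(seq, "plastome")) seq <- seq$sequence
  L <- nchar(seq)
  if (L <= 2L * min_len)
    stop("genome length ", L, " too short for IR copies of >= ", min_len,
         " bp")
  S2 <- paste0(seq, seq)
  s2c <- strsplit(S2, "", fixed = TRUE)[[1L]]
  RC2 <- revcomp(S2)
  L2 <- 2L * L

  is <- seq(1L, L2 - k + 1L, by = stride)
  hits <- positions_of(substring(S2, is, is + k - 1L), kmers(RC2, k),
                       cap = 32L)
  n_hits <- lengths(hits)
  if (sum(n_hits) == 0L)
    abort_cond("plastidkit_no_ir", "no inverted repeat found (no seed matches)")
  ii <- rep(is, n_hits)
  jj <- unlist(hits)
  ## match S2[i..] == RC2[j..]  =>  S2[u] pairs with comp(S2[M - u]),
  ## M = i - j + 2L + 1 constant along a match (antidiagonal id)
  M <- ii - jj + L2 + 1L

  cands <- list()
  groups <- split(ii, M)
  for (mi in seq_along(groups)) {
    m <- as.integer(names(groups)[mi])
    us <- sort(unique(groups[[mi]]))
    runs <- split(us, cumsum(c(1L, diff(us) > 300L)))
    for (run in runs) {
      u1 <- run[1L]
      u2 <- run[length(run)] + k - 1L
      if (u2 - u1 + 1L < min_len %/% 2L) next
      ## exact extension at both ends
      while (u1 > 1L && m - u1 + 1L <= L2 &&
             s2c[u1 - 1L] == comp_chars(s2c[m - u1 + 1L])) u1 <- u1 - 1L
      while (u2 < L2 && m - u2 - 1L >= 1L &&
             s2c[u2 + 1L] == comp_chars(s2c[m - u2 - 1L])) u2 <- u2 + 1L
      len <- u2 - u1 + 1L
      if (len < min_len || len > max_len) next
      ident <- mean(s2c[u1:u2] == comp_chars(s2c[m - (u1:u2)]))
      if (ident < min_identity) next
      ## the two copies in circular coordinates
      a1 <- ((u1 - 1L) %% L) + 1L
      b1 <- ((m - u2 - 1L) %% L) + 1L
      copy1 <- c(a1, ((a1 + len - 2L) %% L) + 1L)
      copy2 <- c(b1, ((b1 + len - 2L) %% L) + 1L)
      if (!circ_disjoint(copy1, copy2, L)) next
      key <- paste(min(a1, b1), max(a1, b1), len)
      if (!is.null(cands[[key]])) next
      cands[[key]] <- list(copy1 = copy1, copy2 = copy2, len = len,
                           identity = ident)
    }
  }
  if (length(cands) == 0L)
    abort_cond("plastidkit_no_ir", sprintf(
      "no inverted-repeat pair with copy length in [%d, %d] bp at identity >= %g",
      min_len, max_len, min_identity))
  lens <- vapply(cands, `[[`, numeric(1L), "len")
  best_len <- max(lens)
  best <- cands[lens == best_len]
  if (length(best) > 1L)
    abort_cond("plastidkit_ambiguous_ir", paste0(
      "multiple non-overlapping inverted-repeat pairs of maximal length ",
      best_len, " bp: ", paste(names(best), collapse = "; ")),
      data = best)
  build_ir_partition(best[[1L]], L)
}

## are two circular intervals (start, end; wrapping allowed) disjoint?
#' @noRd
circ_disjoint <- function(a, b, L) {
  expand <- function(iv) {
    if (iv[1L] <= iv[2L]) list(iv) else list(c(iv[1L], L), c(1L, iv[2L]))
  }
  for (x in expand(a)) for (y in expand(b)) {
    if (x[1L] <= y[2L] && y[1L] <= x[2L]) return(FALSE)
  }
  TRUE
}

#' @noRd
build_ir_partition <- function(cand, L) {
  ## single-copy gaps: after copy1 up to copy2, and after copy2 up to copy1
  gap_after <- function(a_end, b_start) {
    len <- (b_start - a_end - 1L) %% L
    list(start = ((a_end) %% L) + 1L,
         end = ((a_end + len - 1L) %% L) + 1L, len = len)
  }
  g1 <- gap_after(cand$copy1[2L], cand$copy2[1L])
  g2 <- gap_after(cand$copy2[2L], cand$copy1[1L])
  if (g1$len == 0L || g2$len == 0L)
    abort_cond("plastidkit_no_ir",
               "candidate repeat copies are adjacent; no single-copy regions")
  ## IRb is the copy whose downstream single-copy neighbour is the shorter gap
  if (g1$len < g2$len) {
    irb <- cand$copy1; ssc <- c(g1$start, g1$end)
    ira <- cand$copy2; lsc <- c(g2$start, g2$end)
  } else {
    irb <- cand$copy2; ssc <- c(g2$start, g2$end)
    ira <- cand$copy1; lsc <- c(g1$start, g1$end)
  }
  junctions <- c(JLB = lsc[2L], JSB = irb[2L], JSA = ssc[2L], JLA = ira[2L])
  structure(list(lsc = lsc, irb = irb, ssc = ssc, ira = ira,
                 junctions = junctions, identity = cand$identity,
                 genome_len = L),
            class = "ir_partition")
}

#' @export
print.ir_partition <- function(x, ...) {
  L <- x$genome_len
  cat("<ir_partition>", L, "bp\n")
  for (r in c("lsc", "irb", "ssc", "ira")) {
    iv <- x[[r]]
    cat(sprintf("  %-4s %7d..%-7d (%s bp)%s\n", toupper(r), iv[1L], iv[2L],
                format(circ_len(iv[1L], iv[2L], L), big.mark = ","),
                if (iv[1L] > iv[2L]) " [wraps origin]" else ""))
  }
  cat("  junctions:",
      paste(names(x$junctions), x$junctions, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Extract a region's sequence given the partition
#'
#' @param seq genome DNA string (or [plastome()]).
#' @param ir an `ir_partition`.
#' @param region one of `"lsc"`, `"irb"`, `"ssc"`, `"ira"`.
#' @return DNA string of the region along the forward strand.
#' @export
region_sequence <- function(seq, ir, region = c("lsc", "irb", "ssc", "ira")) {
  if (inherits(seq, "plastome")) seq <- seq$sequence
  region <- match.arg(region)
  iv <- ir[[region]]
  circ_substr(seq, iv[1L], iv[2L])
}

#' Partition table as a data frame
#'
#' @param ir an `ir_partition`.
#' @param sample_id optional id column.
#' @return data frame with region, start, end, length.
#' @export
ir_partition_table <- function(ir, sample_id = NA_character_) {
  regions <- c("lsc", "irb", "ssc", "ira")
  data.frame(sample_id = sample_id,
             region = toupper(regions),
             start = vapply(regions, function(r) ir[[r]][1L], integer(1L)),
             end = vapply(regions, function(r) ir[[r]][2L], integer(1L)),
             length = vapply(regions, function(r)
               circ_len(ir[[r]][1L], ir[[r]][2L], ir$genome_len), integer(1L)),
             row.names = NULL)
}
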