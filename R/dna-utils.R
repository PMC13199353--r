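#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement; `N` maps to `N`.
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                   collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

#' @noRd
comp_chars <- function(v) chartr("ACGTN", "TGCAN", v)

## Uppercase and collapse IUPAC ambiguity codes (other than N) to N.
#' @noRd
sanitize_dna <- function(s, warn = TRUE) {
  s <- toupper(s)
  if (grepl("[^ACGTN]", s)) {
    n_bad <- sum(strsplit(s, "", fixed = TRUE)[[1L]] %in%
                   c("A", "C", "G", "T", "N") == FALSE)
    if (warn) {
      warning(sprintf("%d ambiguity/non-ACGTN character(s) converted to N",
                      n_bad), call. = FALSE)
    }
    s <- gsub("[^ACGTN]", "N", s)
  }
  s
}

## Circular 1-based substring: positions may wrap past the end.
#' @noRd
circ_substr <- function(seq, start, end) {
  L <- nchar(seq)
  start <- ((start - 1L) %% L) + 1L
  end <- ((end - 1L) %% L) + 1L
  if (start <= end) substr(seq, start, end)
  else paste0(substr(seq, start, L), substr(seq, 1L, end))
}

## Circular rotation so that position `offset + 1` becomes position 1.
#' @noRd
rotate_seq <- function(seq, offset) {
  L <- nchar(seq)
  offset <- offset %% L
  if (offset == 0L) return(seq)
  paste0(substr(seq, offset + 1L, L), substr(seq, 1L, offset))
}

## All k-mers of a string as a character vector (positions 1..L-k+1).
#' @noRd
kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0L))
  starts <- seq_len(L - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

## For each element of `query`, the integer positions of all occurrences of
## that value in `subject`, as a list (sort-based grouping; no hashing of
## duplicate values beyond a single match()).  Values with multiplicity in
## `subject` above `cap` yield integer(0) (low-complexity guard).
#' @noRd
positions_of <- function(query, subject, cap = Inf) {
  o <- order(subject, method = "radix")
  so <- subject[o]
  r <- rle(so)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- match(query, r$values)
  lapply(seq_along(query), function(i) {
    j <- idx[i]
    if (is.na(j)) return(integer(0L))
    if (r$lengths[j] > cap) return(integer(0L))
    o[starts[j]:ends[j]]
  })
}

## Random DNA of given length with target GC content, using only integer
## draws so that synthesis is reproducible.
#' @noRd
random_dna <- function(n, gc = 0.36) {
  ## approximate gc by an integer weighting out of 1000
  w_gc <- as.integer(round(gc * 500))
  w_at <- 500L - w_gc
  bases <- c("A", "T", "G", "C")
  paste(sample(bases, n, replace = TRUE,
               prob = c(w_at, w_at, w_gc, w_gc)), collapse = "")
}
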