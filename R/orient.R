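## Orientation and start-position normalization against a reference genome.
##
## Assemblers emit circular organelle genomes in an arbitrary orientation and
## rotation.  Both are fixed here by anchor matching against an annotated
## reference: exact k-mer sharing decides the strand, and a k-mer vote over
## the reference's leading window locates the start.

#' Choose the forward orientation of an assembly
#'
#' Compares the fraction of exact k-mers shared with the reference between
#' the input sequence and its reverse complement and returns whichever
#' orientation shares more.
#'
#' @param seq DNA string to orient.
#' @param ref reference [plastome()] (or a plain DNA string).
#' @param k anchor length in bp (default 21).
#' @param min_share minimum shared-anchor fraction below which the sequence is
#'   considered unrelated to the reference (default 0.05).
#' @return list with `sequence` (oriented string) and `report`, a one-row
#'   data frame with `flipped`, `rotation_offset` (0 here) and
#'   `anchor_identity` (shared fraction for the chosen orientation).
#' @export
orient_to_reference <- function(seq, ref, k = 21L, min_share = 0.05) {
  ref_seq <- if (inherits(ref, "plastome")) ref$sequence else ref
  stopifnot(nchar(seq) > 0L, nchar(ref_seq) > 0L)
  seq <- sanitize_dna(seq, warn = FALSE)
  ref_k <- unique(kmers(ref_seq, k))
  share <- function(s) {
    km <- kmers(s, k)
    if (length(km) == 0L) return(0)
    mean(km %in% ref_k)
  }
  fwd <- share(seq)
  rc_seq <- revcomp(seq)
  rev <- share(rc_seq)
  if (max(fwd, rev) < min_share)
    stop(sprintf(paste0("orientation ambiguous: neither strand shares >= %g ",
                        "of %d-mers with the reference (forward %.3f, ",
                        "reverse %.3f)"), min_share, k, fwd, rev))
  flipped <- rev > fwd
  list(sequence = if (flipped) rc_seq else seq,
       report = data.frame(flipped = flipped, rotation_offset = 0L,
                           anchor_identity = max(fwd, rev)))
}

#' Rotate a forward-oriented assembly to the reference start position
#'
#' Locates the best match of the reference's leading anchor (first
#' `anchor_len` bp) in the circular input by k-mer offset voting, verifies it
#' by direct comparison, and rotates the sequence so that the matched
#' position becomes position 1.  Rotation is a pure circular permutation.
#'
#' @param seq forward-oriented DNA string.
#' @param ref reference [plastome()] (or plain DNA string).
#' @param anchor_len leading-anchor length in bp (default 500).
#' @param k voting k-mer length (default 21).
#' @param min_identity minimum per-base identity of the anchor at the chosen
#'   offset (default 0.8); below it the sequence is returned unrotated with a
#'   warning and `warning_flag = TRUE` in the report.
#' @return list with `sequence` and `report` (columns `flipped` = FALSE,
#'   `rotation_offset`, `anchor_identity`, `warning_flag`).
#' @export
rotate_to_reference_start <- function(seq, ref, anchor_len = 500L, k = 21L,
                                      min_identity = 0.8) {
  ref_seq <- if (inherits(ref, "plastome")) ref$sequence else ref
  stopifnot(nchar(seq) > 0L, nchar(ref_seq) >= anchor_len)
  seq <- sanitize_dna(seq, warn = FALSE)
  L <- nchar(seq)
  anchor <- substr(ref_seq, 1L, anchor_len)
  doubled <- paste0(seq, substr(seq, 1L, anchor_len))

  ## offset vote: each anchor k-mer found in the doubled target votes for the
  ## rotation that would place the anchor start at that k-mer's position
  akm <- kmers(anchor, k)
  hits <- positions_of(akm, kmers(doubled, k), cap = 50L)
  votes <- integer(0L)
  for (i in seq_along(hits)) {
    if (length(hits[[i]]) == 0L) next
    votes <- c(votes, ((hits[[i]] - i) %% L))
  }
  fail <- function(msg) {
    warning(msg, call. = FALSE)
    list(sequence = seq,
         report = data.frame(flipped = FALSE, rotation_offset = 0L,
                             anchor_identity = 0, warning_flag = TRUE))
  }
  if (length(votes) == 0L)
    return(fail("no anchor k-mer matches; sequence returned unrotated"))
  tab <- table(votes)
  best <- as.integer(names(tab)[which.max(tab)])   # ties: smallest offset
  window <- substr(doubled, best + 1L, best + anchor_len)
  ident <- mean(strsplit(window, "", fixed = TRUE)[[1L]] ==
                  strsplit(anchor, "", fixed = TRUE)[[1L]])
  if (ident < min_identity)
    return(fail(sprintf(
      "best anchor match identity %.2f below %.2f; sequence returned unrotated",
      ident, min_identity)))
  list(sequence = rotate_seq(seq, best),
       report = data.frame(flipped = FALSE, rotation_offset = best,
                           anchor_identity = ident, warning_flag = FALSE))
}

#' Normalize a batch of assemblies against a reference
#'
#' Applies [orient_to_reference()] then [rotate_to_reference_start()] to each
#' sequence and collects a per-sample orientation report.
#'
#' @param seqs named character vector of DNA strings.
#' @param ref reference [plastome()].
#' @param ... passed to the two steps.
#' @return list with `sequences` (named character vector) and `report`
#'   (data frame: sample_id, flipped, rotation_offset, anchor_identity).
#' @export
normalize_assemblies <- function(seqs, ref, ...) {
  out <- character(length(seqs))
  names(out) <- names(seqs)
  rep_rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    o <- orient_to_reference(seqs[[i]], ref, ...)
    r <- rotate_to_reference_start(o$sequence, ref)
    out[i] <- r$sequence
    rep_rows[[i]] <- data.frame(sample_id = names(seqs)[i],
                                flipped = o$report$flipped,
                                rotation_offset = r$report$rotation_offset,
                                anchor_identity = o$report$anchor_identity)
  }
  list(sequences = out, report = do.call(rbind, rep_rows))
}
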