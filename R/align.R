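## Multiple alignment of one homologous region across samples.
##
## The default path shells out to an external aligner (mafft) when one is
## available; otherwise a deterministic built-in star alignment is used:
## every sequence is globally aligned to the longest sequence (affine gaps,
## match +1 / mismatch -1 / gap open 5 / gap extend 1) and the pairwise gap
## patterns are merged into one master profile.  Either way, ungapping any
## output row reproduces that sample's input sequence exactly.

#' Align one region group
#'
#' @param group named character vector (sample -> raw region sequence), or a
#'   group entry from [group_regions_by_reference()].
#' @param method `"auto"` (external aligner if found, else built-in),
#'   `"mafft"`, or `"builtin"`.
#' @param aligner path to the external aligner executable (default: `mafft`
#'   found on the PATH).
#' @param name,kind carried into the result.
#' @return object of class `aligned_region`: list with `name`, `kind`,
#'   `rows` (named character vector of equal-length gapped sequences) and
#'   `aligned_len`.
#' @export
align_region <- function(group, method = c("auto", "mafft", "builtin"),
                         aligner = getOption("plastidkit.aligner",
                                             Sys.which("mafft")),
                         name = NA_character_, kind = NA_character_) {
  method <- match.arg(method)
  if (is.list(group) && !is.null(group$sequences)) {
    if (is.na(name)) name <- group$name
    if (is.na(kind)) kind <- group$kind
    group <- group$sequences
  }
  empty <- nchar(group) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty sequence(s): ",
            paste(names(group)[empty], collapse = ", "), call. = FALSE)
    group <- group[!empty]
  }
  if (length(group) < 2L)
    stop("alignment needs at least 2 non-empty sequences")
  use_mafft <- switch(method,
                      mafft = TRUE,
                      builtin = FALSE,
                      auto = nzchar(aligner) && file.exists(aligner))
  rows <- if (length(unique(group)) == 1L) {
    group            # identical sequences align to themselves
  } else if (use_mafft) {
    align_mafft(group, aligner)
  } else {
    align_star(group)
  }
  structure(list(name = name, kind = kind, rows = rows,
                 aligned_len = nchar(rows[[1L]])),
            class = "aligned_region")
}

#' @export
print.aligned_region <- function(x, ...) {
  cat(sprintf("<aligned_region> %s [%s]: %d rows x %d columns\n",
              x$name, x$kind, length(x$rows), x$aligned_len))
  invisible(x)
}

#' Remove gap characters from alignment rows
#'
#' @param x an `aligned_region` or character vector of gapped sequences.
#' @return named character vector of ungapped sequences.
#' @export
ungap <- function(x) {
  rows <- if (inherits(x, "aligned_region")) x$rows else x
  gsub("-", "", rows, fixed = TRUE)
}

#' @noRd
align_mafft <- function(group, aligner) {
  tmp_in <- tempfile(fileext = ".fa")
  on.exit(unlink(tmp_in), add = TRUE)
  ## safe ids: sequence order is preserved by mafft
  ids <- sprintf("s%06d", seq_along(group))
  writeLines(paste0(">", ids, "\n", unname(group)), tmp_in)
  out <- suppressWarnings(
    system2(aligner, c("--quiet", "--retree", "2", tmp_in), stdout = TRUE,
            stderr = FALSE))
  if (length(out) == 0L || !any(startsWith(out, ">")))
    stop("external aligner '", aligner, "' produced no alignment")
  hdr <- grep("^>", out)
  stopifnot(length(hdr) == length(group))
  rows <- vapply(seq_along(hdr), function(i) {
    to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(out)
    toupper(paste(out[(hdr[i] + 1L):to], collapse = ""))
  }, character(1L))
  names(rows) <- names(group)[match(sub("^>", "", out[hdr]), ids)]
  rows[names(group)]
}

#' @noRd
align_star <- function(group) {
  n <- length(group)
  center_i <- which.max(nchar(group))
  center <- group[[center_i]]
  nc <- nchar(center)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  others <- setdiff(seq_len(n), center_i)
  ## per-slot insertion counts: slot p = gap columns before center base p+1
  ## (slot 0 = before the first base, slot nc = after the last)
  ins <- matrix(0L, nrow = n, ncol = nc + 1L)
  aligned_other <- vector("list", n)
  for (i in others) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(center), Biostrings::DNAString(group[[i]]),
      type = "global", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 1)
    ca <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1L]]
    sa <- strsplit(as.character(Biostrings::subject(pa)), "")[[1L]]
    ## bucket subject characters by center slot
    slot <- cumsum(ca != "-")          # 0 while before first center base
    slot_of_col <- ifelse(ca == "-", slot, slot - 1L)  # insertions go to slot
    ## count insertions per slot
    ins_cols <- which(ca == "-")
    if (length(ins_cols) > 0L) {
      tab <- table(slot[ins_cols])
      ins[i, as.integer(names(tab)) + 1L] <- as.integer(tab)
    }
    aligned_other[[i]] <- list(ca = ca, sa = sa, slot = slot)
  }
  master <- apply(ins, 2L, max)
  build_row <- function(chars_by_slot) {
    ## chars_by_slot: list of length nc+1; slot p then center base p (p>=1)
    out <- character(0L)
    for (p in 0:nc) {
      ext <- chars_by_slot$slots[[p + 1L]]
      pad <- master[p + 1L] - length(ext)
      out <- c(out, ext, rep("-", pad),
               if (p < nc) chars_by_slot$base[p + 1L])
    }
    paste(out, collapse = "")
  }
  rows <- character(n)
  ## center row: no insertions of its own
  center_chars <- strsplit(center, "")[[1L]]
  rows[center_i] <- build_row(list(
    slots = rep(list(character(0L)), nc + 1L), base = center_chars))
  for (i in others) {
    al <- aligned_other[[i]]
    slots <- rep(list(character(0L)), nc + 1L)
    base <- rep("-", nc)
    for (col in seq_along(al$ca)) {
      if (al$ca[col] == "-") {
        p <- al$slot[col]
        slots[[p + 1L]] <- c(slots[[p + 1L]], al$sa[col])
      } else {
        base[al$slot[col]] <- al$sa[col]
      }
    }
    rows[i] <- build_row(list(slots = slots, base = base))
  }
  names(rows) <- names(group)
  rows
}
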