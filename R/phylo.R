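## Concatenated CDS supermatrix and trait mapping onto a tree.

#' Build a concatenated CDS supermatrix
#'
#' Concatenates per-gene alignments in the given (reference genomic) order.
#' Samples missing a gene receive an all-gap block for that partition.
#'
#' @param aligned_genes list of `aligned_region` objects (CDS groups), in
#'   the order the partitions should appear.
#' @param samples character vector of sample ids defining the row set and
#'   order; default: the union of row names across genes, in first-seen
#'   order.
#' @return object of class `supermatrix`: list with `samples`, `matrix`
#'   (named character vector sample -> concatenated gapped sequence) and
#'   `partitions` (data frame gene, start, end in 1-based concatenated
#'   coordinates).
#' @export
build_supermatrix <- function(aligned_genes, samples = NULL) {
  keep <- vapply(aligned_genes, function(a) length(a$rows) > 0L, logical(1L))
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " gene group(s) with no rows",
            call. = FALSE)
    aligned_genes <- aligned_genes[keep]
  }
  stopifnot(length(aligned_genes) > 0L)
  if (is.null(samples))
    samples <- unique(unlist(lapply(aligned_genes, function(a)
      names(a$rows))))
  mat <- setNames(rep("", length(samples)), samples)
  parts <- list()
  pos <- 0L
  for (a in aligned_genes) {
    w <- a$aligned_len
    block <- setNames(rep(strrep("-", w), length(samples)), samples)
    present <- intersect(samples, names(a$rows))
    block[present] <- unname(a$rows[present])
    mat <- paste0(mat, block)
    names(mat) <- samples
    parts[[length(parts) + 1L]] <- data.frame(
      gene = a$name, start = pos + 1L, end = pos + w)
    pos <- pos + w
  }
  structure(list(samples = samples, matrix = mat,
                 partitions = do.call(rbind, parts)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d samples x %d columns, %d partitions\n",
              length(x$samples), nchar(x$matrix[[1L]]), nrow(x$partitions)))
  invisible(x)
}

#' Write a supermatrix as FASTA plus a RAxML-style partition file
#'
#' @param sm a `supermatrix`.
#' @param fasta_path output FASTA path.
#' @param partition_path output partition file path (lines
#'   `DNA, gene = start-end`); omitted if NULL.
#' @return `fasta_path`, invisibly.
#' @export
write_supermatrix <- function(sm, fasta_path, partition_path = NULL) {
  write_fasta(sm$matrix, fasta_path)
  if (!is.null(partition_path)) {
    writeLines(sprintf("DNA, %s = %d-%d", sm$partitions$gene,
                       sm$partitions$start, sm$partitions$end),
               partition_path)
  }
  invisible(fasta_path)
}

#' Annotate tree tips with trait labels
#'
#' Suffixes each tip label with `|<label>`; topology and branch lengths are
#' preserved byte-for-byte (the newick text is edited in place, not
#' re-serialized).  Traits naming non-existent tips are ignored with a
#' warning; tips without a trait are labelled with `unknown_label` when it
#' is non-NULL, else left unchanged.
#'
#' @param newick newick string (or path to a newick file).
#' @param traits named character vector tip -> trait label.
#' @param unknown_label optional label for tips missing from `traits`.
#' @return annotated newick string.
#' @export
annotate_tree_tips <- function(newick, traits, unknown_label = NULL) {
  if (length(newick) == 1L && !grepl("(", newick, fixed = TRUE) &&
      file.exists(newick))
    newick <- paste(readLines(newick, warn = FALSE), collapse = "")
  tree <- ape::read.tree(text = newick)
  if (is.null(tree)) stop("could not parse newick input")
  tips <- tree$tip.label
  missing <- setdiff(names(traits), tips)
  if (length(missing) > 0L)
    warning("trait labels for non-existent tip(s) ignored: ",
            paste(missing, collapse = ", "), call. = FALSE)
  out <- newick
  for (tip in tips) {
    lab <- if (tip %in% names(traits)) traits[[tip]]
           else if (!is.null(unknown_label)) unknown_label
           else next
    pat <- paste0("(?<=[(,])", escape_regex(tip), "(?=[:,)])")
    out <- sub(pat, paste0(tip, "|", lab), out, perl = TRUE)
  }
  out
}

#' @noRd
escape_regex <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)
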