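## GenBank flat-file reading and writing.
##
## Only the subset of the grammar that annotated organelle records use is
## supported: LOCUS, FEATURES with location strings built from `n..m`,
## `join(...)` and `complement(...)` (partial-end markers `<`/`>` are
## stripped), qualifiers `/gene=` and `/product=`, and ORIGIN sequence blocks.

#' Read an annotated GenBank flat file
#'
#' Parses one GenBank record into a [plastome()].  Every feature carrying a
#' `/gene` or `/product` qualifier is captured; multi-interval `join`
#' locations are preserved in translation order (a `complement(join(...))`
#' is normalized to its reverse-ordered minus-strand intervals); locations
#' that cross the circular origin are split into intervals within `[1, L]`
#' and flagged `spans_origin`.
#'
#' @param path path to a GenBank flat file.
#' @param sample_id sample identifier; default is the file base name.
#' @return a [plastome()].
#' @export
read_genbank <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (is.null(sample_id))
    sample_id <- sub("\\.(gb|gbk|genbank)$", "", basename(path))

  locus <- grep("^LOCUS", lines)
  if (length(locus) == 0L)
    stop("not a GenBank flat file (no LOCUS line): ", path)

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) == 0L)
    stop("GenBank record in '", path, "' has no ORIGIN sequence")
  end_i <- grep("^//", lines)
  if (length(end_i) == 0L) end_i <- length(lines) + 1L

  ## --- sequence ---
  if (orig_i[1L] + 1L > end_i[1L] - 1L)
    stop("empty sequence in GenBank record: ", path)
  seq_lines <- lines[(orig_i[1L] + 1L):(end_i[1L] - 1L)]
  seq <- paste(gsub("[0-9 ]", "", seq_lines), collapse = "")
  if (nchar(seq) == 0L) stop("empty sequence in GenBank record: ", path)
  seq <- sanitize_dna(seq)
  L <- nchar(seq)

  ## --- feature table ---
  features <- list()
  if (length(feat_i) > 0L) {
    ftab <- lines[(feat_i[1L] + 1L):(orig_i[1L] - 1L)]
    ## feature headers have the key at column 6; qualifier/continuation lines
    ## are indented further
    is_hdr <- grepl("^ {5}\\S", ftab)
    hdr_idx <- which(is_hdr)
    for (h in seq_along(hdr_idx)) {
      i0 <- hdr_idx[h]
      i1 <- if (h < length(hdr_idx)) hdr_idx[h + 1L] - 1L else length(ftab)
      block <- ftab[i0:i1]
      key <- sub("^ {5}(\\S+).*", "\\1", block[1L])
      if (key == "source") next
      ## location may continue over lines until the first qualifier line
      qual_start <- grep("^ +/", block)
      loc_end <- if (length(qual_start)) qual_start[1L] - 1L else length(block)
      loc <- paste(gsub(" ", "", c(sub("^ {5}\\S+ +", "", block[1L]),
                                   if (loc_end >= 2L) trimws(block[2:loc_end]))),
                   collapse = "")
      quals <- parse_qualifiers(block[seq_len(length(block)) > loc_end])
      name <- quals[["gene"]] %||% quals[["product"]]
      if (is.null(name)) next
      kind <- if (key %in% c("CDS", "tRNA", "rRNA", "gene")) key else "other"
      parsed <- tryCatch(parse_location(loc, L), error = function(e)
        stop("record '", sample_id, "': bad location for ", key, " '", name,
             "': ", conditionMessage(e)))
      features[[length(features) + 1L]] <-
        feature(name, kind, parsed$intervals, parsed$spans_origin)
    }
  }
  plastome(sample_id, seq, features, source_path = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## split "a,b,join(c,d)" on commas outside parentheses
#' @noRd
split_top_level <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  cut <- which(chars == "," & depth == 0L)
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(chars))
  mapply(function(a, b) paste(chars[a:b], collapse = ""), starts, ends)
}

#' @noRd
parse_qualifiers <- function(lines) {
  out <- list()
  cur_key <- NULL
  for (ln in lines) {
    m <- regmatches(ln, regexec("^ +/([A-Za-z_]+)=?(.*)$", ln))[[1L]]
    if (length(m) == 3L) {
      cur_key <- m[2L]
      out[[cur_key]] <- gsub("\"", "", m[3L])
    } else if (!is.null(cur_key)) {
      out[[cur_key]] <- paste0(out[[cur_key]], gsub("\"", "", trimws(ln)))
    }
  }
  out
}

## Parse a GenBank location string into translation-order intervals.
## Returns list(intervals = matrix(start,end,strand), spans_origin = flag).
#' @noRd
parse_location <- function(loc, genome_len) {
  loc <- gsub("[<>]", "", loc)
  parse_node <- function(s, strand) {
    if (grepl("^complement\\(", s)) {
      inner <- sub("^complement\\((.*)\\)$", "\\1", s)
      ## complement(join(a,b)) == join(complement(b), complement(a))
      return(rev_rows(parse_node(inner, -strand)))
    }
    if (grepl("^join\\(", s) || grepl("^order\\(", s)) {
      inner <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
      parts <- split_top_level(inner)
      return(do.call(rbind, lapply(parts, function(p) parse_node(p, strand))))
    }
    m <- regmatches(s, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", s))[[1L]]
    if (length(m) == 0L) stop("unsupported location syntax: '", s, "'")
    a <- as.integer(m[2L])
    b <- if (m[4L] == "") a else as.integer(m[4L])
    matrix(c(a, b, strand), nrow = 1L)
  }
  rev_rows <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]

  iv <- parse_node(loc, 1L)
  spans_origin <- FALSE
  out <- NULL
  for (r in seq_len(nrow(iv))) {
    a <- iv[r, 1L]; b <- iv[r, 2L]; st <- iv[r, 3L]
    if (a > b) { # single span written across the origin, e.g. 146900..50
      spans_origin <- TRUE
      seg <- rbind(c(a, genome_len, st), c(1L, b, st))
      if (st < 0L) seg <- rev_rows(seg)
      out <- rbind(out, seg)
    } else {
      out <- rbind(out, c(a, b, st))
    }
  }
  ## adjacent intervals wrapping L -> 1 also indicate an origin-crossing span
  if (nrow(out) >= 2L) {
    for (r in seq_len(nrow(out) - 1L)) {
      pair <- out[c(r, r + 1L), , drop = FALSE]
      if (pair[1L, 3L] > 0L && pair[1L, 2L] == genome_len && pair[2L, 1L] == 1L)
        spans_origin <- TRUE
      if (pair[1L, 3L] < 0L && pair[1L, 1L] == 1L && pair[2L, 2L] == genome_len)
        spans_origin <- TRUE
    }
  }
  colnames(out) <- c("start", "end", "strand")
  list(intervals = out, spans_origin = spans_origin)
}

## Render translation-order intervals back into a GenBank location string.
#' @noRd
format_location <- function(f) {
  iv <- f$intervals
  strand <- iv[1L, "strand"]
  if (strand < 0L) iv <- iv[rev(seq_len(nrow(iv))), , drop = FALSE]
  spans <- sprintf("%d..%d", iv[, "start"], iv[, "end"])
  s <- if (length(spans) > 1L) paste0("join(", paste(spans, collapse = ","), ")")
       else spans
  if (strand < 0L) s <- paste0("complement(", s, ")")
  s
}

#' Write a plastome as a GenBank flat file
#'
#' Emits a minimal circular-DNA GenBank record (LOCUS, FEATURES with `/gene`
#' qualifiers, ORIGIN) that [read_genbank()] round-trips with identical
#' feature coordinates.
#'
#' @param p a [plastome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(p, path) {
  L <- nchar(p$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     circular PLN %s",
                     p$sample_id, L, format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s chloroplast, complete genome.",
                     p$sample_id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  writeLines(sprintf("                     /organism=\"%s\"", p$sample_id), con)
  for (f in p$features) {
    key <- if (f$kind == "other") "misc_feature" else f$kind
    writeLines(sprintf("     %-15s %s", key, format_location(f)), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$name), con)
  }
  writeLines("ORIGIN", con)
  starts <- seq(1L, L, by = 60L)
  for (s in starts) {
    chunk <- substr(p$sequence, s, min(s + 59L, L))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", s, tolower(paste(blocks, collapse = " "))),
               con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA path.
#' @return named character vector of uppercase sequences; names are the
#'   record ids truncated at the first whitespace (FASTA convention).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  out <- toupper(as.character(x))
  names(out) <- ids
  out
}

#' Write a FASTA file
#'
#' Sequences are wrapped at 70 columns.  Duplicate ids are an error.
#'
#' @param records named character vector (or list) of DNA strings.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- unlist(records)
  if (anyDuplicated(names(records)))
    stop("duplicate FASTA ids: ",
         paste(unique(names(records)[duplicated(names(records))]),
               collapse = ", "))
  if (length(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
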