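test_that("read_genbank captures simple, joined and origin-crossing CDS", {
  p <- read_genbank(write_gb_text(c(
    "     CDS             10..18",
    "                     /gene=\"g1\"")))
  expect_length(p$features, 1L)
  expect_equal(unname(p$features[[1L]]$intervals[1L, ]), c(10L, 18L, 1L))
  expect_false(p$features[[1L]]$spans_origin)

  p <- read_genbank(write_gb_text(c(
    "     CDS             join(10..15,40..45)",
    "                     /gene=\"g2\"")))
  iv <- p$features[[1L]]$intervals
  expect_equal(nrow(iv), 2L)
  expect_equal(unname(iv[, "start"]), c(10L, 40L))

  ## complement(join) crossing the origin of a 100 bp circle
  p <- read_genbank(write_gb_text(c(
    "     CDS             complement(join(95..100,1..6))",
    "                     /gene=\"g3\"")))
  f <- p$features[[1L]]
  expect_true(f$spans_origin)
  expect_true(all(f$intervals[, "start"] >= 1L & f$intervals[, "end"] <= 100L))
  expect_true(all(f$intervals[, "strand"] == -1L))
  ## translation order: the low segment is read first on the minus strand
  expect_equal(unname(f$intervals[1L, c("start", "end")]), c(1L, 6L))
})

test_that("read_genbank rejects files without sequence or LOCUS", {
  bad <- tempfile()
  writeLines(c("LOCUS       x 10 bp", "FEATURES", "ORIGIN", "//"), bad)
  expect_error(read_genbank(bad), "sequence")
  writeLines(c("not a genbank file"), bad)
  expect_error(read_genbank(bad), "LOCUS")
  expect_error(read_genbank(tempfile()), "no such file")
})

test_that("GenBank write/read round trip preserves features and sequence", {
  p <- fixture_plastome()$plastome
  f <- tempfile(fileext = ".gb")
  write_genbank(p, f)
  p2 <- read_genbank(f, sample_id = p$sample_id)
  expect_identical(p2$sequence, p$sequence)
  expect_length(p2$features, length(p$features))
  expect_identical(lapply(p2$features, `[[`, "intervals"),
                   lapply(p$features, `[[`, "intervals"))
  expect_identical(vapply(p2$features, `[[`, character(1L), "name"),
                   vapply(p$features, `[[`, character(1L), "name"))
})

test_that("FASTA round trip is exact, ids truncate at whitespace, dup ids fail", {
  f <- tempfile(fileext = ".fa")
  recs <- c(a = strrep("ACGT", 40L), b = "ACGTN", c = strrep("GGCC", 60L))
  write_fasta(recs, f)
  expect_identical(read_fasta(f), recs)
  ## 70-column wrapping
  expect_true(all(nchar(readLines(f)) <= 70L))

  writeLines(c(">id with spaces", "ACGT"), f)
  expect_identical(names(read_fasta(f)), "id")

  expect_error(write_fasta(c(a = "ACGT", a = "GGGG"), f), "duplicate")

  write_fasta(character(0L), f)
  expect_identical(length(read_fasta(f)), 0L)
})

test_that("orientation chooses the strand sharing more anchors", {
  p <- fixture_plastome()$plastome
  o <- orient_to_reference(p$sequence, p)
  expect_false(o$report$flipped)
  expect_equal(o$report$anchor_identity, 1.0)

  o2 <- orient_to_reference(revcomp(p$sequence), p)
  expect_true(o2$report$flipped)
  expect_identical(o2$sequence, p$sequence)

  ## 1% substitutions must not flip the call
  set.seed(42)
  ch <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
  idx <- sample.int(length(ch), round(length(ch) * 0.01))
  ch[idx] <- vapply(ch[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
  o3 <- orient_to_reference(paste(ch, collapse = ""), p)
  expect_false(o3$report$flipped)

  ## unrelated sequence is an error
  set.seed(7)
  expect_error(orient_to_reference(random_seq(5000L), p), "ambiguous")
})

test_that("orientation is stable under repetition", {
  p <- fixture_plastome()$plastome
  o1 <- orient_to_reference(revcomp(p$sequence), p)
  o2 <- orient_to_reference(o1$sequence, p)
  expect_false(o2$report$flipped)
  expect_identical(o2$sequence, o1$sequence)
})

test_that("rotation recovers the reference start and is a pure permutation", {
  p <- fixture_plastome()$plastome
  r <- rotate_to_reference_start(rotate_seq(p$sequence, 100L), p)
  expect_identical(r$sequence, p$sequence)
  expect_equal(r$report$rotation_offset %% nchar(p$sequence),
               (nchar(p$sequence) - 100L) %% nchar(p$sequence))

  r0 <- rotate_to_reference_start(p$sequence, p)
  expect_equal(r0$report$rotation_offset, 0L)

  ## 0.5% substitutions on a rotated copy: start recovered exactly
  set.seed(9)
  ch <- strsplit(rotate_seq(p$sequence, 12345L), "", fixed = TRUE)[[1L]]
  idx <- sample.int(length(ch), round(length(ch) * 0.005))
  ch[idx] <- vapply(ch[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
  mutated <- paste(ch, collapse = "")
  r2 <- rotate_to_reference_start(mutated, p)
  expect_equal(r2$report$rotation_offset %% nchar(p$sequence),
               (nchar(p$sequence) - 12345L) %% nchar(p$sequence))

  ## length and base multiset preserved
  expect_identical(sort(strsplit(r2$sequence, "")[[1L]]),
                   sort(strsplit(mutated, "")[[1L]]))

  ## unrelated sequence: warning and unrotated return
  set.seed(10)
  junk <- random_seq(3000L)
  expect_warning(r3 <- rotate_to_reference_start(junk, p), "unrotated")
  expect_true(r3$report$warning_flag)
  expect_identical(r3$sequence, junk)
})
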