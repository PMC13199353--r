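# Shared fixtures: a default synthetic plastome is expensive enough to build
# once per test run.

fixture_env <- new.env()

fixture_plastome <- function(seed = 101L) {
  key <- paste0("p", seed)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- make_plastome(seed = seed)
  fixture_env[[key]]
}

fixture_population <- function(seed = 202L, n = 6L, ...) {
  key <- paste0("pop", seed, "_", n)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- make_population(fixture_plastome(), n = n,
                                          seed = seed, ...)
  fixture_env[[key]]
}

# minimal hand-built plastome: explicit sequence + features
mini_plastome <- function(seq, features, id = "mini") {
  plastome(id, seq, features)
}

# write a small GenBank text and return its path
write_gb_text <- function(lines, seq_len = 100L,
                          seq = strrep("ACGTACGTAC", seq_len %/% 10L)) {
  stopifnot(nchar(seq) %% 60L == 0L || nchar(seq) < 60L ||
              nchar(seq) %% 10L == 0L)
  path <- tempfile(fileext = ".gb")
  orig <- vapply(seq(1L, nchar(seq), by = 60L), function(s) {
    chunk <- substr(seq, s, min(s + 59L, nchar(seq)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    sprintf("%9d %s", s, tolower(paste(blocks, collapse = " ")))
  }, character(1L))
  writeLines(c(sprintf("LOCUS       mini %d bp DNA circular", nchar(seq)),
               "FEATURES             Location/Qualifiers",
               sprintf("     source          1..%d", nchar(seq)),
               lines, "ORIGIN", orig, "//"), path)
  path
}
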