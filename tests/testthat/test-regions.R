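test_that("naming rules reproduce the worked examples byte-exactly", {
  p <- standardize_feature_names(fixture_plastome()$plastome)
  unit_names <- vapply(plastidkit:::select_units(p), `[[`, character(1L),
                       "name")
  ## fragmented gene: parts numbered in genomic order
  expect_true("rps12_part1" %in% unit_names)
  expect_true("rps12_part2" %in% unit_names)
  ## duplicated fragment: copy suffix
  expect_true("rps12_part2_copy1" %in% unit_names)
  ## nested genes: merged unit, left name first
  expect_true("trnH-UGU-merge-matK" %in% unit_names)
  ## plain IR duplicates
  expect_true(all(c("ycf2", "ycf2_copy1") %in% unit_names))
  ## standard names retained untouched
  expect_true(all(c("psbA", "rbcL", "matK") %in%
                    c(unit_names, "matK")))
  expect_false(any(grepl("^psbA_", unit_names)))
})

test_that("merge threshold boundary: 9 bp spacer merges, 10 bp does not", {
  mk <- function(gap) {
    plastome("m", strrep("ACGT", 500L),
             list(feature("g1", "gene", c(101L, 200L, 1L)),
                  feature("g2", "gene", c(201L + gap, 300L + gap, 1L))))
  }
  u9 <- vapply(plastidkit:::select_units(standardize_feature_names(mk(9L))),
               `[[`, character(1L), "name")
  expect_true("g1-merge-g2" %in% u9)
  u10 <- vapply(plastidkit:::select_units(standardize_feature_names(mk(10L))),
                `[[`, character(1L), "name")
  expect_identical(sort(u10), c("g1", "g2"))
})

test_that("IGS extraction: simple gap, merged units, circular gap", {
  p <- plastome("x", strrep("ACGT", 250L),
                list(feature("g1", "gene", c(1L, 100L, 1L)),
                     feature("g2", "gene", c(151L, 300L, 1L))))
  rs <- extract_regions(standardize_feature_names(p))
  igs <- rs$regions[rs$regions$kind == "IGS", ]
  expect_true(any(igs$name == "g1-g2" & igs$start == 101L &
                    igs$end == 150L & igs$length == 50L))

  ## overlapping units merge; no IGS between them
  p2 <- plastome("x", strrep("ACGT", 250L),
                 list(feature("g1", "gene", c(1L, 100L, 1L)),
                      feature("g2", "gene", c(90L, 200L, 1L))))
  rs2 <- extract_regions(standardize_feature_names(p2))
  expect_false(any(rs2$regions$name == "g1-g2" &
                     rs2$regions$kind == "IGS"))
  expect_true("g1-merge-g2" %in% rs2$regions$name)

  ## circular gap: last unit ends L-20, first starts 31 -> 50 bp IGS
  p3 <- plastome("x", strrep("ACGT", 250L),
                 list(feature("g1", "gene", c(31L, 200L, 1L)),
                      feature("g2", "gene", c(800L, 980L, 1L))))
  rs3 <- extract_regions(standardize_feature_names(p3))
  circ <- rs3$regions[rs3$regions$name == "g2-g1", ]
  expect_equal(nrow(circ), 1L)
  expect_equal(circ$length, 50L)
  expect_equal(circ$start, 981L)
  expect_equal(circ$end, 30L)
  expect_equal(nchar(circ$sequence), 50L)
})

test_that("every base is assigned exactly once at the gene-unit level", {
  for (q in list(fixture_plastome()$plastome,
                 fixture_population()$plastomes[[1L]])) {
    rs <- extract_regions(standardize_feature_names(q))
    expect_equal(sum(rs$regions$length), nchar(q$sequence))
  }
})

test_that("reference grouping collects shared regions and flags extras", {
  pop <- fixture_population()
  sets <- lapply(pop$plastomes, function(q)
    extract_regions(standardize_feature_names(q)))
  ref_id <- pop$manifest$samples$sample_id[1L]
  gr <- group_regions_by_reference(unname(sets), ref_sample = ref_id)
  n_per_group <- vapply(gr$groups, function(g) length(g$sequences),
                        integer(1L))
  ## sample 6 carries the insertion, so its ndhA-ndhH neighbourhood is
  ## renamed and missing from those reference groups
  expect_true(all(n_per_group >= 5L))
  sv <- gr$structural_variants
  expect_true(all(sv$sample_id == pop$manifest$samples$sample_id[6L]))
  expect_true("ndhA-ndhH" %in% sv$name)
  expect_equal(sv$length[sv$name == "ndhA-ndhH"], 108L)

  ## identical samples: all groups full, no structural variants
  pop0 <- make_population(fixture_plastome(), n = 3L, sub_rate = 0,
                          n_diagnostic = 0L, indel_events = list(),
                          seed = 5L)
  sets0 <- lapply(pop0$plastomes, function(q)
    extract_regions(standardize_feature_names(q)))
  gr0 <- group_regions_by_reference(unname(sets0))
  expect_true(all(vapply(gr0$groups, function(g) length(g$sequences),
                         integer(1L)) == 3L))
  expect_equal(nrow(gr0$structural_variants), 0L)

  expect_error(group_regions_by_reference(unname(sets), "nope"),
               "not among")
})

test_that("built-in alignment: gap-free on identical input, clean indels, exact ungap", {
  g <- c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAC")
  a <- align_region(g, method = "builtin")
  expect_equal(a$aligned_len, 10L)
  expect_false(any(grepl("-", a$rows, fixed = TRUE)))

  ## a 5 bp deletion gives exactly one 5-column gap block in that row
  set.seed(21)
  base <- random_seq(200L)
  del <- paste0(substr(base, 1L, 100L), substr(base, 106L, 200L))
  a2 <- align_region(c(x = base, y = del, z = base), method = "builtin")
  expect_identical(unname(ungap(a2)), unname(c(x = base, y = del, z = base)))
  gaps <- gregexpr("-+", a2$rows[["y"]])[[1L]]
  expect_equal(length(gaps), 1L)
  expect_equal(attr(gaps, "match.length"), 5L)
  expect_false(grepl("-", a2$rows[["x"]], fixed = TRUE))

  ## empty sequences are dropped with a warning
  expect_warning(a3 <- align_region(c(a = base, b = del, c = ""),
                                    method = "builtin"), "empty")
  expect_equal(length(a3$rows), 2L)
  expect_error(suppressWarnings(align_region(c(a = base, b = ""))),
               "at least 2")
})

test_that("external aligner path also ungaps to the exact inputs", {
  skip_if(Sys.which("mafft") == "", "mafft not on PATH")
  set.seed(22)
  base <- random_seq(300L)
  mut <- paste0(substr(base, 1L, 150L), "TTTTT", substr(base, 151L, 300L))
  g <- c(a = base, b = mut, c = base)
  a <- align_region(g, method = "mafft")
  expect_identical(unname(ungap(a)), unname(g))
})

test_that("Pi matches hand-enumerated pairwise comparisons", {
  expect_equal(nucleotide_diversity(c(a = "AAAAAAAAAA", b = "AAAAAAAAAC")),
               0.1)
  rows <- c(r = "AAAAAAAAAA", s = "CAAAAAAAAA", t = "AAAAAAAAAC")
  ## pairs: (r,s)=0.1, (r,t)=0.1, (s,t)=0.2 -> mean = 0.4/3
  expect_equal(nucleotide_diversity(rows), (0.1 + 0.1 + 0.2) / 3)
  expect_equal(count_snps(rows), 2L)
  expect_equal(nucleotide_diversity(c(a = "ACGT", b = "ACGT", c = "ACGT")), 0)
  expect_error(nucleotide_diversity(c(a = "ACGT")), "fewer than 2")
})

test_that("gap and N columns are ignored as states", {
  rows <- c(a = "AA-GN", b = "AAAGA", c = "AA-GA")
  ## column 3 has one base only; column 5 pairs: (a,b) skip, (b,c) equal
  expect_equal(count_snps(rows), 0L)
  expect_equal(nucleotide_diversity(rows), 0)
  rows2 <- c(a = "AA-G", b = "AACG", c = "AATG")
  expect_equal(count_snps(rows2), 1L)  # column 3: C vs T among bases
})

test_that("Pi agrees with an independent distance-based computation", {
  set.seed(90)
  for (i in 1:10) {
    n <- sample(3:12, 1L)
    len <- sample(50:300, 1L)
    base <- strsplit(random_seq(len), "")[[1L]]
    rows <- vapply(seq_len(n), function(j) {
      ch <- base
      k <- sample.int(len, sample(0:8, 1L))
      ch[k] <- sample(c("A", "C", "G", "T", "-"), length(k), replace = TRUE)
      paste(ch, collapse = "")
    }, character(1L))
    names(rows) <- paste0("s", seq_len(n))
    expect_equal(nucleotide_diversity(rows), oracle_pi_ape(rows),
                 tolerance = 1e-12)
  }
})

test_that("pairwise and complete deletion agree on gap-free alignments", {
  set.seed(91)
  base <- strsplit(random_seq(400L), "")[[1L]]
  rows <- vapply(1:6, function(j) {
    ch <- base
    k <- sample.int(400L, 5L)
    ch[k] <- sample(c("A", "C", "G", "T"), 5L, replace = TRUE)
    paste(ch, collapse = "")
  }, character(1L))
  names(rows) <- paste0("s", 1:6)
  expect_equal(nucleotide_diversity(rows, deletion = "pairwise"),
               nucleotide_diversity(rows, deletion = "complete"))
  ## and on gap-free alignments pi == 0 iff snp_count == 0
  expect_equal(nucleotide_diversity(rows) == 0, count_snps(rows) == 0L)
})

test_that("length polymorphism flags the 106 bp expansion pattern", {
  lens <- c(s1 = 2, s2 = 2, s3 = 2, s4 = 108)
  lp <- length_polymorphism(lens, delta = 50L)
  expect_equal(lp$raw_len_min, 2)
  expect_equal(lp$raw_len_max, 108)
  expect_equal(lp$expansions$sample_id, "s4")
  expect_equal(lp$expansions$delta_bp, 106)

  expect_equal(nrow(length_polymorphism(c(a = 5, b = 5, c = 5))$expansions),
               0L)
  ## deviations below the threshold are not flagged
  expect_equal(nrow(length_polymorphism(c(a = 10, b = 10, c = 40),
                                        delta = 50L)$expansions), 0L)
})

test_that("diagnostic sites: exact recovery, no variation, polymorphic group", {
  pop <- fixture_population()
  labs <- setNames(pop$manifest$samples$group,
                   pop$manifest$samples$sample_id)
  ## rps15 carries the planted group-fixed sites and no indels
  rps15 <- lapply(pop$plastomes, function(q) {
    cds <- extract_cds_sequences(q)
    cds[names(cds) == "rps15"][[1L]]
  })
  a <- align_region(unlist(rps15), method = "builtin")
  ds <- find_diagnostic_sites(a, labs)
  expect_equal(ds$column, pop$manifest$expected_diagnostic_columns)
  expect_true(all(ds$perfect))
  ## with a reference row, columns map to ungapped reference positions
  ds2 <- find_diagnostic_sites(a, labs, ref_row = names(labs)[1L])
  expect_equal(ds2$ref_position, ds2$column)  # gap-free alignment

  rows <- c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT")
  expect_equal(nrow(find_diagnostic_sites(
    rows, c(a = "G1", b = "G1", c = "G2", d = "G2"))), 0L)

  ## fixed in one group, polymorphic in the other: not diagnostic
  rows2 <- c(a = "AAAA", b = "AAAA", c = "CAAA", d = "GAAA")
  expect_equal(nrow(find_diagnostic_sites(
    rows2, c(a = "G1", b = "G1", c = "G2", d = "G2"))), 0L)

  expect_error(find_diagnostic_sites(rows, c(a = "G1", b = "G1")),
               "2 non-empty groups")
})

test_that("diversity table integrates the per-region measures", {
  pop <- fixture_population()
  sets <- lapply(pop$plastomes, function(q)
    extract_regions(standardize_feature_names(q)))
  gr <- group_regions_by_reference(unname(sets),
                                   pop$manifest$samples$sample_id[1L])
  small <- gr$groups[vapply(gr$groups, function(g)
    max(g$lengths) <= 1600L, logical(1L))]
  dt <- diversity_table(small, method = "builtin")
  expect_true(all(dt$pi >= 0 & dt$pi <= 1))
  expect_true(all((dt$pi == 0) == (dt$snp_count == 0L)))
  expect_true(all(dt$n >= 2L))
  expect_true(all(dt$aligned_len >= dt$raw_len_max))
})
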