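test_that("genotype matrix validates codes, dimensions and uniqueness", {
  calls <- matrix(c("II", "ID", "DD", "MISSING"), 2, 2,
                  dimnames = list(c("s1", "s2"), c("L1", "L2")))
  gm <- genotype_matrix(calls, populations = c("a", "a"))
  expect_equal(gm$calls[2, 2], NA_character_)
  expect_equal(n_samples(gm), 2)
  expect_equal(n_loci(gm), 2)

  expect_error(genotype_matrix(matrix("XX", 1, 1), "a"), "invalid genotype")
  expect_error(
    genotype_matrix(matrix("II", 2, 1, dimnames = list(c("s", "s"), "L")),
                    c("a", "a")),
    "duplicate sample")
  expect_error(genotype_matrix(calls, populations = "a"),
               "one population label per sample")
})

test_that("delimited genotype tables round-trip exactly", {
  gm <- simulate_hwe_population(10, runif(5, 0.2, 0.8), seed = 11)
  gm$calls[3, 2] <- NA  # inject a missing call
  for (dialect in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_genotype_table(gm, path, dialect)
    back <- read_genotype_table(path, dialect)
    expect_identical(back$calls, gm$calls)
    expect_identical(back$populations, gm$populations)
  }
})

test_that("GenePop dialect maps two-digit codes and round-trips", {
  path <- withr::local_tempfile()
  writeLines(c("title", "locA", "locB", "POP",
               "s1 , 0102 0101", "s2 , 0000 0202"), path)
  gm <- read_genotype_table(path, "genepop")
  expect_equal(unname(gm$calls["s1", ]), c("ID", "II"))
  expect_equal(unname(gm$calls["s2", ]), c(NA, "DD"))

  gm2 <- simulate_balding_nichols(c(4, 5), L = 3, fst_target = 0.1,
                                  seed = 3)
  out <- withr::local_tempfile()
  write_genotype_table(gm2, out, "genepop")
  back <- read_genotype_table(out, "genepop")
  expect_identical(unname(back$calls), unname(gm2$calls))
  # populations are renamed pop1..popK but grouping must be preserved
  expect_equal(as.integer(table(back$populations)[unique(back$populations)]),
               c(4L, 5L))

  bad <- withr::local_tempfile()
  writeLines(c("t", "locA", "POP", "s1 , 0301"), bad)
  expect_error(read_genotype_table(bad, "genepop"), "unknown allele code")
})

test_that("frequency tables validate range and round-trip to 6 decimals", {
  ft <- freq_table(matrix(c(0.123456789, 0.5, 1, 0), 2, 2,
                          dimnames = list(c("p1", "p2"), c("L1", "L2"))),
                   sample_size = c(p1 = 10L, p2 = 20L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_freq_table(ft, path)
  back <- read_freq_table(path)
  expect_lt(max(abs(back$freq - ft$freq)), 5e-7)
  expect_identical(dimnames(back$freq), dimnames(ft$freq))
  expect_equal(back$sample_size, ft$sample_size)

  bad <- withr::local_tempfile()
  writeLines(c("population,L1", "p1,1.5"), bad)
  expect_error(read_freq_table(bad), "outside")
  expect_error(freq_table(matrix(-0.1, 1, 1)), "\\[0, 1\\]")
})

test_that("a single published-scale frequency row parses to 30 loci", {
  ref <- dipplex_panel_freqs()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste(c("population", ref$locus), collapse = ","),
               paste(c("dongxiang", ref$p_ins), collapse = ",")), path)
  ft <- read_freq_table(path)
  expect_equal(ncol(ft$freq), 30)
  expect_equal(unname(ft$freq["dongxiang", "HLD 77"]), 0.4586)
})

test_that("PHYLIP writer emits taxon count header and handles long labels", {
  dm <- as_distance_matrix(matrix(0, 3, 3),
                           labels = c("A", "B", "C"))
  path <- withr::local_tempfile()
  write_phylip_distance(dm, path)
  lines <- readLines(path)
  expect_length(lines, 4)
  expect_equal(as.integer(trimws(lines[1])), 3)

  long <- as_distance_matrix(matrix(0, 2, 2),
                             labels = c("averylongpopulationname1",
                                        "averylongpopulationname2"))
  expect_warning(write_phylip_distance(long, path), "truncating")
  labs <- substr(readLines(path)[-1], 1, 10)
  expect_false(any(duplicated(labs)))
})

test_that("Newick write/read is a fixed point and stars serialise", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  path <- withr::local_tempfile()
  write_newick(star, path)
  txt1 <- readLines(path)
  expect_match(txt1, "^\\(.*\\);$")
  back <- read_newick(path)
  write_newick(back, path)
  expect_identical(readLines(path), txt1)
  expect_setequal(back$tip.label, c("A", "B", "C"))
})

test_that("distance matrix validation rejects malformed input", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(as_distance_matrix(m), "symmetric")
  m2 <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_error(as_distance_matrix(m2), "diagonal")
  ok <- as_distance_matrix(matrix(c(0, 3, 3, 0), 2, 2),
                           labels = c("x", "y"))
  expect_s3_class(ok, "distance_matrix")
})

test_that("population utilities subset and recombine faithfully", {
  gm <- simulate_balding_nichols(c(6, 4), L = 5, fst_target = 0.1, seed = 8)
  sub <- subset_populations(gm, "pop2")
  expect_equal(n_samples(sub), 4)
  expect_error(subset_populations(gm, "nope"), "unknown population")
  ft <- population_freqs(gm)
  expect_equal(dim(ft$freq), c(2L, 5L))
  expect_true(all(ft$freq >= 0 & ft$freq <= 1))
  # frequencies recompute from dosages
  d <- dosage_matrix(subset_populations(gm, "pop1"))
  expect_equal(unname(ft$freq["pop1", ]),
               unname(colSums(d) / (2 * nrow(d))))
})
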