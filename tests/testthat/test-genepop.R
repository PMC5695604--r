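# Genepop dialect reading/writing and STRUCTURE export.

test_that("write/read round-trips genotypes exactly", {
  af <- simulate_allele_frequencies(5, 4, 0.1, 2, seed = 31)
  g1 <- hwe_geno(af[[1]], 12); g2 <- hwe_geno(af[[2]], 9)
  rownames(g1) <- sprintf("a%02d", 1:12)
  rownames(g2) <- sprintf("b%02d", 1:9)
  g1[2, 1:2] <- NA                      # missing genotype survives
  path <- tempfile(fileext = ".gen")
  write_genepop(list(A = g1, B = g2), path)
  back <- read_genepop(path, pop_names = c("A", "B"))
  expect_identical(back$A, g1)
  expect_identical(back$B, g2)
  # default population labels: last sample id per block
  back2 <- read_genepop(path)
  expect_named(back2, c("a12", "b09"))
})

test_that("2-digit and 3-digit dialects decode correctly", {
  txt2 <- c("title line", "locA", "locB", "Pop",
            "ind1 , 0101 0000", "ind2 , 0102 0203")
  f2 <- tempfile(); writeLines(txt2, f2)
  g <- read_genepop(f2)[[1]]
  expect_equal(unname(g["ind1", ]), c(1L, 1L, NA, NA))
  expect_equal(unname(g["ind2", ]), c(1L, 2L, 2L, 3L))

  txt3 <- c("t", "locA", "Pop", "x , 120124")
  f3 <- tempfile(); writeLines(txt3, f3)
  g3 <- read_genepop(f3)[[1]]
  expect_equal(unname(g3["x", ]), c(120L, 124L))
})

test_that("malformed files and oversized alleles are rejected", {
  bad <- c("t", "locA", "locB", "Pop", "ind1 , 0101")
  fb <- tempfile(); writeLines(bad, fb)
  expect_error(read_genepop(fb), "expected 2")
  g <- geno1(list(c(1000, 1002)))
  expect_error(write_genepop(list(a = g), tempfile()), "re-encode")
})

test_that("STRUCTURE export writes two rows per individual", {
  g <- hwe_geno(simulate_allele_frequencies(3, 3, 0, 1,
                                            seed = 5)[[1]], 4)
  rownames(g) <- sprintf("i%d", 1:4)
  p <- tempfile()
  write_structure(list(a = g), p)
  lines <- readLines(p)
  expect_length(lines, 1 + 8)
  expect_match(lines[2], "^i1\t1\t")
})
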