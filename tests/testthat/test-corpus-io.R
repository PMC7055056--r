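test_that("long and wide dialects read equivalently and round-trip", {
  long <- tempfile(fileext = ".tsv")
  writeLines(c("sample\ttaxon\tcount", "s1\ttA\t3", "s1\ttB\t1", "s2\ttA\t2"),
             long)
  tt_long <- read_taxon_table(long, dialect = "long")
  expect_equal(dim(tt_long), c(2L, 2L))
  expect_equal(unname(sample_totals(tt_long)), c(4, 2))

  wide <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttA\ttB", "s1\t3\t1", "s2\t2\t0"), wide)
  tt_wide <- read_taxon_table(wide, dialect = "wide")
  expect_equal(as.matrix(tt_wide$counts), as.matrix(tt_long$counts))

  # auto-detection: 3 columns -> long, otherwise wide (a 2-taxon wide file
  # is ambiguous, so a 3-taxon fixture exercises the wide branch)
  expect_equal(as.matrix(read_taxon_table(long)$counts),
               as.matrix(tt_long$counts))
  wide3 <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttA\ttB\ttC", "s1\t3\t1\t2", "s2\t2\t0\t5"), wide3)
  expect_equal(unname(as.matrix(read_taxon_table(wide3)$counts)),
               rbind(c(3, 1, 2), c(2, 0, 5)))

  # write-then-read reproduces counts exactly, both dialects (a 2-taxon
  # wide file has 3 columns, so the dialect is passed explicitly)
  for (dialect in c("long", "wide")) {
    out <- tempfile(fileext = ".tsv")
    write_taxon_table(tt_long, out, dialect = dialect)
    expect_equal(as.matrix(read_taxon_table(out, dialect = dialect)$counts),
                 as.matrix(tt_long$counts))
  }
})

test_that("malformed input is rejected with the offending row", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample\ttaxon\tcount", "s1\ttA\t3", "s1\ttA\t1"), f)
  expect_error(read_taxon_table(f, dialect = "long"),
               "duplicate \\(sample, taxon\\) pair at data row 2")

  writeLines(c("sample\ttaxon\tcount", "s1\ttA\t3", "s2\ttB\t-2"), f)
  expect_error(read_taxon_table(f, dialect = "long"),
               "invalid count at data row 2")

  writeLines(c("sample\ttaxon\tcount", "s1\ttA\t1.5"), f)
  expect_error(read_taxon_table(f, dialect = "long"), "invalid count")

  writeLines(c("id\ttA\ttB", "s1\t3\t-1"), f)
  expect_error(read_taxon_table(f, dialect = "wide"),
               "invalid count at data row 1")

  expect_error(taxon_table(matrix(c(1, 2, 3, 4), 2,
                                  dimnames = list(c("a", "a"), NULL))),
               "duplicate sample")
  expect_error(taxon_table(matrix(0.5, 1, 1)), "integers")
})

test_that("zero-total samples are dropped with a warning", {
  m <- rbind(s1 = c(tA = 3, tB = 1), s2 = c(tA = 0, tB = 0))
  expect_warning(tt <- taxon_table(m), "zero total")
  expect_equal(sample_ids(tt), "s1")
})

test_that("to_incidence thresholds counts and flags empty taxa", {
  tt <- taxon_table(rbind(s1 = c(tA = 3, tB = 0), s2 = c(tA = 1, tB = 2)))
  inc1 <- to_incidence(tt, threshold = 1)
  expect_equal(as.matrix(inc1$presence),
               rbind(s1 = c(tA = 1, tB = 0), s2 = c(tA = 1, tB = 1)))
  inc2 <- to_incidence(tt, threshold = 2)
  expect_equal(as.matrix(inc2$presence),
               rbind(s1 = c(tA = 1, tB = 0), s2 = c(tA = 0, tB = 1)))
  expect_equal(inc1$m, 2L)
  expect_error(to_incidence(tt, threshold = 0), "threshold")

  # all-zero column retained and flagged
  tt2 <- suppressWarnings(
    taxon_table(rbind(s1 = c(tA = 2, tB = 0), s2 = c(tA = 1, tB = 0))))
  inc <- to_incidence(tt2)
  expect_equal(ncol(inc$presence), 2L)
  expect_equal(unname(inc$empty_taxa), c(FALSE, TRUE))

  # column sums at threshold 1 = number of samples containing each taxon
  set.seed(11)
  m <- matrix(rpois(60, 1), nrow = 6)
  tt3 <- suppressWarnings(taxon_table(m))
  expect_equal(unname(Matrix::colSums(to_incidence(tt3)$presence)),
               unname(colSums(as.matrix(tt3$counts) > 0)))
})

test_that("incidence_tally counts incidence classes and the k<=2 fraction", {
  # presence column sums (1, 1, 2, 5) over 5 samples
  m <- matrix(0, 5, 4, dimnames = list(paste0("s", 1:5), paste0("t", 1:4)))
  m[1, 1] <- 2; m[2, 2] <- 1; m[c(1, 3), 3] <- 1; m[1:5, 4] <- 7
  tal <- incidence_tally(taxon_table(m))
  expect_equal(tal$tally, c("1" = 2L, "2" = 1L, "5" = 1L))
  expect_equal(tal$n_observed, 4L)
  expect_equal(tal$frac_le2, 0.75)

  # all taxa everywhere: single class at k = m, fraction 0 for m > 2
  full <- taxon_table(matrix(1, 4, 3))
  tal2 <- incidence_tally(full)
  expect_equal(tal2$tally, c("4" = 3L))
  expect_equal(tal2$frac_le2, 0)

  # invariance under sample and taxon permutation
  set.seed(21)
  big <- suppressWarnings(taxon_table(matrix(rpois(200, 0.7), 10)))
  perm <- taxon_table(as.matrix(big$counts)[sample(nrow(big$counts)),
                                            sample(ncol(big$counts))])
  expect_equal(sort(incidence_tally(perm)$tally),
               sort(incidence_tally(big)$tally))
})

test_that("pool_corpus returns the ranked pooled SAD", {
  tt <- taxon_table(rbind(s1 = c(tA = 3, tB = 0), s2 = c(tA = 1, tB = 2)))
  pooled <- pool_corpus(tt)
  expect_equal(unname(pooled), c(4, 2))
  expect_equal(sum(pooled), sum(tt$counts))

  # single sample: pooled SAD is that sample's sorted counts
  one <- taxon_table(matrix(c(5, 1, 3), 1, dimnames = list("s1", NULL)))
  expect_equal(unname(pool_corpus(one)), c(5, 3, 1))

  # permutation invariance of the pooled vector
  set.seed(31)
  m <- matrix(rpois(120, 2), nrow = 8)
  t1 <- suppressWarnings(taxon_table(m))
  t2 <- suppressWarnings(taxon_table(m[sample(8), ]))
  expect_equal(unname(pool_corpus(t1)), unname(pool_corpus(t2)))
})

test_that("BIOM convenience reader round-trips a small table", {
  skip_if_not_installed("biomformat")
  m <- rbind(s1 = c(tA = 3, tB = 1, tC = 0), s2 = c(tA = 2, tB = 0, tC = 5))
  b <- biomformat::make_biom(t(m))  # BIOM stores observations x samples
  path <- tempfile(fileext = ".biom")
  biomformat::write_biom(b, path)
  tt <- read_biom_table(path)
  expect_equal(as.matrix(tt$counts)[rownames(m), colnames(m)], m)
})
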