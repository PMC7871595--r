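test_that("FASTA alignments are read, normalised and validated", {
  f <- write_fasta_text(c(">a", "ACGTACGTAA", ">b", "acgtacgtaa",
                          ">c", "ACGTACGTTT"))
  aln <- read_alignment(f, "COI")
  expect_s3_class(aln, "dna_alignment")
  expect_equal(nrow(aln), 3L)
  expect_equal(ncol(aln), 10L)
  expect_equal(rownames(aln), c("a", "b", "c"))  # file order preserved
  expect_equal(paste(aln["b", ], collapse = ""), "ACGTACGTAA")  # uppercased

  ragged <- write_fasta_text(c(">a", "ACGTACGTAA", ">bad", "ACGTACGTA"))
  expect_error(read_alignment(ragged), "unequal length.*bad")

  illegal <- write_fasta_text(c(">a", "ACGTACGTAA", ">b", "ACGTAZGTAA"))
  expect_error(read_alignment(illegal), "illegal character")
})

test_that("alignments round-trip through FASTA byte-identically", {
  aln <- small_sim()$alignments$COI
  f <- tempfile(fileext = ".fasta")
  write_alignment(aln, f)
  back <- read_alignment(f, attr(aln, "marker"))
  expect_identical(rownames(back), rownames(aln))
  expect_identical(unclass(back)[, ], unclass(aln)[, ])
})

test_that("metadata is validated against its schema and hierarchy", {
  df <- data.frame(sample = c("s1", "s2", "s3", "s4"),
                   population = c("P1", "P1", "P2", "P2"),
                   region = "A", lat = 30, lon = 100,
                   stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  md <- read_metadata(f)
  expect_s3_class(md, "sample_metadata")
  expect_equal(nrow(md), 4L)

  expect_error(as_sample_metadata(df[-1L]), "schema error.*sample")
  expect_error(as_sample_metadata(rbind(df, df[1L, ])),
               "schema error.*duplicate")
  bad <- df
  bad$region <- c("A", "A", "A", "B")   # P2 listed under both A and B
  expect_error(as_sample_metadata(bad), "hierarchy error.*P2")
  expect_error(as_sample_metadata(transform(df, lat = c(30, 30, 95, 30))),
               "latitude")
})

test_that("marker concatenation joins shared samples a-then-b", {
  a <- popgenmt:::new_alignment(c(strrep("A", 652), strrep("C", 652)),
                                c("s1", "s2"), "COI")
  b <- popgenmt:::new_alignment(c(strrep("G", 421), strrep("T", 421)),
                                c("s1", "s2"), "Cytb")
  ab <- concatenate_loci(a, b)
  expect_equal(ncol(ab), 1073L)       # 652 + 421
  expect_equal(attr(ab, "marker"), "COI+Cytb")
  expect_equal(paste(ab["s1", c(1, 653)], collapse = ""), "AG")

  b2 <- popgenmt:::new_alignment(c("GGGG", "TTTT"), c("s2", "s3"), "Cytb")
  expect_warning(ab2 <- concatenate_loci(a, b2), "dropping samples")
  expect_equal(rownames(ab2), "s2")
  expect_equal(ncol(ab2), 656L)       # length additivity on the intersection

  b3 <- popgenmt:::new_alignment("GGGG", "s9", "Cytb")
  expect_error(concatenate_loci(a, b3), "empty intersection")
})

test_that("dataset assembly joins strictly and masks ambiguous columns", {
  aln <- popgenmt:::new_alignment(c("ACGTN-", "ACGTAA", "ACTTAA"),
                                  c("s1", "s2", "s3"), "m")
  meta <- data.frame(sample = c("s1", "s2", "s3"), population = "P1",
                     region = "R1", lat = 0, lon = 0)
  x <- popgen_data(aln, meta)
  expect_equal(x$analyzed, 1:4)       # columns with N or - excluded
  expect_equal(x$n_sites, 6L)

  expect_error(popgen_data(aln, meta[1:2, ]), "missing from metadata.*s3")
  expect_warning(popgen_data(aln, rbind(meta,
    data.frame(sample = "s4", population = "P1", region = "R1",
               lat = 0, lon = 0))), "ignored")
})
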