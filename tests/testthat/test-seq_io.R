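test_that("FASTA reading parses, normalizes and preserves order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 first entry", "ACDEF", "GHIK", ">s2", "acdef"), f)
  db <- read_fasta(f)
  expect_equal(nrow(db), 2)
  expect_equal(db$id, c("s1", "s2"))
  expect_equal(db$residues, c("ACDEFGHIK", "ACDEF"))
  expect_equal(db$description[1], "first entry")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_equal(nrow(read_fasta(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACDEF", ">s1"), bad)
  expect_error(read_fasta(bad), "line 1")
})

test_that("FASTA round-trips and rejects duplicate ids / bad residues", {
  db <- seq_db(c("a", "b"), c("ACDEFGHIKLMNPQRSTVWY", "AAAA"),
               description = c("x", ""))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(db, f, width = 7)
  back <- read_fasta(f)
  expect_equal(back$id, db$id)
  expect_equal(back$residues, db$residues)

  expect_error(seq_db(c("a", "a"), c("AC", "AC")), "unique")
  expect_error(seq_db("a", "AC1DEF"), "illegal residue")
  # '*' terminators and gaps are stripped, ambiguity codes map to X
  expect_equal(seq_db("a", "ACD-EF*b")$residues, "ACDEFX")
})

test_that("MSA reading validates and both dialects agree", {
  f <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">r1", "AC-DE", ">r2", "ACWDE", ">r3", "AC-D-"), f)
  m <- read_msa(f, "aligned-fasta")
  expect_equal(m$ncol, 5)
  expect_equal(length(m$ids), 3)

  sto <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "#=GF ID test", "r1  AC-DE", "r2  ACWDE",
               "r3  AC-D-", "//"), sto)
  m2 <- read_msa(sto, "stockholm")
  expect_equal(m2$aln, m$aln)
  expect_equal(m2$ids, m$ids)

  bad <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">r1", "AC-DE", ">r2", "ACDE"), bad)
  expect_error(read_msa(bad, "aligned-fasta"), "r2|ragged")
})

test_that("MSA writing round-trips byte-identically in both dialects", {
  m <- msa(c("r1", "r2"), c("AC-DEF", "ACWDEF"))
  for (d in c("aligned-fasta", "stockholm")) {
    f <- withr::local_tempfile()
    write_msa(m, f, d)
    back <- read_msa(f, d)
    expect_equal(back$ids, m$ids)
    expect_equal(back$aln, m$aln)
    f2 <- withr::local_tempfile()
    write_msa(back, f2, d)
    expect_identical(readLines(f), readLines(f2))
  }
  expect_equal(degap(msa("r", "A-c.D")), "ACD")
})

test_that("model serialization round-trips bit-exactly with cutoffs and flags", {
  m <- build_profile(msa(paste0("s", 1:6), c("ACDEF", "ACDEF", "ACDEW",
                                             "AC-EF", "ACDEF", "ACDEF")),
                     name = "MDR035x",
                     description = "WARNING: potentially less reliable")
  m$ga <- 12.34; m$tc <- 12.34; m$nc <- 12.24; m$reliable <- FALSE
  f <- withr::local_tempfile(fileext = ".hmm")
  serialize_model(m, f)
  back <- deserialize_model(f)
  expect_identical(back$match_bits, m$match_bits)
  expect_identical(back$tMM, m$tMM)
  expect_identical(back$tDD, m$tDD)
  expect_identical(back$ga, m$ga)
  expect_identical(back$nc, m$nc)
  expect_identical(back$name, "MDR035x")
  expect_false(back$reliable)
  expect_match(back$description, "WARNING")
  # scoring is identical through a round-trip
  expect_identical(viterbi_glocal(back, "ACDEF")$score,
                   viterbi_glocal(m, "ACDEF")$score)
})

test_that("model deserialization rejects truncation and version mismatch", {
  m <- build_profile(msa(c("a", "b"), c("ACD", "ACD")))
  m$ga <- m$tc <- 1; m$nc <- 0.9
  f <- withr::local_tempfile()
  serialize_model(m, f)
  lines <- readLines(f)
  trunc <- withr::local_tempfile()
  writeLines(lines[1:5], trunc)
  expect_error(deserialize_model(trunc), "truncated")
  vers <- withr::local_tempfile()
  writeLines(c(sub("1\\.0", "9.9", lines[1]), lines[-1]), vers)
  expect_error(deserialize_model(vers), "unsupported")
  notmine <- withr::local_tempfile()
  writeLines(c("HMMER2.0", lines[-1]), notmine)
  expect_error(deserialize_model(notmine), "magic")
})

test_that("family table fixtures load with the printed counts", {
  t1 <- load_family_table(system.file("extdata", "table1_families.tsv",
                                      package = "famforge"), "table1")
  expect_equal(nrow(t1), 86)
  expect_equal(t1$family_id[1], "MDR001")
  expect_equal(t1$family_id[86], "MDR086")

  t3 <- load_family_table(system.file("extdata", "table3_zinc_kingdom.tsv",
                                      package = "famforge"), "table3")
  bact <- t3[t3$kingdom == "Bacteria", ]
  expect_equal(c(bact$zn0, bact$zn2), c(3907, 3395))

  t4 <- load_family_table(system.file("extdata",
                                      "table4_conservation_ratios.tsv",
                                      package = "famforge"), "table4")
  r5 <- t4[t4$family_id == "MDR005", ]
  expect_equal(c(r5$catalytic, r5$coenzyme), c(28, 8))

  badschema <- withr::local_tempfile()
  writeLines("kingdom\tzn0\nArchaea\t5", badschema)
  expect_error(load_family_table(badschema, "table3"), "missing column")
})

test_that("taxonomy sidecar reading validates kingdom labels", {
  f <- withr::local_tempfile()
  writeLines(c("id\tkingdom", "s1\tBacteria", "s2\tEukaryota"), f)
  tx <- read_taxonomy(f)
  expect_equal(tx$kingdom, c("Bacteria", "Eukaryota"))
  expect_true(all(is.na(tx$species_group)))
  bad <- withr::local_tempfile()
  writeLines(c("id\tkingdom", "s1\tMartian"), bad)
  expect_error(read_taxonomy(bad), "Martian")
})
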