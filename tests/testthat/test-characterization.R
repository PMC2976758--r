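test_that("conservation scores follow the modal-frequency definition", {
  m <- msa(paste0("s", 1:20), rep("K", 20))
  expect_equal(cscore_profile(m), 100)
  # 19 K + 1 gap: gaps count in the denominator
  m2 <- msa(paste0("s", 1:20), c(rep("K", 19), "-"))
  expect_equal(cscore_profile(m2), 95)
  # invariant under row reordering
  m3 <- msa(paste0("s", 1:6), c("KA", "KA", "KW", "WA", "KA", "KW"))
  perm <- c(4, 2, 6, 1, 3, 5)
  m3p <- msa(m3$ids[perm], m3$aln[perm])
  expect_equal(cscore_profile(m3), cscore_profile(m3p))
  # pluggable scorer
  expect_equal(cscore_profile(m3, scorer = function(col) 7), c(7, 7))
})

test_that("domain conservation counts and ratios reproduce printed cases", {
  # 28 perfectly conserved catalytic columns + 8 conserved coenzyme columns
  nrows <- 20
  cat_cols <- strrep("K", 28)
  coe_cols <- strrep("D", 8)
  varied <- function() paste(sample(famforge:::AA_ALPHABET20, 14, TRUE), collapse = "")
  set.seed(81)
  aln <- vapply(seq_len(nrows), function(i) {
    paste0(cat_cols, varied(), coe_cols, varied())
  }, character(1))
  m <- msa(paste0("s", 1:nrows), aln)
  dc <- domain_conservation_counts(m, boundary_column = 42, threshold = 95)
  expect_equal(dc$catalytic_count, 28)
  expect_equal(dc$coenzyme_count, 8)
  expect_equal(dc$ratio, 3.50)
  expect_equal(round(10 / 37, 2), 0.27)     # the inverse-skewed printed case
  # equal counts give ratio 1; zero coenzyme count is undefined, not Inf
  m5 <- msa(paste0("s", 1:10), rep(paste0(strrep("K", 5), strrep("D", 5)), 10))
  expect_equal(domain_conservation_counts(m5, 5)$ratio, 1.00)
  m0 <- msa(paste0("s", 1:10),
            vapply(1:10, function(i) paste0(strrep("K", 5), random_seq(12)),
                   character(1)))
  expect_true(is.na(domain_conservation_counts(m0, 5)$ratio))
  # counts are monotonically non-increasing in the threshold
  cs <- cscore_profile(m)
  for (th in c(50, 75, 90, 99)) {
    expect_gte(sum(cs > 50), sum(cs > th))
  }
})

test_that("net charge sums modal charges over conserved columns", {
  m <- msa(paste0("s", 1:10), rep("KKKE", 10))
  expect_equal(conserved_net_charge(m), 2L)        # +3 - 1
  expect_equal(conserved_net_charge(m, excluded_columns = 4L), 3L)
  expect_equal(conserved_net_charge(msa(paste0("s", 1:5), rep("GGGG", 5))), 0L)
  # average net charge is the row mean
  m2 <- msa(c("a", "b"), c("KKDE", "KKKK"))
  expect_equal(average_net_charge(m2), mean(c(0, 4)))
})

test_that("family summaries compute identity and kingdom statistics", {
  db <- seq_db(c("a", "b"), c("ACDEFGHIKL", "ACDEFGHIKL"),
               review_tier = c("reviewed", "unreviewed"),
               kingdom = c("Bacteria", "Bacteria"))
  fs <- family_summary(db, "F001")
  expect_equal(fs$pcid_avg, 100)
  expect_equal(fs$pcid_std, 0)
  expect_equal(fs$swissprot_count, 1)
  expect_equal(fs$n_bact, 2)

  # known pairwise identities 50/60/70% -> mean 60, sample sd 10
  a <- strrep("A", 10)
  mk <- function(nid) paste0(strrep("A", nid), paste(rep("W", 10 - nid), collapse = ""))
  db2 <- seq_db(c("r", "x", "y"), c(a, mk(5), mk(6)))
  # identities: r-x 5/10, r-y 6/10, x-y 9/10... use a direct triple instead
  ids <- c(pairwise_identity(a, mk(5)), pairwise_identity(a, mk(6)),
           pairwise_identity(mk(5), mk(6)))
  fs2 <- family_summary(db2)
  expect_equal(fs2$pcid_avg, mean(ids) * 100)
  expect_equal(fs2$pcid_std, stats::sd(ids * 100))

  # planted kingdom labels come through exactly; Unclassified excluded
  db3 <- seq_db(paste0("s", 1:6), replicate(6, random_seq(20)),
                kingdom = c("Eukaryota", "Eukaryota", "Bacteria", "Archaea",
                            "Unclassified", "Bacteria"))
  fs3 <- family_summary(db3)
  expect_equal(c(fs3$n_euk, fs3$n_bact, fs3$n_arch), c(2, 2, 1))
  expect_equal(fs3$size, 6)
})

test_that("superfamily aggregates reproduce the fixture tables' headlines", {
  t1 <- load_family_table(system.file("extdata", "table1_families.tsv",
                                      package = "famforge"), "table1")
  t3 <- load_family_table(system.file("extdata", "table3_zinc_kingdom.tsv",
                                      package = "famforge"), "table3")
  rep <- superfamily_report(t1, t3, total_domain_pairs = 15136)
  expect_equal(rep$total_members, 11579)
  expect_equal(rep$n_families, 86)
  expect_equal(rep$size_min, 20)
  expect_equal(rep$size_max, 2217)
  expect_equal(round(rep$pcid_avg_of_avgs), 61)
  expect_gt(rep$coverage, 76)
  bact <- rep$zn_class_pct[rep$zn_class_pct$kingdom == "Bacteria", ]
  expect_equal(round(bact$pct_zn0), 54)
  euk <- rep$zn_class_pct[rep$zn_class_pct$kingdom == "Eukaryota", ]
  expect_equal(round(euk$pct_zn2), 66)
  # nearly half the families purely bacterial, few purely eukaryotic
  expect_gt(rep$frac_purely_bacterial, 0.4)
  expect_lt(rep$frac_purely_eukaryotic, 0.2)
  # degenerate single-family table: coverage = size / total
  rep1 <- superfamily_report(t1[1, ], total_domain_pairs = 15136)
  expect_equal(rep1$coverage, 100 * 2217 / 15136)
})

test_that("motif scanning reports window match fractions", {
  m <- msa(paste0("s", 1:4), rep("WWGAGAAGWW", 4))
  hits <- motif_scan(m, "GxGxxG")
  expect_equal(hits$column, 3)
  expect_equal(hits$match_fraction, 1)
  # no glycine anywhere: empty
  expect_equal(nrow(motif_scan(msa(c("a", "b"), c("AAAAAA", "AAAAAA")), "GxGxxG")), 0)
  # half the rows matching reports fraction 0.5
  m2 <- msa(paste0("s", 1:4), c("GAGAAG", "GAGAAG", "AAAAAA", "AAAAAA"))
  h2 <- motif_scan(m2, "GxGxxG", min_fraction = 0.5)
  expect_equal(h2$match_fraction, 0.5)
  expect_error(motif_scan(m2, "G1G"), "wildcard")
})
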