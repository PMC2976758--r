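# engine config without smoothing: closed-form scores for uniform background
cfg0 <- engine_config(pseudocount = 0, trans_prior_weight = 0)

test_that("profile building follows the match-column and emission rules", {
  # 5 identical gapless rows: one match state per column, modal emission 1
  m <- build_profile(msa(paste0("s", 1:5), rep("ACD", 5)), cfg0)
  expect_equal(m$L, 3)
  expect_equal(unname(m$match_bits[1, "A"]), log2(20))
  expect_equal(unname(m$match_bits[2, "C"]), log2(20))
  expect_true(all(m$match_bits[1, setdiff(colnames(m$match_bits), "A")] == -Inf))

  # a column with 60% gaps is not a match state
  m2 <- build_profile(msa(paste0("s", 1:5),
                          c("A-C", "A-C", "A-C", "AWC", "AWC")), cfg0)
  expect_equal(m2$L, 2)

  expect_error(build_profile(msa(c("a", "b", "c"), c("-", "-", "A"))),
               "zero match columns")
})

test_that("emission rows renormalize to 1 before log-odds", {
  set.seed(11)
  rows <- replicate(10, random_seq(30))
  m <- build_profile(msa(paste0("s", 1:10), rows))
  p <- sweep(2^m$match_bits, 2, m$background, "*")
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  # transition probabilities also normalize per state
  for (j in seq_len(m$L - 1)) {
    expect_lt(abs(sum(2^c(m$tMM[j], m$tMI[j], m$tMD[j])) - 1), 1e-12)
    expect_lt(abs(sum(2^c(m$tDM[j], m$tDD[j])) - 1), 1e-12)
  }
})

test_that("glocal Viterbi scores the closed-form case and free flanks", {
  m <- build_profile(msa(paste0("s", 1:5), rep("ACD", 5)), cfg0)
  v <- viterbi_glocal(m, "ACD")
  expect_equal(v$score, 3 * log2(20), tolerance = 1e-12)
  expect_equal(v$env, c(1L, 3L))
  # flanking junk is skipped at zero cost; envelope shifts to the core
  v2 <- viterbi_glocal(m, "WWWACDWWW")
  expect_equal(v2$score, v$score, tolerance = 1e-12)
  expect_equal(v2$env, c(4L, 6L))
})

test_that("glocal Viterbi equals brute-force path enumeration", {
  set.seed(42)
  for (k in 1:250) {
    mod <- random_small_model(sample(1:5, 1))
    s <- random_seq(sample(1:7, 1))
    expect_equal(viterbi_glocal(mod, s)$score, oracle_viterbi(mod, s),
                 tolerance = 1e-9)
  }
})

test_that("score-only and traceback kernels agree", {
  set.seed(43)
  for (k in 1:50) {
    mod <- random_small_model(sample(2:5, 1))
    s <- random_seq(sample(2:7, 1))
    expect_equal(famforge:::fast_score(mod, s), viterbi_glocal(mod, s)$score,
                 tolerance = 1e-12)
  }
  # and on a realistic model
  set.seed(44)
  rows <- chartr("W", "A", replicate(8, random_seq(60)))
  mod <- build_profile(msa(paste0("s", 1:8), rows))
  s <- random_seq(80)
  expect_equal(famforge:::fast_score(mod, s), viterbi_glocal(mod, s)$score,
               tolerance = 1e-12)
})

test_that("best_domains finds tandem duplications as separate hits", {
  set.seed(12)
  core <- random_seq(40)
  fam <- vapply(1:8, function(i) famforge:::mutate_seq(core, 0.1), character(1))
  mod <- build_profile(msa(paste0("s", 1:8), fam))
  dup <- paste0("MW", famforge:::mutate_seq(core, 0.1), "KY",
                famforge:::mutate_seq(core, 0.1), "MW")
  h <- best_domains(mod, dup, max_domains = 3, sequence_id = "dup")
  expect_gte(nrow(h), 2)
  expect_true(!is.unsorted(rev(h$score)))  # sorted by descending score
  # the two domain hits do not overlap
  h2 <- h[1:2, ]
  expect_true(h2$end[which.min(h2$start)] < h2$start[which.max(h2$start)])
  expect_lt(abs(h2$score[1] - h2$score[2]) / abs(h2$score[1]), 0.5)

  # max_domains = 1 reproduces the plain glocal envelope
  h1 <- best_domains(mod, dup, max_domains = 1)
  v <- viterbi_glocal(mod, dup)
  expect_equal(c(h1$start, h1$end), v$env)
  expect_equal(h1$score, v$score)
})

test_that("unrelated sequences score far below family members", {
  set.seed(13)
  core <- random_seq(60)
  fam <- vapply(1:10, function(i) famforge:::mutate_seq(core, 0.15), character(1))
  mod <- build_profile(msa(paste0("s", 1:10), fam))
  member_scores <- vapply(fam, function(s) viterbi_glocal(mod, s)$score,
                          numeric(1))
  decoy_scores <- vapply(1:10, function(i) viterbi_glocal(mod, random_seq(60))$score,
                         numeric(1))
  expect_lt(max(decoy_scores), min(member_scores))
})

test_that("search honours its threshold and retains the model's own seeds", {
  set.seed(14)
  core <- random_seq(50)
  fam <- vapply(1:8, function(i) famforge:::mutate_seq(core, 0.12), character(1))
  db <- seq_db(paste0("s", 1:8), fam)
  mod <- build_profile(msa(db$id, fam))
  min_seed <- min(vapply(fam, function(s) viterbi_glocal(mod, s)$score, numeric(1)))
  hits <- search_db(mod, db, min_seed)
  expect_setequal(hits$sequence_id, db$id)   # self-retention at the seed minimum
  expect_equal(nrow(search_db(mod, db, 1e6)), 0)
})

test_that("alignment to a model is a fixed point on its training data", {
  m0 <- msa(paste0("s", 1:5), rep("ACDEFGHIK", 5))
  mod <- build_profile(m0, cfg0)
  al <- align_to_model(mod, seq_db(m0$ids, rep("ACDEFGHIK", 5)))
  expect_equal(al$aln, m0$aln)
  expect_equal(degap(al), rep("ACDEFGHIK", 5))

  # a 2-residue insertion shows up as two insert columns (smoothed model:
  # an unsmoothed one has no finite insert transitions at all)
  mod_s <- build_profile(m0, engine_config())
  al2 <- align_to_model(mod_s, seq_db(c("a", "b"),
                                      c("ACDEFGHIK", "ACDEWWFGHIK")))
  expect_equal(al2$ncol, 9 + 2)
  expect_equal(degap(al2), c("ACDEFGHIK", "ACDEWWFGHIK"))
  expect_equal(sum(!attr(al2, "match_cols")), 2)

  expect_error(align_to_model(mod, seq_db(character(0), character(0))),
               "no sequences")
})

test_that("truncating a family member strictly decreases its glocal score", {
  set.seed(15)
  core <- random_seq(80)
  fam <- vapply(1:8, function(i) famforge:::mutate_seq(core, 0.1), character(1))
  mod <- build_profile(msa(paste0("s", 1:8), fam))
  full <- fam[1]
  scores <- vapply(c(80, 70, 55, 40), function(len) {
    viterbi_glocal(mod, substr(full, 1, len))$score
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})
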