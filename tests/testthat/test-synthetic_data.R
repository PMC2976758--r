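test_that("generation is byte-deterministic given the seed", {
  p <- superfamily_params(n_families = 3, family_sizes = c(25, 30, 40),
                          within_identity_target = 0.65, rng_seed = 42)
  g1 <- generate_superfamily(p)
  g2 <- generate_superfamily(p)
  expect_identical(g1, g2)
  expect_equal(sum(g1$truth$family != "orphan" & g1$truth$pair_index == 1), 95)
  # a different seed produces different sequences
  g3 <- generate_superfamily(superfamily_params(n_families = 3,
                                                family_sizes = c(25, 30, 40),
                                                within_identity_target = 0.65,
                                                rng_seed = 43))
  expect_false(identical(g1$db$residues, g3$db$residues))
  # the caller's RNG stream is left untouched
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(generate_superfamily(p)); after <- runif(1)
  expect_identical(before, after)
})

test_that("every generated sequence has truth rows and valid spans", {
  g <- generate_superfamily(superfamily_params(n_families = 2,
                                               family_sizes = c(10, 10),
                                               n_orphans = 5, rng_seed = 44))
  expect_setequal(unique(g$truth$id), g$db$id)
  fam <- g$truth[g$truth$family != "orphan", ]
  slen <- nchar(g$db$residues)[match(fam$id, g$db$id)]
  expect_true(all(fam$start >= 1 & fam$end <= slen))
  expect_true(all(table(g$truth$id[g$truth$multidomain]) == 2))
})

test_that("the planted identity structure matches the configured targets", {
  p <- superfamily_params(n_families = 3, family_sizes = c(14, 14, 14),
                          within_identity_target = c(0.60, 0.75, 0.90),
                          fragment_fraction = 0, multidomain_fraction = 0,
                          n_orphans = 0, rng_seed = 45)
  g <- generate_superfamily(p)
  for (f in 1:3) {
    fam <- sprintf("FAM%02d", f)
    tr <- g$truth[g$truth$family == fam, ][1:8, ]
    seqs <- substr(g$db$residues[match(tr$id, g$db$id)], tr$start, tr$end)
    prs <- utils::combn(8, 2)
    idv <- vapply(seq_len(ncol(prs)), function(k) {
      pairwise_identity(seqs[prs[1, k]], seqs[prs[2, k]])
    }, numeric(1))
    target <- p$within_identity_target[f]
    expect_lt(abs(mean(idv) - target), 0.05)
  }
  # between-family identity stays below the configured cap
  pick <- function(f) {
    tr <- g$truth[g$truth$family == f, ][1:6, ]
    substr(g$db$residues[match(tr$id, g$db$id)], tr$start, tr$end)
  }
  s1 <- pick("FAM01"); s2 <- pick("FAM02")
  bt <- vapply(1:6, function(k) pairwise_identity(s1[k], s2[k]), numeric(1))
  expect_lt(max(bt), p$between_identity_max)
})

test_that("infeasible parameters are rejected before generation", {
  expect_error(superfamily_params(within_identity_target = 0.3,
                                  between_identity_max = 0.4),
               "infeasible")
  expect_error(superfamily_params(fragment_fraction = 1.5), "fractions")
})

test_that("an embedded motif is visible to the motif scanner", {
  p <- superfamily_params(n_families = 1, family_sizes = 12,
                          within_identity_target = 0.7, n_orphans = 0,
                          fragment_fraction = 0, multidomain_fraction = 0,
                          motif = "GAGAAG", rng_seed = 46)
  g <- generate_superfamily(p)
  tr <- g$truth
  rec <- seq_db(tr$id, substr(g$db$residues[match(tr$id, g$db$id)],
                              tr$start, tr$end))
  hits <- motif_scan(star_align(rec), "GxGxxG", min_fraction = 0.9)
  expect_gte(nrow(hits), 1)
})

test_that("truth-evaluation arithmetic matches hand-computed cases", {
  truth <- data.frame(id = c(paste0("a", 1:4), paste0("b", 1:4)),
                      family = rep(c("FA", "FB"), each = 4))
  mk <- function(ids, fid) seed_set(fid, data.frame(sequence_id = ids,
                                                    start = 1L, end = 10L,
                                                    score = NA_real_),
                                    msa(ids, rep("ACDEFGHIKL", length(ids))))
  # perfect recovery
  ev <- evaluate_against_truth(list(mk(paste0("a", 1:4), "ra"),
                                    mk(paste0("b", 1:4), "rb")), truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_true(all(ev$per_family$exact))
  # one alien member: precision (n-1)/n for that family
  ev2 <- evaluate_against_truth(list(mk(c(paste0("a", 1:4), "b1"), "ra"),
                                     mk(paste0("b", 2:4), "rb")), truth)
  pa <- ev2$per_family$precision[ev2$per_family$family == "FA"]
  expect_equal(pa, 4 / 5)
  # merging two planted families: recall 1, precision ~ 0.5 for each
  ev3 <- evaluate_against_truth(list(mk(c(paste0("a", 1:4), paste0("b", 1:4)),
                                        "merged")), truth)
  expect_equal(ev3$recall, 1)
  expect_equal(ev3$precision, 0.5)
})
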