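# two families with controllable sharing, plus models, on one database
make_overlap_setting <- function(rng_seed = 71, shared = 3) {
  set.seed(rng_seed)
  coreA <- random_seq(70)
  coreB <- random_seq(70)
  memA <- vapply(1:10, function(i) famforge:::mutate_seq(coreA, 0.12), character(1))
  memB <- vapply(1:8, function(i) famforge:::mutate_seq(coreB, 0.12), character(1))
  db <- seq_db(c(paste0("a", 1:10), paste0("b", 1:8)), c(memA, memB))
  fam <- function(ids, id) seed_from_db(db[match(ids, db$id), ], id)
  idsA <- paste0("a", 1:10)
  idsB <- c(paste0("b", 1:8), if (shared > 0) paste0("a", seq_len(shared)))
  families <- list(A = fam(idsA, "A"), B = fam(idsB, "B"))
  models <- lapply(families, function(s) build_profile(s$msa, name = s$family_id))
  list(db = db, families = families, models = models)
}

test_that("overlap detection agrees with a brute-force intersection oracle", {
  set.seed(72)
  for (trial in 1:10) {
    # random family memberships over a shared id universe
    ids <- paste0("s", 1:12)
    fams <- lapply(1:3, function(f) {
      n <- sample(3:8, 1)
      mem <- sample(ids, n)
      seed_set(paste0("F", f),
               data.frame(sequence_id = mem, start = 1L, end = 10L,
                          score = NA_real_),
               msa(mem, rep("ACDEFGHIKW", n)))
    })
    names(fams) <- paste0("F", 1:3)
    db <- seq_db(ids, vapply(ids, function(i) random_seq(10), character(1)))
    models <- lapply(fams, function(s) build_profile(s$msa, name = s$family_id))
    reports <- find_overlaps(fams, models, db)
    found <- vapply(reports, function(r) paste(r$family_a, r$family_b), character(1))
    for (a in 1:2) for (b in (a + 1):3) {
      kind <- brute_overlap_kind(fams[[a]], fams[[b]])
      key <- paste(fams[[a]]$family_id, fams[[b]]$family_id)
      if (is.null(kind)) {
        expect_false(key %in% found)
      } else {
        expect_true(key %in% found)
        rep <- reports[[match(key, found)]]
        expect_setequal(rep$shared_ids,
                        intersect(unique(fams[[a]]$members$sequence_id),
                                  unique(fams[[b]]$members$sequence_id)))
        if (kind == "subset") expect_equal(rep$kind, "subset")
        else expect_true(rep$kind %in% c("partial_low", "partial_high"))
      }
    }
  }
})

test_that("subset resolution keeps the superset and shelves the subset", {
  st <- make_overlap_setting(73, shared = 0)
  # build a nested subfamily: a strict subset of family A
  sub <- seed_set("Asub", st$families$A$members[1:4, ],
                  msa(st$families$A$msa$ids[1:4], st$families$A$msa$aln[1:4]))
  fams <- c(st$families["A"], list(Asub = sub))
  models <- lapply(fams, function(s) build_profile(s$msa, name = s$family_id))
  reports <- find_overlaps(fams, models, st$db)
  expect_length(reports, 1)
  expect_equal(reports[[1]]$kind, "subset")
  act <- resolve_subset(reports[[1]], fams)
  expect_equal(act$keep, "A")
  expect_equal(act$shelved, "Asub")
  expect_true(act$shelf[[1]]$disjoint)
  # a second disjoint subset is still marked disjoint; an overlapping one not
  sub2 <- seed_set("Asub2", st$families$A$members[5:7, ],
                   msa(st$families$A$msa$ids[5:7], st$families$A$msa$aln[5:7]))
  act2 <- resolve_subset(overlap_report_for(st$families$A, sub2),
                         c(st$families["A"], list(Asub2 = sub2)), act$shelf)
  expect_true(act2$shelf[[2]]$disjoint)
  sub3 <- seed_set("Asub3", st$families$A$members[1:2, ],
                   msa(st$families$A$msa$ids[1:2], st$families$A$msa$aln[1:2]))
  act3 <- resolve_subset(overlap_report_for(st$families$A, sub3),
                         c(st$families["A"], list(Asub3 = sub3)), act2$shelf)
  expect_false(act3$shelf[[3]]$disjoint)
  # identical seed sets: deterministic tie-break by id
  twin <- seed_set("Atwin", st$families$A$members, st$families$A$msa)
  act4 <- resolve_subset(overlap_report_for(st$families$A, twin),
                         c(st$families["A"], list(Atwin = twin)))
  expect_equal(act4$keep, "A")
})

test_that("merge resolution unions memberships and verifies by refinement", {
  st <- make_overlap_setting(74, shared = 3)
  r <- overlap_report_for(st$families$A, st$families$B, kind = "partial_high")
  act <- resolve_merge(r, st$families, st$db)
  if (act$action == "merged") {
    merged <- act$families[[act$merged_id]]
    expect_equal(nrow(merged$members) >= 10, TRUE)
  }
  # merged size law: |larger| + |smaller \ shared|
  nA <- 10; nB <- 11; nShared <- 3
  expect_equal(nB + (nA - nShared), 18)

  # merging two unrelated families: divergent refinement rejects the merge
  bx <- make_bridge_fixture(75)
  dbx <- bx$db
  famA <- seed_from_db(dbx[1:22, ], "pureA")
  famB <- seed_from_db(dbx[(nrow(dbx) - 21):nrow(dbx), ], "pureB")
  famB$members$sequence_id[1] <- famA$members$sequence_id[1]  # force a shared id
  famB$msa$ids[1] <- famA$msa$ids[1]
  rr <- overlap_report_for(famA, famB, kind = "partial_high")
  act2 <- resolve_merge(rr, list(pureA = famA, pureB = famB), dbx, cap = 40)
  expect_equal(act2$action, "merge_rejected")
  expect_length(act2$families, 2)
})

test_that("a full resolution pass leaves primary seed sets pairwise disjoint", {
  st <- make_overlap_setting(76, shared = 2)
  out <- resolve_overlaps(st$families, st$db)
  ids <- lapply(out$families, function(s) unique(s$members$sequence_id))
  if (length(ids) >= 2) {
    for (a in seq_len(length(ids) - 1)) for (b in (a + 1):length(ids)) {
      expect_length(intersect(ids[[a]], ids[[b]]), 0)
    }
  }
  expect_true(length(out$families) >= 1)
})
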