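overlap_report <- function(family_a, family_b, shared_ids, kind,
                           resolution = "pending") {
  structure(list(family_a = family_a, family_b = family_b,
                 shared_ids = shared_ids, kind = kind,
                 resolution = resolution), class = "overlap_report")
}

family_member_ids <- function(seed) unique(seed$members$sequence_id)

#' Detect seed-set overlaps between stable families
#'
#' Every pair of families sharing members is reported. The overlap kind is
#' `subset` when one membership contains the other (identical sets count as
#' subset), otherwise `partial_low` when every shared member scores below a
#' separability margin under at least one of the two models (the model's
#' minimum seed score minus `margin` bits), else `partial_high`.
#'
#' @param families named list of [seed_set()]s.
#' @param models named list of corresponding [profile_model()]s (same order).
#' @param db sequence database.
#' @param margin separability margin in bits (default 2).
#' @return list of `overlap_report`s.
#' @export
find_overlaps <- function(families, models, db, margin = 2) {
  reports <- list()
  nf <- length(families)
  if (nf < 2) return(reports)
  min_seed_score <- function(f) {
    min(score_seed_members(models[[f]], families[[f]], db))
  }
  mss <- vapply(seq_len(nf), min_seed_score, numeric(1))
  for (a in seq_len(nf - 1)) {
    for (b in (a + 1):nf) {
      ia <- family_member_ids(families[[a]])
      ib <- family_member_ids(families[[b]])
      shared <- intersect(ia, ib)
      if (length(shared) == 0) next
      if (all(ia %in% ib) || all(ib %in% ia)) {
        kind <- "subset"
      } else {
        hit_score <- function(model, s) {
          sc <- best_domains(model, s, max_domains = 1L)$score
          if (length(sc)) sc[1] else -Inf  # no envelope at all
        }
        low <- vapply(shared, function(sid) {
          s <- db$residues[match(sid, db$id)]
          (hit_score(models[[a]], s) < mss[a] - margin) ||
            (hit_score(models[[b]], s) < mss[b] - margin)
        }, logical(1))
        kind <- if (all(low)) "partial_low" else "partial_high"
      }
      reports[[length(reports) + 1]] <-
        overlap_report(families[[a]]$family_id, families[[b]]$family_id,
                       shared, kind)
    }
  }
  reports
}

#' Resolve a subset overlap: keep the superset, shelve the subset
#'
#' The superset stays in the primary library; the subset moves to the
#' subfamily shelf, where it is flagged disjoint or non-disjoint against the
#' subsets already shelved (disjoint subsets are especially useful for
#' discriminating between subfamilies). Identical seed sets are treated as
#' subset either way with a deterministic tie-break by size then id.
#'
#' @param report an `overlap_report` of kind `subset`.
#' @param families named list of [seed_set()]s.
#' @param shelf current list of shelved subfamily entries.
#' @return list with `keep` (family id retained), `shelved` (new shelf
#'   entry: seed + `disjoint` flag), `shelf` (updated shelf).
#' @export
resolve_subset <- function(report, families, shelf = list()) {
  stopifnot(report$kind == "subset")
  fa <- families[[report$family_a]]
  fb <- families[[report$family_b]]
  na <- length(family_member_ids(fa))
  nb <- length(family_member_ids(fb))
  if (na > nb || (na == nb && fa$family_id < fb$family_id)) {
    super <- fa; sub <- fb
  } else {
    super <- fb; sub <- fa
  }
  sub_ids <- family_member_ids(sub)
  disjoint <- all(vapply(shelf, function(e) {
    length(intersect(family_member_ids(e$seed), sub_ids)) == 0
  }, logical(1)))
  entry <- list(seed = sub, parent = super$family_id, disjoint = disjoint)
  list(keep = super$family_id, shelved = sub$family_id,
       shelf = c(shelf, list(entry)))
}

#' Resolve a partial overlap with low-scoring inconsistent members
#'
#' For the model that assigns the shared members low scores, the inclusion
#' threshold is raised to just above the highest inconsistent member's
#' score (plus 0.1 bits, mirroring the noise-cutoff offset); all seed
#' members falling below the new threshold are evicted and the trimmed
#' family is rebuilt and re-verified stable via [refine()]. If raising the
#' threshold would evict more than `max_evict_fraction` of the seeds, the
#' overlap escalates to the merge path instead.
#'
#' @param report an `overlap_report` of kind `partial_low`.
#' @param families named list of [seed_set()]s.
#' @param models named list of [profile_model()]s.
#' @param db sequence database.
#' @param config an [engine_config()].
#' @param epsilon threshold raise above the top inconsistent score.
#' @param max_evict_fraction escalation guard (default 0.2).
#' @return list with `action` (`raise_threshold` or `escalate_merge`),
#'   `family` (edited family id), `families` (updated list), `verified`
#'   (logical: post-edit refinement converged without membership change).
#' @export
resolve_partial_low <- function(report, families, models, db,
                                config = engine_config(), epsilon = 0.1,
                                max_evict_fraction = 0.2) {
  stopifnot(report$kind == "partial_low")
  # pick the family under whose model the shared members score lower
  score_under <- function(fid) {
    m <- models[[fid]]
    vapply(report$shared_ids, function(sid) {
      sc <- best_domains(m, db$residues[match(sid, db$id)], max_domains = 1L)$score
      if (length(sc)) sc[1] else -Inf
    }, numeric(1))
  }
  sa <- score_under(report$family_a)
  sb <- score_under(report$family_b)
  target <- if (max(sa) <= max(sb)) report$family_a else report$family_b
  tsc <- if (target == report$family_a) sa else sb
  seed <- families[[target]]
  all_sc <- score_seed_members(models[[target]], seed, db)
  new_threshold <- max(tsc) + epsilon
  evict <- all_sc < new_threshold
  if (mean(evict) > max_evict_fraction) {
    return(list(action = "escalate_merge", family = target,
                families = families, verified = NA))
  }
  keep <- which(!evict)
  trimmed <- seed_set(seed$family_id, seed$members[keep, , drop = FALSE],
                      msa(seed$msa$ids[keep], seed$msa$aln[keep]))
  res <- refine(trimmed, db, config = config)
  verified <- res$status == "converged" &&
    setequal(member_keys(res$final_seed$members), member_keys(trimmed$members))
  families[[target]] <- res$final_seed
  list(action = "raise_threshold", family = target, families = families,
       verified = verified, new_threshold = new_threshold)
}

#' Resolve a partial overlap by merging into a common supergroup
#'
#' The non-overlapping members of the smaller seed set are added to the
#' larger one, the merged set is realigned de novo and refined. On
#' convergence the merged family replaces both participants; if refinement
#' diverges the merge is rejected and both families are retained, with the
#' conflict logged.
#'
#' @param report an `overlap_report` (kind `partial_high`, or an escalated
#'   `partial_low`).
#' @param families named list of [seed_set()]s.
#' @param db sequence database.
#' @param config an [engine_config()].
#' @param cap divergence cap for the verification refinement.
#' @return list with `action` (`merged` or `merge_rejected`), `families`
#'   (updated list), and `merged_id` when merged.
#' @export
resolve_merge <- function(report, families, db, config = engine_config(),
                          cap = 3000) {
  fa <- families[[report$family_a]]
  fb <- families[[report$family_b]]
  if (nrow(fa$members) >= nrow(fb$members)) {
    larger <- fa; smaller <- fb
  } else {
    larger <- fb; smaller <- fa
  }
  extra <- smaller$members[!smaller$members$sequence_id %in%
                             larger$members$sequence_id, , drop = FALSE]
  merged_members <- rbind(larger$members, extra)
  rec <- seq_db(id = sprintf("%s/%d-%d", merged_members$sequence_id,
                             merged_members$start, merged_members$end),
                residues = substr(db$residues[match(merged_members$sequence_id, db$id)],
                                  merged_members$start, merged_members$end))
  merged_msa <- star_align(rec)
  merged <- seed_set(larger$family_id, merged_members, merged_msa)
  res <- refine(merged, db, cap = cap, config = config)
  if (res$status == "converged") {
    families[[smaller$family_id]] <- NULL
    families[[larger$family_id]] <- res$final_seed
    list(action = "merged", families = families, merged_id = larger$family_id)
  } else {
    list(action = "merge_rejected", families = families,
         conflict = c(report$family_a, report$family_b))
  }
}

#' Full overlap-resolution pass
#'
#' Repeatedly detects overlaps among the primary families and resolves
#' them - subset set-aside, threshold raising, or merge-and-refine - until
#' the primary library's seed sets are pairwise disjoint (or only logged
#' merge-rejections remain).
#'
#' @param families named list of [seed_set()]s.
#' @param db sequence database.
#' @param config an [engine_config()].
#' @param margin partial-low separability margin in bits.
#' @param cap divergence cap for merge verification.
#' @param max_rounds safety valve.
#' @return list with `families` (primary library), `shelf` (shelved
#'   subfamily entries), `log` (resolution actions).
#' @export
resolve_overlaps <- function(families, db, config = engine_config(),
                             margin = 2, cap = 3000, max_rounds = 10) {
  shelf <- list()
  log <- list()
  rejected <- character(0)
  for (round in seq_len(max_rounds)) {
    models <- lapply(families, function(s) build_profile(s$msa, config,
                                                         name = s$family_id))
    reports <- find_overlaps(families, models, db, margin)
    pairkey <- function(r) paste(sort(c(r$family_a, r$family_b)), collapse = "|")
    reports <- Filter(function(r) !pairkey(r) %in% rejected, reports)
    if (length(reports) == 0) break
    r <- reports[[1]]
    if (r$kind == "subset") {
      act <- resolve_subset(r, families, shelf)
      shelf <- act$shelf
      families[[act$shelved]] <- NULL
      log[[length(log) + 1]] <- list(kind = "subset", keep = act$keep,
                                     shelved = act$shelved)
    } else if (r$kind == "partial_low") {
      act <- resolve_partial_low(r, families, models, db, config)
      if (act$action == "escalate_merge") {
        act2 <- resolve_merge(r, families, db, config, cap)
        families <- act2$families
        if (act2$action == "merge_rejected") rejected <- c(rejected, pairkey(r))
        log[[length(log) + 1]] <- c(list(kind = "partial_low_escalated"), act2["action"])
      } else {
        families <- act$families
        log[[length(log) + 1]] <- list(kind = "partial_low", family = act$family,
                                       verified = act$verified)
      }
    } else {
      act <- resolve_merge(r, families, db, config, cap)
      families <- act$families
      if (act$action == "merge_rejected") rejected <- c(rejected, pairkey(r))
      log[[length(log) + 1]] <- c(list(kind = "partial_high"), act["action"])
    }
  }
  list(families = families, shelf = shelf, log = log)
}
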