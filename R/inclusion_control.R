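#' Leave-one-out observation for one seed member
#'
#' Rebuilds the family model without the chosen member (drop the row,
#' rebuild, realign the remaining members, rebuild again) and records the
#' left-out member's domain score, the minimum score among the remaining
#' seed members, and - when a comparison database is supplied - the best
#' score among non-seed sequences.
#'
#' @param seed a converged [seed_set()] with at least 3 members.
#' @param db sequence database.
#' @param index which member (row of `seed$members`) to leave out.
#' @param with_db if `TRUE`, search the database for the best non-seed
#'   domain score (needed by strategies II/III); if `FALSE` the comparison
#'   is internal and `best_nonseed_score` is `NA`.
#' @param config an [engine_config()].
#' @param nonseed_margin the non-seed comparison search threshold is the
#'   left-out score minus this many bits.
#' @param realign if `TRUE`, the remaining members are realigned to the
#'   dropped-row model and the model rebuilt from the realignment; the
#'   default rebuilds directly from the row-dropped alignment (removing one
#'   row leaves the others' columns unchanged, and the jackknife repeats
#'   n times per family, so the cheap rebuild is the default).
#' @return a `loo_observation`: `left_out_id`, `left_out_score`,
#'   `min_remaining_seed_score`, `best_nonseed_score` (or `NA`).
#' @export
leave_one_out <- function(seed, db, index, with_db = TRUE,
                          config = engine_config(), nonseed_margin = 5,
                          realign = FALSE) {
  n <- nrow(seed$members)
  stopifnot(n >= 3, index >= 1, index <= n)
  loo_observe(toupper(msa_matrix(seed$msa)), seed_records(seed, db),
              seed, db, index, with_db, config, nonseed_margin, realign)
}

# worker shared by leave_one_out and stability_check: `mat` is the seed MSA
# as an uppercase character matrix, `rec` the seed region records
loo_observe <- function(mat, rec, seed, db, index, with_db,
                        config, nonseed_margin, realign = FALSE) {
  n <- nrow(seed$members)
  keep <- setdiff(seq_len(n), index)
  model <- build_profile_mat(mat[keep, , drop = FALSE], config,
                             name = seed$family_id)
  if (isTRUE(realign)) {
    realigned <- align_to_model(model, rec[keep, , drop = FALSE])
    model <- build_profile(realigned, config, name = seed$family_id)
  }
  lo_score <- fast_score(model, rec$residues[index])
  if (!is.finite(lo_score)) lo_score <- -1e6  # sentinel: no hit at all
  min_rem <- min(vapply(rec$residues[keep], function(s) fast_score(model, s),
                        numeric(1), USE.NAMES = FALSE))
  best_nonseed <- NA_real_
  if (isTRUE(with_db)) {
    nonseed <- db[!db$id %in% seed$members$sequence_id, , drop = FALSE]
    if (nrow(nonseed) > 0) {
      hits <- search_db(model, nonseed, lo_score - nonseed_margin, max_domains = 1L)
      best_nonseed <- if (nrow(hits) > 0) hits$score[1] else -Inf
    } else {
      best_nonseed <- -Inf
    }
  }
  structure(list(left_out_id = seed$members$sequence_id[index],
                 left_out_score = lo_score,
                 min_remaining_seed_score = min_rem,
                 best_nonseed_score = best_nonseed),
            class = "loo_observation")
}

#' Classify a leave-one-out observation as spurious
#'
#' Strategy I (exclusive): the left-out member scores strictly below the
#' minimum remaining seed score. Strategy II (intermediate): additionally,
#' at least one non-seed sequence exceeds the left-out score (membership
#' strength below the noise level). Strategy III (inclusive): additionally,
#' the left-out score falls below 90 percent of the minimum remaining seed
#' score. By construction spurious(III) implies spurious(II) implies
#' spurious(I). Ties with the remaining minimum are not spurious.
#'
#' @param obs a `loo_observation`.
#' @param strategy `"I"`, `"II"` or `"III"`.
#' @return logical.
#' @export
classify_spurious <- function(obs, strategy = c("II", "I", "III")) {
  strategy <- match.arg(strategy)
  s1 <- obs$left_out_score < obs$min_remaining_seed_score
  if (strategy == "I") return(s1)
  s2 <- s1 && !is.na(obs$best_nonseed_score) &&
    obs$best_nonseed_score > obs$left_out_score
  if (strategy == "II") return(s2)
  s2 && obs$left_out_score < 0.9 * obs$min_remaining_seed_score
}

#' Jackknife stability check of one family
#'
#' Runs [leave_one_out()] for every member. Database comparisons (needed by
#' strategies II and III) are evaluated only for members that already fail
#' the internal strategy-I criterion, which yields identical spurious sets
#' at a fraction of the search cost.
#'
#' @param seed a converged [seed_set()].
#' @param db sequence database.
#' @param strategy inclusion control strategy (`"I"`, `"II"`, `"III"`).
#' @param config an [engine_config()].
#' @param nonseed_margin see [leave_one_out()].
#' @return list with `observations` (one `loo_observation` per member;
#'   for clearly-retained members `min_remaining_seed_score` holds the first
#'   witnessing score at or below the left-out score, which suffices for
#'   the classification) and
#'   `spurious_ids` (character vector).
#' @export
stability_check <- function(seed, db, strategy = "II",
                            config = engine_config(), nonseed_margin = 5) {
  n <- nrow(seed$members)
  mat <- toupper(msa_matrix(seed$msa))
  rec <- seed_records(seed, db)
  obs <- vector("list", n)
  spurious <- character(0)
  keepall <- seq_len(n)
  # full-model scores guide two shortcuts below; removing one of n seed rows
  # shifts any score by far less than `drift` bits
  full_model <- build_profile_mat(mat, config, name = seed$family_id)
  member_full <- vapply(rec$residues, function(s) fast_score(full_model, s),
                        numeric(1), USE.NAMES = FALSE)
  nonseed <- db[!db$id %in% seed$members$sequence_id, , drop = FALSE]
  nonseed_full <- vapply(nonseed$residues,
                         function(s) fast_score(full_model, s),
                         numeric(1), USE.NAMES = FALSE)
  drift <- 40
  for (k in keepall) {
    model <- build_profile_mat(mat[-k, , drop = FALSE], config,
                               name = seed$family_id)
    lo <- fast_score(model, rec$residues[k])
    if (!is.finite(lo)) lo <- -1e6
    # strategy I asks whether the left-out member scores below *every*
    # remaining member; scanning weakest-first (by full-model score) stops
    # at the first remaining member scoring at or below it
    ord <- keepall[-k][order(member_full[-k])]
    minrem <- Inf
    witness <- FALSE
    for (j in ord) {
      s <- fast_score(model, rec$residues[j])
      if (s < minrem) minrem <- s
      if (s <= lo) { witness <- TRUE; break }
    }
    if (witness || strategy == "I") {
      # either retained (min_remaining then reports the witnessing score,
      # an upper bound on the true minimum: the classification is
      # identical) or strategy I needs no database comparison
      o <- structure(list(left_out_id = seed$members$sequence_id[k],
                          left_out_score = lo,
                          min_remaining_seed_score = minrem,
                          best_nonseed_score = NA_real_),
                     class = "loo_observation")
    } else {
      # strategy-I failure: find the best non-seed domain score, searching
      # only sequences that could plausibly reach the comparison threshold
      thr <- lo - nonseed_margin
      cand <- nonseed[nonseed_full >= thr - drift, , drop = FALSE]
      best_nonseed <- -Inf
      if (nrow(cand) > 0) {
        hits <- search_db(model, cand, thr, max_domains = 1L)
        if (nrow(hits) > 0) best_nonseed <- hits$score[1]
      }
      o <- structure(list(left_out_id = seed$members$sequence_id[k],
                          left_out_score = lo,
                          min_remaining_seed_score = minrem,
                          best_nonseed_score = best_nonseed),
                     class = "loo_observation")
    }
    obs[[k]] <- o
    if (classify_spurious(o, strategy)) {
      spurious <- c(spurious, o$left_out_id)
    }
  }
  list(observations = obs, spurious_ids = spurious)
}

stability_report <- function(family_id, strategy, spurious_ids, n_nonspurious,
                             min_reliable = 20) {
  structure(list(family_id = family_id, strategy = strategy,
                 spurious_ids = spurious_ids,
                 stable = length(spurious_ids) == 0,
                 reliable = n_nonspurious >= min_reliable),
            class = "stability_report")
}

#' One inclusion-control pass over a set of families
#'
#' For every family, all members are jackknifed and spurious members are
#' removed. Affected families are realigned de novo, rebuilt and flagged
#' for another refinement pass; unaffected families are stable. Families
#' whose non-spurious membership falls below `min_reliable` are marked
#' potentially less reliable: their name receives an `x` postfix and their
#' model description an explicit warning.
#'
#' @param families list of converged [seed_set()]s.
#' @param db sequence database.
#' @param strategy inclusion control strategy.
#' @param config an [engine_config()].
#' @param min_reliable reliability floor on non-spurious membership
#'   (default 20).
#' @param nonseed_margin see [leave_one_out()].
#' @return list with `reports` (per-family `stability_report`), `families`
#'   (updated seed sets), `needs_refine` (logical per family) and
#'   `reliable` (logical per family).
#' @export
stability_pass <- function(families, db, strategy = "II",
                           config = engine_config(), min_reliable = 20,
                           nonseed_margin = 5) {
  reports <- vector("list", length(families))
  needs_refine <- logical(length(families))
  reliable <- logical(length(families))
  out <- families
  for (f in seq_along(families)) {
    seed <- families[[f]]
    chk <- stability_check(seed, db, strategy, config, nonseed_margin)
    n_keep <- nrow(seed$members) - length(chk$spurious_ids)
    reports[[f]] <- stability_report(seed$family_id, strategy,
                                     chk$spurious_ids, n_keep, min_reliable)
    reliable[f] <- reports[[f]]$reliable
    if (length(chk$spurious_ids) > 0) {
      keep <- which(!seed$members$sequence_id %in% chk$spurious_ids)
      trimmed <- seed$members[keep, , drop = FALSE]
      rec <- seq_db(id = sprintf("%s/%d-%d", trimmed$sequence_id,
                                 trimmed$start, trimmed$end),
                    residues = substr(db$residues[match(trimmed$sequence_id, db$id)],
                                      trimmed$start, trimmed$end))
      new_msa <- star_align(rec)
      new_msa$ids <- rec$id
      out[[f]] <- seed_set(seed$family_id, trimmed, new_msa)
      needs_refine[f] <- TRUE
    }
  }
  list(reports = reports, families = out, needs_refine = needs_refine,
       reliable = reliable)
}

#' Inclusion-control loop with re-injection into refinement
#'
#' Alternates [stability_pass()] and [refine()] on the affected families
#' until no family changes or the pass limit is reached.
#'
#' @param families list of converged [seed_set()]s.
#' @param db sequence database.
#' @param strategy inclusion control strategy.
#' @param config an [engine_config()].
#' @param max_passes reiteration limit (default 6).
#' @param cap,max_iter passed to [refine()].
#' @param min_reliable reliability floor (default 20).
#' @return list with `families`, `reports` (final pass), `reliable`,
#'   `passes` (number of stability passes run).
#' @export
run_inclusion_control <- function(families, db, strategy = "II",
                                  config = engine_config(), max_passes = 6,
                                  cap = 3000, max_iter = 50, min_reliable = 20) {
  passes <- 0
  reports <- vector("list", length(families))
  reliable <- rep(TRUE, length(families))
  active <- seq_along(families)
  while (length(active) > 0 && passes < max_passes) {
    passes <- passes + 1
    sp <- stability_pass(families[active], db, strategy, config, min_reliable)
    families[active] <- sp$families
    reports[active] <- sp$reports
    reliable[active] <- sp$reliable
    changed <- active[sp$needs_refine]
    for (f in changed) {
      res <- refine(families[[f]], db, cap = cap, max_iter = max_iter,
                    config = config)
      families[[f]] <- res$final_seed
    }
    active <- changed  # stable families need no further jackknifing
  }
  list(families = families, reports = reports, reliable = reliable,
       passes = passes)
}
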