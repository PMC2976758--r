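#' Construct a seed set
#'
#' The evolving membership of one family model: a member table (one row per
#' domain region) plus the seed alignment the model is built from.
#'
#' @param family_id family identifier.
#' @param members data.frame with columns `sequence_id`, `start`, `end`,
#'   `score` (last recorded bit score; may be `NA` before first scoring).
#' @param msa an [msa()] whose rows correspond 1:1 to the members.
#' @return a `seed_set` object.
#' @export
seed_set <- function(family_id, members, msa) {
  stopifnot(nrow(members) >= 1, length(msa$ids) == nrow(members))
  members$sequence_id <- as.character(members$sequence_id)
  structure(list(family_id = family_id, members = members, msa = msa),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("seed_set '%s': %d members\n", x$family_id, nrow(x$members)))
  invisible(x)
}

member_keys <- function(members) {
  # region identity is per (sequence, ordinal domain along the sequence):
  # envelopes may drift a little between iterations without changing the key
  ave_rank <- stats::ave(members$start, members$sequence_id,
                         FUN = function(x) rank(x, ties.method = "first"))
  paste(members$sequence_id, ave_rank, sep = "#")
}

seed_records <- function(seed, db) {
  idx <- match(seed$members$sequence_id, db$id)
  if (anyNA(idx)) {
    stop(sprintf("seed member(s) missing from database: %s",
                 paste(unique(seed$members$sequence_id[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  seq_db(id = sprintf("%s/%d-%d", seed$members$sequence_id,
                      seed$members$start, seed$members$end),
         residues = substr(db$residues[idx], seed$members$start, seed$members$end),
         kingdom = db$kingdom[idx], review_tier = db$review_tier[idx],
         species_group = db$species_group[idx])
}

# score every seed member's region under the model (best single domain);
# only the score is needed, so the score-only kernel is used
score_seed_members <- function(model, seed, db) {
  rec <- seed_records(seed, db)
  vapply(rec$residues, function(s) fast_score(model, s),
         numeric(1), USE.NAMES = FALSE)
}

#' One refinement iteration
#'
#' The inclusion threshold is the minimum over the current seed members of
#' their best domain score under the model; every domain in the database
#' scoring at or above it (ties included, so current seeds always
#' self-retain) forms the next seed, realigned to the model.
#'
#' @param model the current [profile_model()] (built from `seed$msa`).
#' @param seed the current [seed_set()].
#' @param db the sequence database ([seq_db()]).
#' @param max_domains per-sequence domain cap during the search.
#' @return the next [seed_set()]; always a superset of the input membership.
#' @export
refine_iteration <- function(model, seed, db, max_domains = 4L) {
  sc <- score_seed_members(model, seed, db)
  if (any(!is.finite(sc))) {
    stop(sprintf("internal consistency failure: seed member(s) of '%s' no longer match their own model",
                 seed$family_id), call. = FALSE)
  }
  threshold <- min(sc)
  hits <- search_db(model, db, threshold, max_domains)
  if (nrow(hits) == 0) {
    stop("refinement search returned no hits at the seed threshold", call. = FALSE)
  }
  members <- data.frame(sequence_id = hits$sequence_id, start = hits$start,
                        end = hits$end, score = hits$score,
                        stringsAsFactors = FALSE)
  members <- members[order(members$sequence_id, members$start), , drop = FALSE]
  rownames(members) <- NULL
  idx <- match(members$sequence_id, db$id)
  rec <- seq_db(id = sprintf("%s/%d-%d", members$sequence_id, members$start, members$end),
                residues = substr(db$residues[idx], members$start, members$end))
  new_msa <- align_to_model(model, rec)
  seed_set(seed$family_id, members, new_msa)
}

refinement_result <- function(status, iterations, seed_history_sizes,
                              final_seed, final_model, log = list()) {
  structure(list(status = status, iterations = iterations,
                 seed_history_sizes = seed_history_sizes,
                 final_seed = final_seed, final_model = final_model,
                 log = log), class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("refinement '%s': %s after %d iteration(s); seed sizes %s\n",
              x$final_seed$family_id, x$status, x$iterations,
              paste(x$seed_history_sizes, collapse = " -> ")))
  invisible(x)
}

#' Iterative refinement of a family model
#'
#' Loops build -> search -> include until the membership no longer changes
#' (converged), the seed grows past the divergence cap (diverged), or the
#' iteration limit is hit. Because each iteration's seed is a superset of
#' the previous one, the loop always terminates on a finite database.
#'
#' @param seed0 initial [seed_set()] (at least 2 members).
#' @param db sequence database.
#' @param cap divergence cap: refinements gathering more seed sequences than
#'   this are classed as divergent and aborted (default 3000).
#' @param max_iter safety valve on iterations (not a convergence criterion).
#' @param config an [engine_config()].
#' @param max_domains per-sequence domain cap.
#' @return a `refinement_result` with status `converged`, `diverged` or
#'   `not_converged`, the iteration log, final seed and final model.
#' @export
refine <- function(seed0, db, cap = 3000, max_iter = 50,
                   config = engine_config(), max_domains = 4L) {
  stopifnot(nrow(seed0$members) >= 2)
  seed <- seed0
  sizes <- nrow(seed$members)
  log <- list()
  status <- "not_converged"
  model <- NULL
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    model <- build_profile(seed$msa, config, name = seed$family_id)
    nxt <- refine_iteration(model, seed, db, max_domains)
    sizes <- c(sizes, nrow(nxt$members))
    log[[iter]] <- list(iteration = iter, size = nrow(nxt$members),
                        threshold = min(nxt$members$score))
    if (nrow(nxt$members) > cap) {
      seed <- nxt
      status <- "diverged"
      break
    }
    if (setequal(member_keys(nxt$members), member_keys(seed$members))) {
      seed <- nxt
      status <- "converged"
      break
    }
    seed <- nxt
  }
  refinement_result(status, iter, sizes, seed, model, log)
}

#' Curate an initial seed after a divergent refinement
#'
#' Scores the seed members against the model and removes the lowest-scoring
#' fraction (at least one sequence). The caller re-enters [refine()]; see
#' [refine_with_curation()] for the full remove-and-retry loop.
#'
#' @param seed the initial [seed_set()] of the divergent refinement.
#' @param model the model to score against.
#' @param db sequence database.
#' @param removal_fraction fraction removed per round (default 0.05, e.g.
#'   70 sequences from a seed of 1390).
#' @return the trimmed [seed_set()].
#' @export
curate_initial_seed <- function(seed, model, db, removal_fraction = 0.05) {
  n <- nrow(seed$members)
  n_rm <- max(1L, round(removal_fraction * n))
  sc <- score_seed_members(model, seed, db)
  drop <- order(sc)[seq_len(n_rm)]
  keep <- setdiff(seq_len(n), drop)
  if (length(keep) == 0) stop("curation removed the entire seed", call. = FALSE)
  seed_set(seed$family_id, seed$members[keep, , drop = FALSE],
           msa(seed$msa$ids[keep], seed$msa$aln[keep]))
}

#' Refinement with progressive curation of the initial seed
#'
#' Runs [refine()]; on divergence, progressively removes the lowest-scoring
#' initial seed sequences ([curate_initial_seed()]) and restarts from
#' scratch, until refinement converges or the seed shrinks below the
#' minimum size (status `aborted_curation`).
#'
#' @inheritParams refine
#' @param removal_fraction per-round removal fraction.
#' @param min_seed minimum seed size to keep trying (default 21).
#' @return a `refinement_result`.
#' @export
refine_with_curation <- function(seed0, db, cap = 3000, max_iter = 50,
                                 config = engine_config(), max_domains = 4L,
                                 removal_fraction = 0.05, min_seed = 21) {
  seed <- seed0
  curation_rounds <- 0
  repeat {
    res <- refine(seed, db, cap = cap, max_iter = max_iter, config = config,
                  max_domains = max_domains)
    if (res$status != "diverged") {
      res$log <- c(res$log, list(list(curation_rounds = curation_rounds)))
      return(res)
    }
    model0 <- build_profile(seed$msa, config, name = seed$family_id)
    seed <- curate_initial_seed(seed, model0, db, removal_fraction)
    curation_rounds <- curation_rounds + 1
    if (nrow(seed$members) < min_seed) {
      return(refinement_result("aborted_curation", res$iterations,
                               res$seed_history_sizes, seed, model0,
                               c(res$log, list(list(curation_rounds = curation_rounds)))))
    }
  }
}

#' Record score cutoffs on a refined model
#'
#' The gathering and trusted cutoffs are both set to the minimum over the
#' seed members of their best domain score under the final model; the noise
#' cutoff is 0.1 bits less.
#'
#' @param model the converged [profile_model()].
#' @param seed the converged [seed_set()].
#' @param db sequence database.
#' @param nc_offset noise cutoff offset below GA (default 0.1 bits).
#' @return the model with `ga`, `tc`, `nc` set.
#' @export
record_cutoffs <- function(model, seed, db, nc_offset = 0.1) {
  sc <- score_seed_members(model, seed, db)
  ga <- min(sc)
  model$ga <- ga
  model$tc <- ga
  model$nc <- ga - nc_offset
  model
}
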