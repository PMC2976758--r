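#' Engine configuration
#'
#' Numerical knobs of the profile-HMM engine.
#'
#' @param background length-20 background amino-acid distribution (sums to 1).
#'   Uniform 1/20 by default so small test models have closed-form scores.
#' @param pseudocount Laplace add-k pseudocount for match emissions (k = 0.1
#'   by default; 0 gives maximum-likelihood emissions).
#' @param trans_prior_weight total prior count added to each state's outgoing
#'   transitions (0 disables smoothing). The prior composition is fixed:
#'   match .9/.05/.05 (MM/MI/MD), insert .5/.5 (IM/II), delete .25/.75
#'   (DM/DD), begin .95/.05 (BM/BD). The delete prior makes gap *extension*
#'   cheap while gap *entry* stays expensive, so terminally truncated
#'   sequences are penalized smoothly but strictly.
#' @return an `engine_config` list.
#' @export
engine_config <- function(background = rep(1 / 20, 20), pseudocount = 0.1,
                          trans_prior_weight = 2) {
  stopifnot(length(background) == 20, abs(sum(background) - 1) < 1e-9,
            pseudocount >= 0, trans_prior_weight >= 0)
  structure(list(background = background, pseudocount = pseudocount,
                 trans_prior_weight = trans_prior_weight),
            class = "engine_config")
}

new_profile_model <- function(name, match_bits, background, tBM, tBD,
                              tMM, tMI, tMD, tIM, tII, tDM, tDD,
                              ga = NA_real_, tc = NA_real_, nc = NA_real_,
                              reliable = TRUE, description = "") {
  L <- nrow(match_bits)
  stopifnot(L >= 1, ncol(match_bits) == 20)
  structure(list(name = name, description = description, L = L,
                 match_bits = match_bits, background = background,
                 tBM = tBM, tBD = tBD, tMM = tMM, tMI = tMI, tMD = tMD,
                 tIM = tIM, tII = tII, tDM = tDM, tDD = tDD,
                 ga = ga, tc = tc, nc = nc, reliable = reliable),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("profile_model '%s': %d match states; GA/TC/NC = %s/%s/%s%s\n",
              x$name, x$L, format(x$ga), format(x$tc), format(x$nc),
              if (isTRUE(x$reliable)) "" else " [unreliable]"))
  invisible(x)
}

#' Alias a profile model
#' @param model a [profile_model()].
#' @param name new model name.
#' @param description new description (kept if missing).
#' @keywords internal
rename_model <- function(model, name, description = NULL) {
  model$name <- name
  if (!is.null(description)) model$description <- description
  model
}

seq_to_int <- function(s) {
  m <- match(strsplit(toupper(s), "")[[1]], AA_ALPHABET20)
  m[is.na(m)] <- 0L  # unknown residues emit background (0 bits)
  as.integer(m)
}

log2p <- function(x) ifelse(x > 0, log2(x), -Inf)

# Normalize observed transition counts with the fixed prior composition.
smooth_trans <- function(counts, prior, weight) {
  p <- counts + prior * weight
  tot <- sum(p)
  if (tot <= 0) p <- prior else p <- p / sum(p)
  log2p(p)
}

#' Build a profile HMM from a multiple sequence alignment
#'
#' Columns with gap fraction below 0.5 become match states. Match emissions
#' are add-k smoothed residue frequencies converted to log-odds (bits)
#' against the background; transition probabilities are estimated from the
#' observed match/insert/delete paths of the rows with fixed-composition
#' prior counts (see [engine_config()]). Sequence weighting is uniform; the
#' redundancy-reduction step upstream does the equivalent work.
#'
#' @param m an [msa()] object (non-empty).
#' @param config an [engine_config()].
#' @param name model name.
#' @param description free-text description.
#' @return a [profile_model()].
#' @export
build_profile <- function(m, config = engine_config(), name = "model",
                          description = "") {
  stopifnot(inherits(m, "msa"))
  if (length(m$ids) == 0) stop("cannot build a profile from an empty MSA", call. = FALSE)
  build_profile_mat(toupper(msa_matrix(m)), config, name, description)
}

# matrix-level worker: `mat` is an uppercase character matrix (rows =
# sequences); callers that rebuild many row-subsets (the jackknife) convert
# once and subset the matrix instead of re-parsing strings
build_profile_mat <- function(mat, config = engine_config(), name = "model",
                              description = "") {
  gapfrac <- colMeans(mat == "-" | mat == ".")
  match_cols <- which(gapfrac < 0.5)
  L <- length(match_cols)
  if (L == 0) stop("degenerate model: MSA has zero match columns", call. = FALSE)
  n <- nrow(mat)
  k <- config$pseudocount
  bg <- config$background

  # emissions (vectorized residue counting over all match columns at once)
  mm <- mat[, match_cols, drop = FALSE]
  code <- match(mm, AA_ALPHABET20)          # NA for gaps and X
  colix <- rep(seq_len(L), each = n)
  ok <- !is.na(code)
  counts <- matrix(tabulate(code[ok] + 20L * (colix[ok] - 1L), nbins = 20L * L),
                   nrow = L, ncol = 20, byrow = TRUE)
  p <- counts + k
  rs <- rowSums(p)
  zero <- rs == 0
  if (any(zero)) p[zero, ] <- matrix(bg, sum(zero), 20, byrow = TRUE)
  p[!zero, ] <- p[!zero, , drop = FALSE] / rs[!zero]
  em <- log2(sweep(p, 2, bg, "/"))
  dimnames(em) <- list(NULL, AA_ALPHABET20)

  # per-row state sequence over match columns plus insert counts between them
  is_gap <- mat == "-" | mat == "."
  mstate <- !is_gap[, match_cols, drop = FALSE]          # TRUE = M, FALSE = D
  # residues in non-match columns are insertions attributed to the preceding node
  node_of_col <- findInterval(seq_len(ncol(mat)), match_cols)
  ins_cols <- setdiff(seq_len(ncol(mat)), match_cols)
  inscnt <- matrix(0L, n, L + 1)                         # node 0 .. L
  if (length(ins_cols) > 0) {
    for (cc in ins_cols) {
      nd <- node_of_col[cc] + 1L
      inscnt[, nd] <- inscnt[, nd] + as.integer(!is_gap[, cc])
    }
  }

  cMM <- cMI <- cMD <- numeric(L); cIM <- cII <- numeric(L)
  cDM <- cDD <- numeric(L); cBM <- cBD <- 0
  first <- mstate[, 1]
  cBM <- sum(first); cBD <- sum(!first)
  if (L >= 2) {
    for (j in seq_len(L - 1)) {
      from_m <- mstate[, j]
      to_m <- mstate[, j + 1]
      ins <- inscnt[, j + 1]  # insertions between node j and j+1
      # rows with insertions: entry counted from M (lenient for D-adjacent
      # inserts, which the internal aligners never produce), then II runs,
      # then exit into the next node's state
      has_i <- ins > 0
      cMI[j] <- cMI[j] + sum(has_i)
      cII[j] <- cII[j] + sum(pmax(ins - 1L, 0L))
      cIM[j] <- cIM[j] + sum(has_i & to_m)
      # direct transitions for rows without insertions
      cMM[j] <- cMM[j] + sum(from_m & !has_i & to_m)
      cMD[j] <- cMD[j] + sum(from_m & !has_i & !to_m)
      cDM[j] <- cDM[j] + sum(!from_m & !has_i & to_m)
      cDD[j] <- cDD[j] + sum(!from_m & !has_i & !to_m)
      # insert rows leaving into a delete state: count as I->M then M->D proxy
      cMD[j] <- cMD[j] + sum(has_i & !to_m)
    }
  }

  w <- config$trans_prior_weight
  tMM <- tMI <- tMD <- tIM <- tII <- tDM <- tDD <- numeric(L)
  for (j in seq_len(L)) {
    if (j < L) {
      mtr <- smooth_trans(c(cMM[j], cMI[j], cMD[j]), c(.9, .05, .05), w)
      itr <- smooth_trans(c(cIM[j], cII[j]), c(.5, .5), w)
      dtr <- smooth_trans(c(cDM[j], cDD[j]), c(.25, .75), w)
      tMM[j] <- mtr[1]; tMI[j] <- mtr[2]; tMD[j] <- mtr[3]
      tIM[j] <- itr[1]; tII[j] <- itr[2]
      tDM[j] <- dtr[1]; tDD[j] <- dtr[2]
    } else {
      tMM[j] <- 0; tMI[j] <- -Inf; tMD[j] <- -Inf  # node L -> E, cost 0
      tIM[j] <- 0; tII[j] <- -Inf
      tDM[j] <- 0; tDD[j] <- -Inf
    }
  }
  btr <- smooth_trans(c(cBM, cBD), c(.95, .05), w)

  mdl <- new_profile_model(name = name, description = description,
                           match_bits = em, background = bg,
                           tBM = btr[1], tBD = btr[2],
                           tMM = tMM, tMI = tMI, tMD = tMD,
                           tIM = tIM, tII = tII, tDM = tDM, tDD = tDD)
  attr(mdl, "match_cols") <- match_cols
  mdl
}

#' Glocal Viterbi alignment of a sequence to a profile model
#'
#' Finds the maximum-scoring path that traverses the model globally
#' (M1..ML, deletions allowed at cost) while matching any subsequence of the
#' target (flanking residues are skipped at zero cost). Ties are broken
#' deterministically: leftmost envelope, then fewest insertions.
#'
#' @param model a [profile_model()].
#' @param seq a residue string (non-empty).
#' @return list with `score` (bits), `env` = c(start, end) 1-based inclusive
#'   envelope of emitting states (c(0, 0) for an all-delete path), and `path`
#'   (per-node state 1 = match / 3 = delete, matched sequence positions, and
#'   insert counts per node).
#' @export
viterbi_glocal <- function(model, seq) {
  stopifnot(inherits(model, "profile_model"), nzchar(seq))
  s <- seq_to_int(seq)
  r <- viterbi_glocal_cpp(model$match_bits, model$tBM, model$tBD,
                          model$tMM, model$tMI, model$tMD,
                          model$tIM, model$tII, model$tDM, model$tDD, s)
  list(score = r$score, env = r$env,
       path = list(states = r$states, mpos = r$mpos, ins = r$ins))
}

# score-only glocal Viterbi (same recurrences, no traceback)
fast_score <- function(model, seq) {
  viterbi_score_cpp(model$match_bits, model$tBM, model$tBD,
                    model$tMM, model$tMI, model$tMD,
                    model$tIM, model$tII, model$tDM, model$tDD,
                    seq_to_int(seq))
}

#' Greedy extraction of the best non-overlapping domain hits
#'
#' Takes the best glocal hit, masks its envelope, and repeats on the
#' remaining unmasked segments. Hits are non-overlapping and reported in
#' descending score order.
#'
#' @param model a [profile_model()].
#' @param seq residue string.
#' @param max_domains maximum number of hits to report (>= 1).
#' @param sequence_id id recorded in the output rows.
#' @param min_score stop when the best remaining hit falls below this score.
#' @return data.frame with columns `sequence_id`, `model_name`, `start`,
#'   `end`, `score`, `matched_subsequence`.
#' @export
best_domains <- function(model, seq, max_domains = 1L, sequence_id = "",
                         min_score = -Inf) {
  stopifnot(max_domains >= 1)
  n <- nchar(seq)
  segments <- list(c(1L, n))
  seg_scores <- fast_score(model, seq)
  hits <- list()
  while (length(hits) < max_domains && length(segments) > 0) {
    best_k <- which.max(seg_scores)
    if (!is.finite(seg_scores[best_k]) || seg_scores[best_k] < min_score) break
    sg <- segments[[best_k]]
    best <- viterbi_glocal(model, substr(seq, sg[1], sg[2]))
    if (best$env[1] == 0) break  # all-delete path: no emitting state, stop
    sg <- segments[[best_k]]
    st <- sg[1] + best$env[1] - 1L
    en <- sg[1] + best$env[2] - 1L
    hits[[length(hits) + 1]] <- data.frame(
      sequence_id = sequence_id, model_name = model$name,
      start = st, end = en, score = best$score,
      matched_subsequence = substr(seq, st, en), stringsAsFactors = FALSE)
    left <- c(sg[1], st - 1L); right <- c(en + 1L, sg[2])
    segments <- segments[-best_k]
    seg_scores <- seg_scores[-best_k]
    for (sg2 in list(left, right)) {
      if (sg2[2] - sg2[1] + 1L >= 10L) {
        segments <- c(segments, list(sg2))
        seg_scores <- c(seg_scores, fast_score(model, substr(seq, sg2[1], sg2[2])))
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(sequence_id = character(0), model_name = character(0),
                      start = integer(0), end = integer(0), score = numeric(0),
                      matched_subsequence = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(-out$score), , drop = FALSE]
}

#' Search a sequence database with a profile model
#'
#' Runs [best_domains()] on every database sequence and keeps all domain
#' hits scoring at or above the threshold, sorted by descending score.
#'
#' @param model a [profile_model()].
#' @param db a [seq_db()] data frame.
#' @param threshold bit-score inclusion threshold (finite).
#' @param max_domains per-sequence cap on reported domains.
#' @return data.frame of domain hits (see [best_domains()]).
#' @export
search_db <- function(model, db, threshold, max_domains = 4L) {
  stopifnot(is.finite(threshold))
  res <- lapply(seq_len(nrow(db)), function(k) {
    # a subsequence hit can never beat the whole-sequence optimum, so a
    # cheap score-only pass safely gates the traceback search
    if (fast_score(model, db$residues[k]) < threshold) return(NULL)
    h <- best_domains(model, db$residues[k], max_domains = max_domains,
                      sequence_id = db$id[k], min_score = threshold)
    h[h$score >= threshold, , drop = FALSE]
  })
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0) {
    return(best_domains(build_dummy(), "A")[0, ])
  }
  rownames(out) <- NULL
  out[order(-out$score), , drop = FALSE]
}

# empty-hit-table template helper
build_dummy <- function() {
  em <- matrix(0, 1, 20, dimnames = list(NULL, AA_ALPHABET20))
  new_profile_model("empty", em, rep(1 / 20, 20), 0, -Inf,
                    0, -Inf, -Inf, 0, -Inf, 0, -Inf)
}

#' Align sequences against a profile model
#'
#' Renders each sequence's glocal Viterbi path into a common coordinate
#' system: one uppercase column per match state, lowercase left-justified
#' insert blocks between them, and flanking residues carried as insert
#' blocks before the first and after the last match state, so that degapping
#' a row reproduces the input sequence exactly.
#'
#' @param model a [profile_model()].
#' @param seqs a [seq_db()] data frame (non-empty).
#' @return an [msa()] with attributes `match_cols` (logical per column) and
#'   `scores` (per-row glocal bit scores).
#' @export
align_to_model <- function(model, seqs) {
  if (is.null(seqs) || nrow(seqs) == 0) stop("no sequences to align", call. = FALSE)
  L <- model$L
  paths <- lapply(seq_len(nrow(seqs)), function(k) viterbi_glocal(model, seqs$residues[k]))
  # insert block widths: node 0 (leading flank) .. node L (trailing flank)
  blk <- matrix(0L, nrow(seqs), L + 1)
  for (k in seq_along(paths)) {
    p <- paths[[k]]
    n <- nchar(seqs$residues[k])
    env <- p$env
    blk[k, 1] <- if (env[1] > 0) env[1] - 1L else n
    blk[k, L + 1] <- if (env[1] > 0) n - env[2] else 0L
    if (L >= 2) blk[k, 2:L] <- p$path$ins[1:(L - 1)]
  }
  width <- apply(blk, 2, max)
  rows <- character(nrow(seqs))
  for (k in seq_along(paths)) {
    p <- paths[[k]]
    chars <- strsplit(seqs$residues[k], "")[[1]]
    out <- character(0)
    pos <- 0L  # residues consumed so far
    # leading flank block (right-justified against M1)
    lead <- blk[k, 1]
    out <- c(out, rep("-", width[1] - lead),
             if (lead > 0) tolower(chars[seq_len(lead)]) else character(0))
    pos <- lead
    for (j in seq_len(L)) {
      if (p$path$states[j] == 1) {
        pos <- p$path$mpos[j]
        out <- c(out, toupper(chars[pos]))
      } else {
        out <- c(out, "-")
      }
      bw <- width[j + 1]
      if (bw > 0) {
        nk <- blk[k, j + 1]
        ins <- if (nk > 0) tolower(chars[pos + seq_len(nk)]) else character(0)
        out <- c(out, ins, rep("-", bw - nk))
        pos <- pos + nk
      }
    }
    rows[k] <- paste(out, collapse = "")
  }
  m <- msa(seqs$id, rows)
  is_match <- logical(m$ncol)
  mcols <- cumsum(c(width[1] + 1,
                    if (L >= 2) width[2:L] + 1 else integer(0)))
  is_match[mcols] <- TRUE
  attr(m, "match_cols") <- is_match
  attr(m, "scores") <- vapply(paths, function(p) p$score, numeric(1))
  m
}
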