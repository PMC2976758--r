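#' Pairwise sequence identity
#'
#' Identity is the number of identical residues on the optimal global
#' alignment divided by the length of the longer sequence. The alignment is
#' a deterministic Needleman-Wunsch with BLOSUM62 and affine gap penalties
#' (open 11, extend 1), standing in for pairwise BLAST; the denominator rule
#' is preserved exactly, so fragment pairs are down-weighted by coverage.
#'
#' @param a,b residue strings (non-empty).
#' @return identity fraction in \[0, 1\]; symmetric in its arguments.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence in identity computation", call. = FALSE)
  if (a == b) return(1)
  nid <- Biostrings::nmatch(align_global(a, b))
  nid / max(nchar(a), nchar(b))
}

blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})

align_global <- function(a, b) {
  Biostrings::pairwiseAlignment(Biostrings::AAString(a), Biostrings::AAString(b),
                                substitutionMatrix = blosum62(),
                                gapOpening = 11, gapExtension = 1,
                                type = "global")
}

# identity of many patterns against one subject, same rule as pairwise_identity
identity_to_many <- function(patterns, subject) {
  if (length(patterns) == 0) return(numeric(0))
  al <- Biostrings::pairwiseAlignment(Biostrings::AAStringSet(patterns),
                                      Biostrings::AAString(subject),
                                      substitutionMatrix = blosum62(),
                                      gapOpening = 11, gapExtension = 1,
                                      type = "global")
  Biostrings::nmatch(al) / pmax(nchar(patterns), nchar(subject))
}

#' Greedy identity clustering
#'
#' cd-hit style: sequences are sorted by decreasing length (id-lexicographic
#' tie-break) and each joins the first existing cluster whose representative
#' it matches at more than `threshold` identity, else founds a new cluster.
#' Representatives are therefore mutually at or below the threshold.
#'
#' @param db a [seq_db()] data frame.
#' @param threshold identity threshold in (0, 1\]; membership requires
#'   identity strictly above it.
#' @return data.frame with columns `cluster_id`, `representative`, `member`,
#'   `identity_to_rep`; one row per member, clusters numbered in foundation
#'   order.
#' @export
greedy_cluster <- function(db, threshold = 0.40) {
  stopifnot(threshold > 0, threshold <= 1)
  ord <- order(-nchar(db$residues), db$id)
  reps <- character(0)
  rep_seq <- character(0)
  rows <- vector("list", nrow(db))
  for (k in ord) {
    idv <- identity_to_many(rep_seq, db$residues[k])
    hit <- which(idv > threshold | idv == 1)  # exact duplicates always join
    if (length(hit) > 0) {
      j <- hit[1]
      rows[[k]] <- data.frame(cluster_id = j, representative = reps[j],
                              member = db$id[k], identity_to_rep = idv[j],
                              stringsAsFactors = FALSE)
    } else {
      reps <- c(reps, db$id[k])
      rep_seq <- c(rep_seq, db$residues[k])
      j <- length(reps)
      rows[[k]] <- data.frame(cluster_id = j, representative = db$id[k],
                              member = db$id[k], identity_to_rep = 1,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[ord])
  rownames(out) <- NULL
  out[order(out$cluster_id), , drop = FALSE]
}

#' Select clusters large enough to seed a family model
#'
#' @param clusters output of [greedy_cluster()].
#' @param min_size minimum cluster size; the default keeps clusters with
#'   more than 20 members (i.e. at least 21).
#' @return the subset of cluster rows belonging to qualifying clusters.
#' @export
select_seed_clusters <- function(clusters, min_size = 21) {
  sizes <- table(clusters$cluster_id)
  keep <- names(sizes)[sizes >= min_size]
  if (length(keep) == 0) {
    warning("no cluster reaches the minimum seed size", call. = FALSE)
  }
  clusters[clusters$cluster_id %in% as.integer(keep), , drop = FALSE]
}

#' Redundancy reduction by greedy representative selection
#'
#' Sequences are processed by decreasing length; a sequence is kept iff its
#' identity to every already-kept representative is below the threshold.
#'
#' @param db a [seq_db()] data frame.
#' @param threshold identity ceiling (default 0.90: output representatives
#'   are mutually below 90 percent identity).
#' @return the reduced [seq_db()] subset, one representative per redundancy
#'   group, in input order.
#' @export
redundancy_reduce <- function(db, threshold = 0.90) {
  if (nrow(db) == 0) return(db)
  ord <- order(-nchar(db$residues), db$id)
  kept <- integer(0)
  kept_seq <- character(0)
  for (k in ord) {
    idv <- identity_to_many(kept_seq, db$residues[k])
    if (all(idv < threshold)) {
      kept <- c(kept, k)
      kept_seq <- c(kept_seq, db$residues[k])
    }
  }
  db[sort(kept), , drop = FALSE]
}

#' Star alignment around a representative sequence
#'
#' De novo aligner used for initial cluster seed sets and post-curation
#' rebuilds: every member is globally aligned to the representative and the
#' pairwise alignments are merged into a common coordinate system (the
#' representative's columns, plus insert blocks where any member inserts
#' relative to it).
#'
#' @param db a [seq_db()] data frame of cluster members.
#' @param representative id of the representative (defaults to first row).
#' @return an [msa()] object; degapping reproduces the inputs.
#' @export
star_align <- function(db, representative = db$id[1]) {
  stopifnot(nrow(db) >= 1)
  ridx <- match(representative, db$id)
  if (is.na(ridx)) stop("representative not in input set", call. = FALSE)
  rep_seq <- db$residues[ridx]
  rl <- nchar(rep_seq)
  others <- setdiff(seq_len(nrow(db)), ridx)
  # per member: residue aligned to each rep position + inserts after each
  at_pos <- matrix("-", nrow(db), rl)
  ins_after <- matrix("", nrow(db), rl + 1)  # keyed by rep position 0..rl
  at_pos[ridx, ] <- strsplit(rep_seq, "")[[1]]
  for (k in others) {
    al <- align_global(db$residues[k], rep_seq)
    p <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
    s <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
    r <- 0L
    for (cc in seq_along(p)) {
      if (s[cc] != "-") {
        r <- r + 1L
        at_pos[k, r] <- p[cc]
      } else if (p[cc] != "-") {
        ins_after[k, r + 1L] <- paste0(ins_after[k, r + 1L], p[cc])
      }
    }
  }
  width <- apply(nchar(ins_after), 2, max)
  pad <- function(x, w) paste0(tolower(x), strrep("-", w - nchar(x)))
  rows <- vapply(seq_len(nrow(db)), function(k) {
    out <- pad(ins_after[k, 1], width[1])
    for (r in seq_len(rl)) {
      out <- paste0(out, toupper(at_pos[k, r]),
                    if (width[r + 1] > 0) pad(ins_after[k, r + 1], width[r + 1]) else "")
    }
    out
  }, character(1))
  msa(db$id, rows)
}
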