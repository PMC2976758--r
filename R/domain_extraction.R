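#' Pairing rules for N/C domain extraction
#'
#' @param max_linker maximum residue gap between an N-domain hit and a
#'   C-domain hit for them to be fused into one domain-pair region.
#' @param linker_len expected linker length used when expanding singlets.
#' @param margin small error margin added when expanding singlets.
#' @return a `pairing_rules` list.
#' @export
pairing_rules <- function(max_linker = 40, linker_len = 12, margin = 15) {
  structure(list(max_linker = max_linker, linker_len = linker_len,
                 margin = margin), class = "pairing_rules")
}

region_df <- function(sequence_id = character(0), start = integer(0),
                      end = integer(0), has_n_hit = logical(0),
                      has_c_hit = logical(0), expanded = logical(0),
                      pair_index = integer(0)) {
  data.frame(sequence_id = sequence_id, start = as.integer(start),
             end = as.integer(end), has_n_hit = has_n_hit,
             has_c_hit = has_c_hit, expanded = expanded,
             pair_index = as.integer(pair_index), stringsAsFactors = FALSE)
}

#' Pair N-terminal and C-terminal domain hits into domain-pair regions
#'
#' An N hit and a C hit on the same sequence with the N hit ending before
#' the C hit starts and a gap of at most `max_linker` residues are fused
#' into one region spanning both (linker included). Pairing is greedy left
#' to right, matching the tandem-repeat architecture of multidomain
#' superfamily members; unpaired hits become singlet regions. Hits that
#' would overlap an already formed region are dropped in score order.
#'
#' @param hits_n,hits_c domain hit tables (see [best_domains()]) from the
#'   N-domain and C-domain query models.
#' @param rules a [pairing_rules()] object.
#' @return a region data.frame: `sequence_id`, `start`, `end`, `has_n_hit`,
#'   `has_c_hit`, `expanded`, `pair_index` (ordinal along the sequence).
#' @export
pair_domains <- function(hits_n, hits_c, rules = pairing_rules()) {
  ids <- union(hits_n$sequence_id, hits_c$sequence_id)
  out <- list()
  for (sid in ids) {
    hn <- hits_n[hits_n$sequence_id == sid, , drop = FALSE]
    hc <- hits_c[hits_c$sequence_id == sid, , drop = FALSE]
    hn <- hn[order(hn$start), , drop = FALSE]
    hc <- hc[order(hc$start), , drop = FALSE]
    used_c <- logical(nrow(hc))
    regions <- list()
    for (i in seq_len(nrow(hn))) {
      cand <- which(!used_c & hc$start > hn$end[i] &
                      hc$start - hn$end[i] - 1 <= rules$max_linker)
      if (length(cand) > 0) {
        j <- cand[1]
        used_c[j] <- TRUE
        regions[[length(regions) + 1]] <-
          list(start = hn$start[i], end = hc$end[j], n = TRUE, c = TRUE,
               score = hn$score[i] + hc$score[j])
      } else {
        regions[[length(regions) + 1]] <-
          list(start = hn$start[i], end = hn$end[i], n = TRUE, c = FALSE,
               score = hn$score[i])
      }
    }
    for (j in which(!used_c)) {
      regions[[length(regions) + 1]] <-
        list(start = hc$start[j], end = hc$end[j], n = FALSE, c = TRUE,
             score = hc$score[j])
    }
    # enforce non-overlap: keep higher-scoring regions
    if (length(regions) > 1) {
      sc <- vapply(regions, function(r) r$score, numeric(1))
      keep <- logical(length(regions))
      taken <- matrix(numeric(0), 0, 2)
      for (i in order(-sc)) {
        r <- regions[[i]]
        clash <- nrow(taken) > 0 &&
          any(r$start <= taken[, 2] & r$end >= taken[, 1])
        if (!clash) {
          keep[i] <- TRUE
          taken <- rbind(taken, c(r$start, r$end))
        }
      }
      regions <- regions[keep]
    }
    if (length(regions) == 0) next
    st <- vapply(regions, function(r) r$start, numeric(1))
    ord <- order(st)
    regions <- regions[ord]
    out[[sid]] <- region_df(
      sequence_id = rep(sid, length(regions)),
      start = vapply(regions, function(r) r$start, numeric(1)),
      end = vapply(regions, function(r) r$end, numeric(1)),
      has_n_hit = vapply(regions, function(r) r$n, logical(1)),
      has_c_hit = vapply(regions, function(r) r$c, logical(1)),
      expanded = rep(FALSE, length(regions)),
      pair_index = seq_along(regions))
  }
  if (length(out) == 0) return(region_df())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expand a singlet domain hit towards its missing partner
#'
#' A lone N-domain hit is extended C-terminally (and a lone C-domain hit
#' N-terminally) by the expected linker length plus the expected partner
#' domain length plus a small error margin, clipped at the sequence bounds,
#' so that a partner domain the query model failed to detect is still
#' captured in the extracted region.
#'
#' @param hit one-row domain hit (from the N or C query model).
#' @param partner_expected_len expected partner domain length in residues
#'   (typically the partner model's match state count).
#' @param linker_len expected linker length.
#' @param margin error margin in residues.
#' @param seq_len length of the parent sequence.
#' @param side `"N"` if the hit is an N-domain singlet, `"C"` otherwise.
#' @return a one-row region data.frame with `expanded = TRUE`.
#' @export
expand_singlet <- function(hit, partner_expected_len, linker_len = 12,
                           margin = 15, seq_len, side = c("N", "C")) {
  side <- match.arg(side)
  if (side == "N") {
    st <- hit$start
    en <- min(seq_len, hit$end + linker_len + partner_expected_len + margin)
    region_df(hit$sequence_id, st, en, TRUE, FALSE, TRUE, 1L)
  } else {
    st <- max(1, hit$start - linker_len - partner_expected_len - margin)
    region_df(hit$sequence_id, st, hit$end, FALSE, TRUE, TRUE, 1L)
  }
}

#' Drop regions shorter than a minimum length
#'
#' Partial sequences shorter than the minimum (default 250 residues) are
#' removed before clustering; the removal count is reported as an attribute.
#'
#' @param regions region data.frame.
#' @param min_len minimum region length in residues; regions strictly
#'   shorter are removed.
#' @return filtered regions with attribute `n_removed`.
#' @export
filter_length <- function(regions, min_len = 250) {
  len <- regions$end - regions$start + 1
  out <- regions[len >= min_len, , drop = FALSE]
  attr(out, "n_removed") <- nrow(regions) - nrow(out)
  out
}

#' Extract domain-pair regions from a database
#'
#' Runs the N and C query models over the database, pairs their hits, expands
#' singlets towards the missing partner and applies the length filter. The
#' returned records carry region coordinates in their ids
#' (`<sequence_id>/<start>-<end>`).
#'
#' @param db a [seq_db()] data frame.
#' @param n_model,c_model query [profile_model()]s for the N- and C-terminal
#'   domains.
#' @param rules a [pairing_rules()] object.
#' @param threshold bit-score threshold for the query model search.
#' @param min_len minimum region length (see [filter_length()]).
#' @param max_domains per-sequence cap on query model hits.
#' @return list with `regions` (region table) and `records` (a [seq_db()] of
#'   extracted region sequences inheriting taxonomy from their parents).
#' @export
extract_regions <- function(db, n_model, c_model, rules = pairing_rules(),
                            threshold = 0, min_len = 250, max_domains = 4L) {
  hn <- search_db(n_model, db, threshold, max_domains)
  hc <- search_db(c_model, db, threshold, max_domains)
  paired <- pair_domains(hn, hc, rules)
  # expand singlets towards the absent partner
  if (nrow(paired) > 0) {
    slen <- nchar(db$residues)[match(paired$sequence_id, db$id)]
    for (k in seq_len(nrow(paired))) {
      if (paired$has_n_hit[k] && !paired$has_c_hit[k]) {
        paired$end[k] <- min(slen[k], paired$end[k] + rules$linker_len +
                               c_model$L + rules$margin)
        paired$expanded[k] <- TRUE
      } else if (!paired$has_n_hit[k] && paired$has_c_hit[k]) {
        paired$start[k] <- max(1, paired$start[k] - rules$linker_len -
                                 n_model$L - rules$margin)
        paired$expanded[k] <- TRUE
      }
    }
    # expansion may create overlaps on multidomain sequences: clip at the
    # neighbouring region boundary
    for (sid in unique(paired$sequence_id)) {
      ix <- which(paired$sequence_id == sid)
      if (length(ix) > 1) {
        ix <- ix[order(paired$start[ix])]
        for (t in seq_len(length(ix) - 1)) {
          if (paired$end[ix[t]] >= paired$start[ix[t + 1]]) {
            paired$end[ix[t]] <- paired$start[ix[t + 1]] - 1L
          }
        }
      }
    }
  }
  regions <- filter_length(paired, min_len)
  idx <- match(regions$sequence_id, db$id)
  rec <- seq_db(
    id = sprintf("%s/%d-%d", regions$sequence_id, regions$start, regions$end),
    residues = substr(db$residues[idx], regions$start, regions$end),
    description = db$description[idx],
    review_tier = db$review_tier[idx],
    kingdom = db$kingdom[idx],
    species_group = db$species_group[idx])
  list(regions = regions, records = rec)
}
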