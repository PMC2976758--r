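#' Per-column conservation scores
#'
#' The default scorer is the modal-residue frequency: 100 times the
#' frequency of the most common residue in the column, with gap rows
#' counted in the denominator. The scorer is pluggable so an alternative
#' conservation index can be swapped in without touching callers.
#'
#' @param m an [msa()] (non-empty).
#' @param scorer optional function(column characters) -> percent in
#'   \[0, 100\]; `NULL` uses the default modal-frequency scorer.
#' @return numeric vector of per-column percentages.
#' @export
cscore_profile <- function(m, scorer = NULL) {
  stopifnot(inherits(m, "msa"), length(m$ids) > 0)
  mat <- toupper(msa_matrix(m))
  if (is.null(scorer)) {
    scorer <- function(col) {
      res <- col[col %in% AA_ALPHABET20]
      if (length(res) == 0) return(0)
      100 * max(table(res)) / length(col)
    }
  }
  apply(mat, 2, scorer)
}

modal_residue <- function(col) {
  res <- col[col %in% AA_ALPHABET20]
  if (length(res) == 0) return(NA_character_)
  tab <- sort(table(res), decreasing = TRUE)
  names(tab)[1]
}

#' Conserved-position counts per domain and their ratio
#'
#' Splits the alignment at a boundary column into an N-side (catalytic,
#' GroES-like) block and a C-side (coenzyme-binding, Rossmann) block and
#' counts the columns whose conservation score exceeds the threshold in
#' each.
#'
#' @param m an [msa()].
#' @param boundary_column last column of the catalytic (N-side) block.
#' @param threshold conservation threshold in percent (strictly exceeded).
#' @param scorer optional scorer passed to [cscore_profile()].
#' @return list with `catalytic_count`, `coenzyme_count` and `ratio`
#'   (catalytic / coenzyme, rounded to 2 decimals; `NA` when the coenzyme
#'   count is zero).
#' @export
domain_conservation_counts <- function(m, boundary_column, threshold = 95,
                                       scorer = NULL) {
  cs <- cscore_profile(m, scorer)
  stopifnot(boundary_column >= 1, boundary_column < length(cs))
  cat_n <- sum(cs[seq_len(boundary_column)] > threshold)
  coe_n <- sum(cs[(boundary_column + 1):length(cs)] > threshold)
  list(catalytic_count = cat_n, coenzyme_count = coe_n,
       ratio = if (coe_n > 0) round(cat_n / coe_n, 2) else NA_real_)
}

AA_CHARGE <- c(K = 1, R = 1, D = -1, E = -1)

residue_charge <- function(x) {
  ch <- AA_CHARGE[x]
  ch[is.na(ch)] <- 0
  unname(ch)
}

#' Conserved net charge of a family alignment
#'
#' Sums the charges of the modal residues (K/R = +1, D/E = -1, others 0)
#' over all columns whose conservation score exceeds the threshold, optionally
#' excluding named columns (e.g. metal-ligand glutamates).
#'
#' @param m an [msa()].
#' @param threshold conservation threshold in percent.
#' @param excluded_columns column indices excluded from the sum.
#' @param scorer optional scorer passed to [cscore_profile()].
#' @return integer net charge.
#' @export
conserved_net_charge <- function(m, threshold = 95,
                                 excluded_columns = integer(0), scorer = NULL) {
  cs <- cscore_profile(m, scorer)
  mat <- toupper(msa_matrix(m))
  cols <- setdiff(which(cs > threshold), excluded_columns)
  if (length(cols) == 0) return(0L)
  modal <- vapply(cols, function(j) modal_residue(mat[, j]), character(1))
  as.integer(sum(residue_charge(modal)))
}

#' Average net charge over the rows of an alignment
#'
#' @param m an [msa()].
#' @return mean over rows of the per-row net charge within the alignment
#'   span (K/R = +1, D/E = -1).
#' @export
average_net_charge <- function(m) {
  mat <- toupper(msa_matrix(m))
  mean(apply(mat, 1, function(row) sum(residue_charge(row))))
}

#' Family-level summary statistics
#'
#' Size, reviewed-sequence count, mean and sample standard deviation of all
#' pairwise identities among the seed regions (in percent), and kingdom
#' counts and percentages. Members of the Unclassified division are counted
#' in the family size but disregarded for the kingdom percentages.
#'
#' @param records [seq_db()] of the family's seed region sequences with
#'   kingdom labels.
#' @param family_id family identifier.
#' @param name family name (free text).
#' @param max_pairs subsample cap on the number of identity pairs evaluated
#'   (all pairs when below the cap; deterministic subsample above it).
#' @return one-row data.frame in the family property table layout
#'   (`family_id`, `name`, `size`, `swissprot_count`, `pcid_avg`,
#'   `pcid_std`, `n_euk`, `n_bact`, `n_arch`).
#' @export
family_summary <- function(records, family_id = "", name = "",
                           max_pairs = 2000) {
  n <- nrow(records)
  stopifnot(n >= 1)
  pc <- c()
  if (n >= 2) {
    pairs <- utils::combn(n, 2)
    if (ncol(pairs) > max_pairs) {
      sel <- round(seq(1, ncol(pairs), length.out = max_pairs))
      pairs <- pairs[, sel, drop = FALSE]
    }
    # batch alignments by shared second pair member to cut call overhead
    pc <- numeric(0)
    for (j in unique(pairs[2, ])) {
      firsts <- pairs[1, pairs[2, ] == j]
      pc <- c(pc, identity_to_many(records$residues[firsts],
                                   records$residues[j]))
    }
    pc <- pc * 100
  }
  kg <- records$kingdom
  data.frame(family_id = family_id, name = name, size = n,
             swissprot_count = sum(records$review_tier == "reviewed"),
             pcid_avg = if (length(pc)) mean(pc) else 100,
             pcid_std = if (length(pc) > 1) stats::sd(pc) else 0,
             n_euk = sum(kg == "Eukaryota"),
             n_bact = sum(kg == "Bacteria"),
             n_arch = sum(kg == "Archaea"),
             stringsAsFactors = FALSE)
}

#' Superfamily-level aggregate report
#'
#' Aggregates a family property table (and optionally the per-kingdom zinc
#' class counts) into the headline numbers of a subdivision study: totals,
#' size range, the average-of-averages of within-family identity, database
#' coverage, kingdom representation fractions and per-kingdom zinc-class
#' percentages.
#'
#' @param table1_rows family property table (see [load_family_table()]).
#' @param table3_rows optional per-kingdom zinc class counts.
#' @param total_domain_pairs total domain pairs found in the database
#'   (coverage denominator); `NA` skips coverage.
#' @return list of aggregate statistics.
#' @export
superfamily_report <- function(table1_rows, table3_rows = NULL,
                               total_domain_pairs = NA) {
  t1 <- table1_rows
  kn <- t1[c("n_euk", "n_bact", "n_arch")]
  purely <- function(col) {
    other <- setdiff(names(kn), col)
    mean(t1[[col]] > 0 & rowSums(kn[other]) == 0)
  }
  out <- list(
    n_families = nrow(t1),
    total_members = sum(t1$size),
    size_min = min(t1$size), size_max = max(t1$size),
    size_mean = mean(t1$size),
    pcid_avg_of_avgs = mean(t1$pcid_avg),
    pcid_avg_sd = stats::sd(t1$pcid_avg),
    coverage = if (is.na(total_domain_pairs)) NA_real_ else
      100 * sum(t1$size) / total_domain_pairs,
    frac_purely_eukaryotic = purely("n_euk"),
    frac_purely_bacterial = purely("n_bact"),
    frac_archaea_represented = mean(t1$n_arch > 0),
    frac_all_kingdoms = mean(t1$n_euk > 0 & t1$n_bact > 0 & t1$n_arch > 0))
  if (!is.null(table3_rows)) {
    t3 <- table3_rows
    out$zn_class_pct <- data.frame(
      kingdom = t3$kingdom,
      pct_zn0 = 100 * t3$zn0 / (t3$zn0 + t3$zn2),
      pct_zn2 = 100 * t3$zn2 / (t3$zn0 + t3$zn2),
      stringsAsFactors = FALSE)
  }
  out
}

#' Scan an alignment for a degenerate sequence motif
#'
#' Slides the motif (residue letters plus `x` wildcards) across the
#' alignment columns and reports every window where at least `min_fraction`
#' of the rows match it contiguously (gap characters never match).
#'
#' @param m an [msa()].
#' @param pattern motif such as `"GxGxxG"`.
#' @param min_fraction minimum matching row fraction for a window to be
#'   reported.
#' @return data.frame with `column` (window start) and `match_fraction`.
#' @export
motif_scan <- function(m, pattern = "GxGxxG", min_fraction = 0.5) {
  stopifnot(nzchar(pattern))
  pat <- strsplit(toupper(pattern), "")[[1]]
  if (any(!pat %in% c(AA_ALPHABET20, "X"))) {
    stop("motif may contain residue letters and 'x' wildcards only", call. = FALSE)
  }
  mat <- toupper(msa_matrix(m))
  w <- length(pat)
  nc <- ncol(mat)
  if (nc < w) return(data.frame(column = integer(0), match_fraction = numeric(0)))
  res <- lapply(seq_len(nc - w + 1), function(j) {
    win <- mat[, j:(j + w - 1), drop = FALSE]
    ok <- rep(TRUE, nrow(win))
    for (t in seq_len(w)) {
      ok <- ok & if (pat[t] == "X") win[, t] %in% AA_ALPHABET20
                 else win[, t] == pat[t]
    }
    data.frame(column = j, match_fraction = mean(ok))
  })
  out <- do.call(rbind, res)
  out[out$match_fraction >= min_fraction, , drop = FALSE]
}
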