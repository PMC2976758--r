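#' Parameters for synthetic superfamily generation
#'
#' Describes a two-domain protein superfamily with planted family structure:
#' many families of high within-family identity, low between-family
#' identity, fragmentary members, multidomain (tandem domain-pair) members,
#' orphan sequences and kingdom labels.
#'
#' @param n_families number of planted families.
#' @param family_sizes integer vector of family sizes (`NULL`: drawn
#'   uniformly from `size_range`).
#' @param size_range range family sizes are drawn from when `family_sizes`
#'   is `NULL`.
#' @param within_identity_target per-family target pairwise identity among
#'   members (recycled; `NULL`: drawn uniformly from `within_range`).
#' @param within_range sampling range for within-family identity targets.
#' @param between_identity_max upper bound on between-family identity;
#'   family ancestors are diverged to about 90 percent of this bound.
#' @param n_domain_len,c_domain_len,linker_len domain-pair architecture in
#'   residues.
#' @param fragment_fraction fraction of members truncated to a contiguous
#'   piece (retaining 60-100 percent of the full length, so some fall below
#'   the 250-residue pipeline filter).
#' @param multidomain_fraction fraction of members carrying two tandem
#'   domain pairs.
#' @param n_orphans number of unrelated random sequences.
#' @param flank_range range of random flanking residues on each terminus.
#' @param motif optional conserved motif (e.g. `"GAGAAG"`) embedded at the
#'   start of every family's C domain to exercise motif scanning.
#' @param rng_seed integer seed; generation is fully deterministic given it.
#' @return a `superfamily_params` list.
#' @export
superfamily_params <- function(n_families = 6, family_sizes = NULL,
                               size_range = c(25, 60),
                               within_identity_target = NULL,
                               within_range = c(0.55, 0.90),
                               between_identity_max = 0.30,
                               n_domain_len = 160, c_domain_len = 180,
                               linker_len = 12,
                               fragment_fraction = 0.10,
                               multidomain_fraction = 0.05,
                               n_orphans = 50, flank_range = c(5, 30),
                               motif = NULL, rng_seed = 1) {
  p <- list(n_families = n_families, family_sizes = family_sizes,
            size_range = size_range,
            within_identity_target = within_identity_target,
            within_range = within_range,
            between_identity_max = between_identity_max,
            n_domain_len = n_domain_len, c_domain_len = c_domain_len,
            linker_len = linker_len, fragment_fraction = fragment_fraction,
            multidomain_fraction = multidomain_fraction,
            n_orphans = n_orphans, flank_range = flank_range, motif = motif,
            rng_seed = rng_seed)
  wt <- if (is.null(p$within_identity_target)) p$within_range else p$within_identity_target
  if (p$between_identity_max <= 0 || min(wt) <= p$between_identity_max) {
    stop("infeasible identity constraints: need 0 < between_identity_max < min(within_identity_target)",
         call. = FALSE)
  }
  if (p$fragment_fraction < 0 || p$fragment_fraction > 1 ||
      p$multidomain_fraction < 0 || p$multidomain_fraction > 1) {
    stop("fractions must lie in [0,1]", call. = FALSE)
  }
  structure(p, class = "superfamily_params")
}

# expected pairwise identity between two sequences that independently retain
# a fraction q of a common ancestor (random replacement over 20 residues):
#   id(q) = q^2 + (1 - q^2) / 20   =>   q = sqrt((id - 1/20) / (1 - 1/20))
retention_for_identity <- function(id) sqrt((id - 0.05) / 0.95)

random_protein <- function(n) {
  paste(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  ch[hit] <- sample(AA_ALPHABET20, sum(hit), replace = TRUE)
  paste(ch, collapse = "")
}

KINGDOM_ARCHETYPES <- list(
  bacterial = c(Bacteria = 1),
  eukaryotic = c(Eukaryota = 1),
  mixed = c(Bacteria = 0.6, Eukaryota = 0.4),
  all_kingdoms = c(Bacteria = 0.55, Eukaryota = 0.35, Archaea = 0.10),
  arch_bact = c(Bacteria = 0.85, Archaea = 0.15))
ARCHETYPE_PROBS <- c(bacterial = 0.50, eukaryotic = 0.15, mixed = 0.20,
                     all_kingdoms = 0.10, arch_bact = 0.05)

#' Generate a synthetic two-domain protein superfamily with planted truth
#'
#' Each family descends from its own ancestor (two domain blocks joined by
#' a linker), itself derived from a shared superfamily root so that
#' between-family identity sits near (below) the configured cap. Members
#' are substitution-mutated copies of the family ancestor calibrated to hit
#' the within-family identity target, with random terminal flanks; a
#' fraction are truncated to fragments, a fraction carry two tandem domain
#' pairs, and unrelated random orphans are appended. Kingdom labels are
#' drawn from per-family archetypes (mostly bacterial, some eukaryotic or
#' mixed, occasionally all kingdoms).
#'
#' @param params a [superfamily_params()].
#' @return list with `db` (a [seq_db()]), `truth` (data.frame: one row per
#'   planted domain-pair region with `id`, `family`, `pair_index`, `start`,
#'   `end`, `fragment`, `multidomain`, `kingdom`; orphans have family
#'   `"orphan"`), `ancestors` (per-family ancestor records), and
#'   `domain_msas` (gapless [msa()]s of the ancestral N and C domain blocks,
#'   usable as extraction query alignments).
#' @export
generate_superfamily <- function(params = superfamily_params()) {
  stopifnot(inherits(params, "superfamily_params"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(params$rng_seed)

  nf <- params$n_families
  sizes <- params$family_sizes
  if (is.null(sizes)) {
    sizes <- sample(seq(params$size_range[1], params$size_range[2]), nf,
                    replace = TRUE)
  }
  within <- params$within_identity_target
  if (is.null(within)) {
    within <- stats::runif(nf, params$within_range[1], params$within_range[2])
  }
  within <- rep_len(within, nf)

  nl <- params$n_domain_len; cl <- params$c_domain_len; ll <- params$linker_len
  root_n <- random_protein(nl)
  root_c <- random_protein(cl)
  if (!is.null(params$motif)) {
    substr(root_c, 1, nchar(params$motif)) <- toupper(params$motif)
  }
  # family ancestors: diverge from the root to ~90% of the between cap
  p_anc <- retention_for_identity(0.9 * params$between_identity_max)
  anc_rate <- 1 - p_anc
  fam_ids <- sprintf("FAM%02d", seq_len(nf))
  anc_n <- vapply(seq_len(nf), function(f) mutate_seq(root_n, anc_rate), character(1))
  anc_c <- vapply(seq_len(nf), function(f) {
    s <- mutate_seq(root_c, anc_rate)
    if (!is.null(params$motif)) substr(s, 1, nchar(params$motif)) <- toupper(params$motif)
    s
  }, character(1))
  anc_link <- vapply(seq_len(nf), function(f) random_protein(ll), character(1))

  archetype <- sample(names(KINGDOM_ARCHETYPES), nf, replace = TRUE,
                      prob = ARCHETYPE_PROBS)

  recs <- list(); truth <- list()
  for (f in seq_len(nf)) {
    # per-member retention of the ancestor chosen so member-member identity
    # hits the within target
    q <- retention_for_identity(within[f])
    mut_rate <- 1 - q
    mix <- KINGDOM_ARCHETYPES[[archetype[f]]]
    kdm <- sample(names(mix), sizes[f], replace = TRUE, prob = mix)
    n_frag <- round(params$fragment_fraction * sizes[f])
    n_multi <- round(params$multidomain_fraction * sizes[f])
    kind <- rep("intact", sizes[f])
    if (n_frag > 0) kind[seq_len(n_frag)] <- "fragment"
    if (n_multi > 0) kind[n_frag + seq_len(n_multi)] <- "multidomain"
    ancestor_pair <- paste0(anc_n[f], anc_link[f], anc_c[f])
    for (mi in seq_len(sizes[f])) {
      id <- sprintf("%s_%03d", fam_ids[f], mi)
      pair1 <- mutate_seq(ancestor_pair, mut_rate)
      if (!is.null(params$motif)) {
        substr(pair1, nl + ll + 1, nl + ll + nchar(params$motif)) <- toupper(params$motif)
      }
      fl <- params$flank_range
      lead <- random_protein(sample(seq(fl[1], fl[2]), 1))
      trail <- random_protein(sample(seq(fl[1], fl[2]), 1))
      if (kind[mi] == "multidomain") {
        pair2 <- mutate_seq(ancestor_pair, mut_rate)
        spacer <- random_protein(10)
        seqs <- paste0(lead, pair1, spacer, pair2, trail)
        st1 <- nchar(lead) + 1
        en1 <- st1 + nchar(pair1) - 1
        st2 <- en1 + 11
        en2 <- st2 + nchar(pair2) - 1
        recs[[id]] <- c(id = id, res = seqs, kingdom = kdm[mi])
        truth[[length(truth) + 1]] <- data.frame(
          id = id, family = fam_ids[f], pair_index = 1:2,
          start = c(st1, st2), end = c(en1, en2),
          fragment = FALSE, multidomain = TRUE, kingdom = kdm[mi],
          stringsAsFactors = FALSE)
      } else {
        full <- paste0(lead, pair1, trail)
        st <- nchar(lead) + 1
        en <- st + nchar(pair1) - 1
        if (kind[mi] == "fragment") {
          keep_frac <- stats::runif(1, 0.60, 1.00)
          keep_len <- max(30L, round(keep_frac * nchar(full)))
          from_n <- stats::runif(1) < 0.5
          if (from_n) {
            full <- substr(full, 1, keep_len)
          } else {
            off <- nchar(full) - keep_len
            full <- substr(full, off + 1, nchar(full))
            st <- max(1L, st - off); en <- max(1L, en - off)
          }
          en <- min(en, nchar(full))
        }
        recs[[id]] <- c(id = id, res = full, kingdom = kdm[mi])
        truth[[length(truth) + 1]] <- data.frame(
          id = id, family = fam_ids[f], pair_index = 1L,
          start = st, end = en,
          fragment = kind[mi] == "fragment", multidomain = FALSE,
          kingdom = kdm[mi], stringsAsFactors = FALSE)
      }
    }
  }
  for (k in seq_len(params$n_orphans)) {
    id <- sprintf("ORPH%03d", k)
    len <- sample(250:500, 1)
    recs[[id]] <- c(id = id, res = random_protein(len), kingdom = "Unclassified")
    truth[[length(truth) + 1]] <- data.frame(
      id = id, family = "orphan", pair_index = 1L, start = NA_integer_,
      end = NA_integer_, fragment = FALSE, multidomain = FALSE,
      kingdom = "Unclassified", stringsAsFactors = FALSE)
  }
  rc <- do.call(rbind, recs)
  db <- seq_db(id = rc[, "id"], residues = rc[, "res"],
               review_tier = "synthetic", kingdom = rc[, "kingdom"])
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(db = db,
       truth = truth,
       ancestors = data.frame(family = fam_ids, n_domain = anc_n,
                              linker = anc_link, c_domain = anc_c,
                              within_identity = within,
                              archetype = archetype, size = sizes,
                              stringsAsFactors = FALSE),
       domain_msas = list(n = msa(fam_ids, anc_n), c = msa(fam_ids, anc_c)))
}

#' Score recovered families against the planted truth
#'
#' Each planted family is matched to the recovered seed set with the
#' largest membership overlap; precision and recall are computed per family
#' on sequence ids and aggregated weighted by planted family size.
#'
#' @param families list of recovered [seed_set()]s.
#' @param truth planted truth table from [generate_superfamily()].
#' @return list with `per_family` (data.frame: family, matched set,
#'   precision, recall, exact) and weighted `precision` and `recall`.
#' @export
evaluate_against_truth <- function(families, truth) {
  planted <- setdiff(unique(truth$family), "orphan")
  rec_ids <- lapply(families, family_member_ids)
  names(rec_ids) <- vapply(families, function(s) s$family_id, character(1))
  rows <- lapply(planted, function(fam) {
    members <- unique(truth$id[truth$family == fam])
    ov <- vapply(rec_ids, function(r) length(intersect(r, members)), numeric(1))
    if (length(ov) == 0 || max(ov) == 0) {
      return(data.frame(family = fam, matched = NA_character_, size = length(members),
                        precision = 0, recall = 0, exact = FALSE,
                        stringsAsFactors = FALSE))
    }
    best <- names(rec_ids)[which.max(ov)]
    r <- rec_ids[[best]]
    inter <- length(intersect(r, members))
    data.frame(family = fam, matched = best, size = length(members),
               precision = inter / length(r), recall = inter / length(members),
               exact = setequal(r, members), stringsAsFactors = FALSE)
  })
  per_family <- do.call(rbind, rows)
  w <- per_family$size / sum(per_family$size)
  list(per_family = per_family,
       precision = sum(w * per_family$precision),
       recall = sum(w * per_family$recall))
}
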