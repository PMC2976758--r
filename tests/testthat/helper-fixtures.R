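# Constructed fixtures shared across tests.

# A small single-domain family: mutated copies of a common core.
make_family_db <- function(n = 10, len = 60, rate = 0.12, prefix = "s",
                           rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  core <- random_seq(len)
  seqs <- vapply(seq_len(n), function(i) famforge:::mutate_seq(core, rate),
                 character(1))
  seq_db(paste0(prefix, seq_len(n)), seqs)
}

seed_from_db <- function(db, family_id = "fam") {
  seed_set(family_id,
           data.frame(sequence_id = db$id, start = 1L,
                      end = nchar(db$residues), score = NA_real_,
                      stringsAsFactors = FALSE),
           star_align(db))
}

# "Bridge" database: two families joined by a ladder of chimeric
# intermediates (nested mixtures along a fixed position permutation), so
# refinement started from family A cascades across the bridge into family B
# and blows past a small divergence cap. Three deliberately distant family-A
# members anchor the inclusion threshold low enough for the first rung.
make_bridge_fixture <- function(rng_seed = 5) {
  set.seed(rng_seed)
  mut <- famforge:::mutate_seq
  ancA <- random_seq(300); ancB <- random_seq(300)
  perm <- sample(300)
  mix <- function(t) {
    a <- strsplit(ancA, "")[[1]]; b <- strsplit(ancB, "")[[1]]
    sel <- perm[seq_len(round(300 * t))]
    a[sel] <- b[sel]
    paste(a, collapse = "")
  }
  strong <- vapply(1:22, function(i) mut(ancA, 0.12), character(1))
  weak <- vapply(1:3, function(i) mut(ancA, 0.30), character(1))
  famB <- vapply(1:25, function(i) mut(ancB, 0.12), character(1))
  ts <- rep(seq(0.10, 0.90, by = 0.08), each = 8)
  inter <- vapply(ts, function(t) mut(mix(t), 0.02), character(1))
  db <- seq_db(c(paste0("A", 1:25), paste0("I", seq_along(inter)),
                 paste0("B", 1:25)),
               c(strong, weak, inter, famB), review_tier = "synthetic")
  list(db = db, seed0 = seed_from_db(db[1:25, ], "bridge"))
}

# One alien-injection trial: two planted families; family A's seed receives
# one family-B member. Returns the injected seed set, the clean seed set and
# the database.
make_alien_trial <- function(rng_seed) {
  g <- generate_superfamily(superfamily_params(
    n_families = 2, family_sizes = c(12, 12), within_identity_target = 0.70,
    n_orphans = 10, fragment_fraction = 0, multidomain_fraction = 0,
    rng_seed = rng_seed))
  truth <- g$truth
  reg <- function(fam) truth[truth$family == fam, , drop = FALSE]
  mk_members <- function(tr) data.frame(sequence_id = tr$id, start = tr$start,
                                        end = tr$end, score = NA_real_,
                                        stringsAsFactors = FALSE)
  ra <- reg("FAM01"); rb <- reg("FAM02")
  recs <- function(tr) seq_db(tr$id, substr(g$db$residues[match(tr$id, g$db$id)],
                                            tr$start, tr$end))
  clean <- seed_set("clean", mk_members(ra), star_align(recs(ra)))
  alien_row <- rb[sample(nrow(rb), 1), , drop = FALSE]
  inj_tr <- rbind(ra, alien_row)
  injected <- seed_set("injected", mk_members(inj_tr), star_align(recs(inj_tr)))
  list(db = g$db, clean = clean, injected = injected,
       alien_id = alien_row$id)
}

overlap_report_for <- function(fa, fb, kind = "subset") {
  famforge:::overlap_report(
    fa$family_id, fb$family_id,
    intersect(unique(fa$members$sequence_id), unique(fb$members$sequence_id)),
    kind)
}

brute_overlap_kind <- function(fa, fb) {
  ia <- unique(fa$members$sequence_id)
  ib <- unique(fb$members$sequence_id)
  sh <- intersect(ia, ib)
  if (length(sh) == 0) return(NULL)
  if (all(ia %in% ib) || all(ib %in% ia)) "subset" else "partial"
}
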