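#' Pipeline configuration
#'
#' All thresholds of the subdivision pipeline in one flat list. Defaults
#' follow the study design: 40 percent clustering identity, clusters of
#' more than 20 sequences, 250-residue pre-clustering length filter,
#' 270-residue characterization filter, 3000-sequence divergence cap,
#' 90 percent redundancy reduction, 95 percent conservation threshold and
#' a 0.1-bit noise-cutoff offset.
#'
#' @param cluster_identity greedy clustering identity threshold.
#' @param min_cluster_size minimum seed cluster size (more than 20 = 21).
#' @param min_region_len pre-clustering region length filter.
#' @param char_min_len characterization length filter.
#' @param divergence_cap refinement divergence cap.
#' @param redundancy_threshold characterization redundancy reduction.
#' @param cscore_threshold conservation threshold in percent.
#' @param nc_offset noise cutoff offset in bits.
#' @param strategy inclusion control strategy (`"I"`, `"II"`, `"III"`).
#' @param max_passes inclusion-control reiteration limit.
#' @param extract_threshold query-model bit threshold during extraction.
#' @param max_linker,expand_linker,expand_margin extraction pairing rules.
#' @param max_domains per-sequence domain cap.
#' @param max_iter refinement iteration safety valve.
#' @param removal_fraction curation removal fraction per round.
#' @param min_reliable reliability floor on non-spurious membership.
#' @param nonseed_margin non-seed comparison search margin in bits.
#' @param overlap_margin partial-low separability margin in bits.
#' @param engine an [engine_config()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cluster_identity = 0.40, min_cluster_size = 21,
                            min_region_len = 250, char_min_len = 270,
                            divergence_cap = 3000,
                            redundancy_threshold = 0.90,
                            cscore_threshold = 95, nc_offset = 0.1,
                            strategy = "II", max_passes = 6,
                            extract_threshold = 0, max_linker = 40,
                            expand_linker = 12, expand_margin = 15,
                            max_domains = 4L, max_iter = 50,
                            removal_fraction = 0.05, min_reliable = 20,
                            nonseed_margin = 5, overlap_margin = 2,
                            engine = engine_config()) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full superfamily subdivision pipeline
#'
#' extract -> cluster -> align -> refine (with curation on divergence) ->
#' inclusion control loop -> overlap resolution -> cutoff recording ->
#' characterization. Deterministic for fixed inputs and configuration.
#'
#' @param db sequence database ([seq_db()] or FASTA path).
#' @param n_model,c_model query [profile_model()]s for the N- and
#'   C-terminal domains (built, e.g., from curated domain alignments).
#' @param taxonomy optional taxonomy sidecar (data.frame or TSV path);
#'   overrides kingdom labels carried on `db`.
#' @param config a [pipeline_config()].
#' @return a `family_library`: `models` (primary models with GA/TC/NC set),
#'   `seeds` (their seed sets), `shelf` (shelved subfamily models),
#'   `reports` (stability reports), `characterization` (family property
#'   table), `log` (structured stage log) and `provenance`.
#' @export
run_pipeline <- function(db, n_model, c_model, taxonomy = NULL,
                         config = pipeline_config()) {
  if (is.character(db)) db <- read_fasta(db)
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)
  if (!is.null(taxonomy)) {
    idx <- match(db$id, taxonomy$id)
    db$kingdom[!is.na(idx)] <- taxonomy$kingdom[idx[!is.na(idx)]]
    db$species_group[!is.na(idx)] <- taxonomy$species_group[idx[!is.na(idx)]]
  }
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1]] <<- c(list(stage = stage), list(...))
  }
  empty_library <- function() {
    structure(list(models = list(), seeds = list(), shelf = list(),
                   reports = list(), characterization = NULL, log = log,
                   provenance = list(config = config, n_db = nrow(db))),
              class = "family_library")
  }
  if (nrow(db) == 0) {
    note("empty_database")
    return(empty_library())
  }

  # 1. domain-pair extraction
  rules <- pairing_rules(config$max_linker, config$expand_linker,
                         config$expand_margin)
  ext <- extract_regions(db, n_model, c_model, rules,
                         threshold = config$extract_threshold,
                         min_len = config$min_region_len,
                         max_domains = config$max_domains)
  note("extract", n_regions = nrow(ext$regions),
       n_removed_short = attr(ext$regions, "n_removed"))
  if (nrow(ext$records) == 0) {
    note("no_regions")
    return(empty_library())
  }

  # 2. greedy identity clustering + seed cluster selection
  clusters <- greedy_cluster(ext$records, config$cluster_identity)
  seedcl <- select_seed_clusters(clusters, config$min_cluster_size)
  cids <- unique(seedcl$cluster_id)
  note("cluster", n_clusters = length(unique(clusters$cluster_id)),
       n_seed_clusters = length(cids))
  if (length(cids) == 0) return(empty_library())

  # 3-4. star-align each seed cluster, then refine with curation
  results <- list()
  for (ci in seq_along(cids)) {
    rows <- seedcl[seedcl$cluster_id == cids[ci], ]
    rec <- ext$records[match(rows$member, ext$records$id), , drop = FALSE]
    m0 <- star_align(rec, representative = rows$representative[1])
    reg <- ext$regions[match(rows$member, ext$records$id), , drop = FALSE]
    fid <- sprintf("C%03d", ci)
    seed0 <- seed_set(fid, data.frame(sequence_id = reg$sequence_id,
                                      start = reg$start, end = reg$end,
                                      score = NA_real_, stringsAsFactors = FALSE),
                      m0)
    res <- refine_with_curation(seed0, db, cap = config$divergence_cap,
                                max_iter = config$max_iter,
                                config = config$engine,
                                max_domains = config$max_domains,
                                removal_fraction = config$removal_fraction,
                                min_seed = config$min_cluster_size)
    note("refine", family = fid, status = res$status,
         iterations = res$iterations, sizes = res$seed_history_sizes)
    if (res$status == "converged") {
      results[[fid]] <- res$final_seed
    }
  }
  if (length(results) == 0) return(empty_library())

  # 5. inclusion control with re-injection
  ic <- run_inclusion_control(results, db, strategy = config$strategy,
                              config = config$engine,
                              max_passes = config$max_passes,
                              cap = config$divergence_cap,
                              max_iter = config$max_iter,
                              min_reliable = config$min_reliable)
  note("inclusion_control", passes = ic$passes,
       n_spurious = sum(vapply(ic$reports, function(r) length(r$spurious_ids),
                               numeric(1))))

  # 6. overlap resolution
  ov <- resolve_overlaps(ic$families, db, config = config$engine,
                         margin = config$overlap_margin,
                         cap = config$divergence_cap)
  note("overlaps", n_actions = length(ov$log),
       n_shelved = length(ov$shelf))
  families <- ov$families

  # 7. final naming (by decreasing size), models and cutoffs
  sizes <- vapply(families, function(s) nrow(s$members), numeric(1))
  families <- families[order(-sizes, names(families))]
  reliable <- ic$reliable[match(vapply(families, function(s) s$family_id,
                                       character(1)),
                                vapply(ic$families, function(s) s$family_id,
                                       character(1)))]
  reliable[is.na(reliable)] <- TRUE
  models <- list()
  seeds <- list()
  for (k in seq_along(families)) {
    fam <- families[[k]]
    base <- sprintf("F%03d", k)
    nm <- if (reliable[k]) base else paste0(base, "x")
    desc <- if (reliable[k]) "" else
      "WARNING: fewer than 20 non-spurious seed sequences; potentially less reliable"
    fam$family_id <- nm
    model <- build_profile(fam$msa, config$engine, name = nm,
                           description = desc)
    model$reliable <- reliable[k]
    model <- record_cutoffs(model, fam, db, nc_offset = config$nc_offset)
    models[[nm]] <- model
    seeds[[nm]] <- fam
  }
  shelf <- lapply(ov$shelf, function(e) {
    e$model <- build_profile(e$seed$msa, config$engine,
                             name = paste0(e$seed$family_id, "_sub"))
    e$model <- record_cutoffs(e$model, e$seed, db,
                              nc_offset = config$nc_offset)
    e
  })

  # 8. characterization
  char <- do.call(rbind, lapply(names(seeds), function(nm) {
    fam <- seeds[[nm]]
    rec <- seed_records(fam, db)
    fs <- family_summary(rec, family_id = nm, name = nm, max_pairs = 100)
    bnd <- domain_boundary_column(models[[nm]], n_model)
    cs <- cscore_profile(fam$msa)
    dc <- tryCatch(domain_conservation_counts(fam$msa, bnd,
                                              config$cscore_threshold),
                   error = function(e) list(catalytic_count = NA,
                                            coenzyme_count = NA, ratio = NA))
    fs$conserved_catalytic <- dc$catalytic_count
    fs$conserved_coenzyme <- dc$coenzyme_count
    fs$conservation_ratio <- dc$ratio
    fs$conserved_net_charge <- conserved_net_charge(fam$msa,
                                                    config$cscore_threshold)
    fs$average_net_charge <- average_net_charge(fam$msa)
    fs
  }))
  note("characterize", n_families = length(seeds))

  structure(list(models = models, seeds = seeds, shelf = shelf,
                 reports = ic$reports, characterization = char, log = log,
                 provenance = list(config = config, n_db = nrow(db),
                                   passes = ic$passes)),
            class = "family_library")
}

# map the N-domain query model onto the family MSA to find the catalytic /
# coenzyme boundary: the end of the N model's envelope on the family
# consensus, translated to an alignment column
domain_boundary_column <- function(family_model, n_model) {
  cons <- consensus_sequence(family_model)
  v <- viterbi_glocal(n_model, cons)
  endpos <- max(1, v$env[2])
  # consensus position k corresponds to the k-th match column of the family
  # model; in the family seed MSA (aligned to that model) the boundary is
  # the column index of that match state
  endpos
}

consensus_sequence <- function(model) {
  paste(AA_ALPHABET20[apply(model$match_bits, 1, which.max)], collapse = "")
}

#' @export
print.family_library <- function(x, ...) {
  cat(sprintf("family_library: %d primary model(s), %d shelved subfamily model(s)\n",
              length(x$models), length(x$shelf)))
  for (nm in names(x$models)) {
    cat(sprintf("  %s: %d seeds, GA %.1f\n", nm,
                nrow(x$seeds[[nm]]$members), x$models[[nm]]$ga))
  }
  invisible(x)
}

#' Classify sequences against a family library
#'
#' Scores every sequence against every model in the library; a sequence is
#' assigned to each model whose gathering cutoff its best domain score
#' meets, the best-scoring assignment is marked primary, and hits to
#' unreliable (`x`-postfixed) models are flagged. Sequences meeting no
#' cutoff are reported unclassified.
#'
#' @param seqs a [seq_db()] of query sequences.
#' @param library a `family_library` from [run_pipeline()].
#' @param include_shelf also score against shelved subfamily models and
#'   annotate subfamily hits.
#' @return data.frame with one row per (sequence, assigned model), plus one
#'   `unclassified` row for sequences matching nothing: `sequence_id`,
#'   `model`, `score`, `ga`, `primary`, `reliable`, `subfamily`.
#' @export
scan_sequences <- function(seqs, library, include_shelf = TRUE) {
  stopifnot(length(library$models) > 0)
  out <- list()
  for (k in seq_len(nrow(seqs))) {
    s <- seqs$residues[k]
    rows <- list()
    for (nm in names(library$models)) {
      m <- library$models[[nm]]
      h <- best_domains(m, s, max_domains = 1L)
      sc <- if (nrow(h) > 0) h$score[1] else -Inf
      if (is.finite(sc) && sc >= m$ga) {
        rows[[length(rows) + 1]] <- data.frame(
          sequence_id = seqs$id[k], model = nm, score = sc, ga = m$ga,
          primary = FALSE, reliable = m$reliable, subfamily = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    if (include_shelf) {
      for (e in library$shelf) {
        m <- e$model
        h <- best_domains(m, s, max_domains = 1L)
        sc <- if (nrow(h) > 0) h$score[1] else -Inf
        if (is.finite(sc) && sc >= m$ga) {
          rows[[length(rows) + 1]] <- data.frame(
            sequence_id = seqs$id[k], model = m$name, score = sc, ga = m$ga,
            primary = FALSE, reliable = TRUE, subfamily = TRUE,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows) == 0) {
      out[[k]] <- data.frame(sequence_id = seqs$id[k], model = "unclassified",
                             score = NA_real_, ga = NA_real_, primary = NA,
                             reliable = NA, subfamily = NA,
                             stringsAsFactors = FALSE)
    } else {
      df <- do.call(rbind, rows)
      prim <- df[!df$subfamily, , drop = FALSE]
      if (nrow(prim) > 0) {
        df$primary[!df$subfamily][which.max(prim$score)] <- TRUE
      } else {
        df$primary[which.max(df$score)] <- TRUE
      }
      out[[k]] <- df[order(-xtfrm(df$primary), -df$score), , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Strategy comparison summary
#'
#' Summarises one pipeline run in the layout of the study's strategy
#' comparison table: number of families (unreliable in parentheses), total
#' seed sequences, inclusion-control reiterations, and shelved subsets.
#'
#' @param library a `family_library`.
#' @return one-row data.frame: `strategy`, `families`, `unreliable`,
#'   `sequences`, `reiterations`, `subsets`.
#' @export
strategy_summary <- function(library) {
  data.frame(
    strategy = library$provenance$config$strategy,
    families = length(library$models),
    unreliable = sum(!vapply(library$models, function(m) m$reliable, logical(1))),
    sequences = sum(vapply(library$seeds, function(s) nrow(s$members), numeric(1))),
    reiterations = library$provenance$passes,
    subsets = length(library$shelf),
    stringsAsFactors = FALSE)
}
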