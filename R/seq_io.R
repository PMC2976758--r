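#' @useDynLib famforge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
MODEL_FORMAT_MAGIC <- "FAMFORGE-HMM"
MODEL_FORMAT_VERSION <- "1.0"

#' Normalize a raw residue string
#'
#' Uppercases, strips gap/terminator characters (`-`, `.`, `*`, whitespace)
#' and maps ambiguity codes (B, Z, J, U, O) to `X`.
#'
#' @param x character vector of residue strings.
#' @return normalized character vector.
#' @keywords internal
normalize_residues <- function(x) {
  x <- toupper(x)
  x <- gsub("[-.* \t]", "", x)
  chartr("BZJUO", "XXXXX", x)
}

validate_residues <- function(x, ids) {
  bad <- grepl(sprintf("[^%sX]", paste(AA_ALPHABET20, collapse = "")), x)
  if (any(bad)) {
    stop(sprintf("illegal residue character(s) in record(s): %s",
                 paste(ids[bad], collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a sequence database
#'
#' A sequence database is a plain `data.frame` with one row per protein:
#' `id`, `description`, `residues`, `review_tier` (reviewed / unreviewed /
#' synthetic), `kingdom` (Archaea / Bacteria / Eukaryota / Unclassified) and
#' `species_group` (optional, `NA` when unknown).
#'
#' @param id unique sequence identifiers.
#' @param residues amino-acid strings (normalized on construction).
#' @param description free-text descriptions.
#' @param review_tier review status per sequence.
#' @param kingdom taxonomic kingdom per sequence.
#' @param species_group optional finer species group labels.
#' @return a `data.frame` of class `seq_db`.
#' @export
seq_db <- function(id, residues, description = "",
                   review_tier = "unreviewed", kingdom = "Unclassified",
                   species_group = NA_character_) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("sequence ids must be unique within a database", call. = FALSE)
  }
  residues <- normalize_residues(as.character(residues))
  if (any(!nzchar(residues))) {
    stop(sprintf("empty residues for record(s): %s",
                 paste(id[!nzchar(residues)], collapse = ", ")), call. = FALSE)
  }
  validate_residues(residues, id)
  db <- data.frame(id = id, description = rep_len(as.character(description), length(id)),
                   residues = residues,
                   review_tier = rep_len(as.character(review_tier), length(id)),
                   kingdom = rep_len(as.character(kingdom), length(id)),
                   species_group = rep_len(as.character(species_group), length(id)),
                   stringsAsFactors = FALSE)
  class(db) <- c("seq_db", "data.frame")
  db
}

#' Read protein sequences from a FASTA file
#'
#' @param path path to a FASTA file.
#' @return a [seq_db()] data frame, one row per entry, in file order.
#'   Residues are uppercased with gap and `*` characters stripped.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(seq_db(character(0), character(0)))
  }
  hdr <- grepl("^>", lines)
  if (!hdr[1]) {
    stop(sprintf("malformed FASTA header at line 1: expected '>' , got '%s'",
                 substr(lines[1], 1, 40)), call. = FALSE)
  }
  grp <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  bad <- !nzchar(trimws(headers))
  if (any(bad)) {
    stop(sprintf("malformed header: empty identifier at line %d",
                 which(hdr)[which(bad)[1]]), call. = FALSE)
  }
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  # entries with no sequence lines yield empty residues -> caught by seq_db
  out <- rep("", length(ids))
  out[as.integer(names(seqs))] <- seqs
  seq_db(ids, out, description = desc)
}

#' Write sequences to FASTA
#'
#' @param db a [seq_db()] data frame (or anything with `id`/`residues`).
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(db, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(db))) {
    hdr <- if (nzchar(db$description[k])) paste(db$id[k], db$description[k]) else db$id[k]
    writeLines(paste0(">", hdr), con)
    s <- db$residues[k]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a multiple sequence alignment object
#'
#' @param ids row identifiers.
#' @param aln aligned strings (equal length, `-` for gaps; lowercase marks
#'   insert columns where produced by [align_to_model()]).
#' @return an object of class `msa` with elements `ids`, `aln`, `ncol`.
#' @export
msa <- function(ids, aln) {
  ids <- as.character(ids)
  aln <- as.character(aln)
  stopifnot(length(ids) == length(aln))
  w <- nchar(aln)
  if (length(aln) > 0 && length(unique(w)) != 1) {
    ragged <- ids[w != stats::median(w)]
    stop(sprintf("ragged alignment rows (unequal widths): %s",
                 paste(ragged, collapse = ", ")), call. = FALSE)
  }
  structure(list(ids = ids, aln = aln, ncol = if (length(aln)) w[1] else 0L),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d rows x %d columns\n", length(x$ids), x$ncol))
  invisible(x)
}

msa_matrix <- function(m) {
  if (length(m$aln) == 0) return(matrix(character(0), 0, 0))
  do.call(rbind, strsplit(m$aln, ""))
}

#' Remove gaps from alignment rows
#'
#' @param m an [msa()] object.
#' @return character vector of ungapped, uppercased residue strings.
#' @export
degap <- function(m) {
  toupper(gsub("[-.]", "", m$aln))
}

#' Read a multiple sequence alignment
#'
#' @param path input file.
#' @param dialect `"aligned-fasta"` or `"stockholm"`.
#' @return an [msa()] object.
#' @export
read_msa <- function(path, dialect = c("aligned-fasta", "stockholm")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (dialect == "aligned-fasta") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(msa(character(0), character(0)))
    hdr <- grepl("^>", lines)
    if (!hdr[1]) stop("malformed FASTA header at line 1", call. = FALSE)
    grp <- cumsum(hdr)
    ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    aln <- vapply(split(lines[!hdr], grp[!hdr]),
                  function(x) paste(x, collapse = ""), character(1))
    out <- rep("", length(ids))
    out[as.integer(names(aln))] <- aln
    msa(ids, gsub("\\.", "-", out))
  } else {
    read_stockholm(path)
  }
}

# Minimal Stockholm 1.0 reader: sequence lines only, '#' annotations skipped,
# multi-block alignments concatenated, terminated by '//'.
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seqs <- list()
  order <- character(0)
  for (ln in lines) {
    if (grepl("^//", ln)) break
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) {
      stop(sprintf("malformed Stockholm sequence line: '%s'", ln), call. = FALSE)
    }
    id <- parts[1]
    if (!id %in% order) order <- c(order, id)
    seqs[[id]] <- paste0(if (is.null(seqs[[id]])) "" else seqs[[id]], parts[2])
  }
  if (length(order) == 0) return(msa(character(0), character(0)))
  msa(order, gsub("\\.", "-", toupper(unlist(seqs[order]))))
}

#' Write a multiple sequence alignment
#'
#' @param m an [msa()] object.
#' @param path output path.
#' @param dialect `"aligned-fasta"` or `"stockholm"`.
#' @export
write_msa <- function(m, path, dialect = c("aligned-fasta", "stockholm")) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "aligned-fasta") {
    for (k in seq_along(m$ids)) {
      writeLines(c(paste0(">", m$ids[k]), m$aln[k]), con)
    }
  } else {
    writeLines("# STOCKHOLM 1.0", con)
    wid <- max(nchar(m$ids), 0) + 2
    for (k in seq_along(m$ids)) {
      writeLines(sprintf("%-*s%s", wid, m$ids[k], m$aln[k]), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

num_fmt <- function(x) sprintf("%.17g", x)

#' Serialize a profile model to the package's ASCII model format
#'
#' The format is a versioned, line-oriented ASCII layout (HMMER2-like in
#' spirit): header fields (`NAME`, `DESC`, `LENG`, cutoffs, reliability),
#' background frequencies, begin transitions, then one `MATCH` (20 log-odds
#' bit scores) and one `TRANS` (7 transition log2-probabilities) line per
#' match state, terminated by `//`. Numeric fields round-trip bit-exactly.
#'
#' @param model a [profile_model()].
#' @param path output path.
#' @export
serialize_model <- function(model, path) {
  stopifnot(inherits(model, "profile_model"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w(MODEL_FORMAT_MAGIC, " ", MODEL_FORMAT_VERSION)
  w("NAME  ", model$name)
  w("DESC  ", model$description)
  w("LENG  ", model$L)
  w("ALPH  ", paste(AA_ALPHABET20, collapse = ""))
  w("GA    ", num_fmt(model$ga))
  w("TC    ", num_fmt(model$tc))
  w("NC    ", num_fmt(model$nc))
  w("RELIABLE ", if (isTRUE(model$reliable)) "yes" else "no")
  w("BG    ", paste(num_fmt(model$background), collapse = " "))
  w("BEGIN ", num_fmt(model$tBM), " ", num_fmt(model$tBD))
  for (j in seq_len(model$L)) {
    w("MATCH ", j, " ", paste(num_fmt(model$match_bits[j, ]), collapse = " "))
    w("TRANS ", j, " ", paste(num_fmt(c(model$tMM[j], model$tMI[j], model$tMD[j],
                                        model$tIM[j], model$tII[j],
                                        model$tDM[j], model$tDD[j])),
                              collapse = " "))
  }
  w("//")
  invisible(path)
}

#' Read a profile model from the package's ASCII model format
#'
#' @param path path to a serialized model.
#' @return a [profile_model()].
#' @export
deserialize_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("truncated model file: empty", call. = FALSE)
  head1 <- strsplit(lines[1], "\\s+")[[1]]
  if (length(head1) < 2 || head1[1] != MODEL_FORMAT_MAGIC) {
    stop("not a famforge model file (bad magic line)", call. = FALSE)
  }
  if (head1[2] != MODEL_FORMAT_VERSION) {
    stop(sprintf("unsupported model file version: %s (expected %s)",
                 head1[2], MODEL_FORMAT_VERSION), call. = FALSE)
  }
  if (!any(grepl("^//", lines))) {
    stop("truncated model file: missing '//' terminator", call. = FALSE)
  }
  field <- function(key) {
    ln <- lines[grepl(paste0("^", key, "\\s"), lines)]
    if (length(ln) == 0) stop(sprintf("model file missing field %s", key), call. = FALSE)
    sub(paste0("^", key, "\\s+"), "", ln[1])
  }
  L <- as.integer(field("LENG"))
  nums <- function(x) as.numeric(strsplit(trimws(x), "\\s+")[[1]])
  beg <- nums(field("BEGIN"))
  match_lines <- lines[grepl("^MATCH ", lines)]
  trans_lines <- lines[grepl("^TRANS ", lines)]
  if (length(match_lines) != L || length(trans_lines) != L) {
    stop("truncated model file: wrong number of MATCH/TRANS lines", call. = FALSE)
  }
  mb <- t(vapply(match_lines, function(x) nums(sub("^MATCH\\s+\\d+\\s+", "", x)),
                 numeric(20)))
  tr <- t(vapply(trans_lines, function(x) nums(sub("^TRANS\\s+\\d+\\s+", "", x)),
                 numeric(7)))
  dimnames(tr) <- NULL
  rownames(mb) <- NULL
  colnames(mb) <- AA_ALPHABET20
  new_profile_model(name = field("NAME"), description = field("DESC"),
                    match_bits = mb, background = nums(field("BG")),
                    tBM = beg[1], tBD = beg[2],
                    tMM = tr[, 1], tMI = tr[, 2], tMD = tr[, 3],
                    tIM = tr[, 4], tII = tr[, 5], tDM = tr[, 6], tDD = tr[, 7],
                    ga = as.numeric(field("GA")), tc = as.numeric(field("TC")),
                    nc = as.numeric(field("NC")),
                    reliable = identical(field("RELIABLE"), "yes"))
}

#' Load a transcription of one of the printed family tables
#'
#' The package ships TSV transcriptions of the three printed summary tables
#' of the study: the family property table (`table1`), the per-kingdom zinc
#' class counts (`table3`) and the domain conservation ratios (`table4`).
#'
#' @param path TSV file.
#' @param schema which table layout to expect.
#' @return a typed `data.frame`; counts validated non-negative, percentages
#'   validated within 0–100.
#' @export
load_family_table <- function(path, schema = c("table1", "table3", "table4")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- switch(schema,
    table1 = c("family_id", "name", "size", "swissprot_count", "pcid_avg",
               "pcid_std", "n_euk", "n_bact", "n_arch"),
    table3 = c("kingdom", "zn0", "zn2"),
    table4 = c("family_id", "name", "catalytic", "coenzyme", "ratio"))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("table schema '%s' missing column(s): %s", schema,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- df[required]
  counts <- intersect(c("size", "swissprot_count", "n_euk", "n_bact", "n_arch",
                        "zn0", "zn2", "catalytic", "coenzyme"), required)
  for (cc in counts) {
    df[[cc]] <- as.integer(df[[cc]])
    if (any(df[[cc]] < 0, na.rm = TRUE)) {
      stop(sprintf("negative count in column %s", cc), call. = FALSE)
    }
  }
  for (pc in intersect(c("pcid_avg", "pcid_std"), required)) {
    df[[pc]] <- as.numeric(df[[pc]])
    if (any(df[[pc]] < 0 | df[[pc]] > 100, na.rm = TRUE)) {
      stop(sprintf("percentage out of [0,100] in column %s", pc), call. = FALSE)
    }
  }
  if (schema == "table1" &&
      any(with(df, n_euk + n_bact + n_arch > size))) {
    stop("kingdom counts exceed family size", call. = FALSE)
  }
  df
}

#' Read a taxonomy sidecar table
#'
#' A tab-separated table mapping sequence ids to kingdom and (optionally)
#' species-group labels, standing in for a live taxonomy database lookup.
#'
#' @param path TSV with columns `id`, `kingdom` and optionally `species_group`.
#' @return data.frame with those columns.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "kingdom") %in% names(df))) {
    stop("taxonomy sidecar needs columns: id, kingdom", call. = FALSE)
  }
  if (!"species_group" %in% names(df)) df$species_group <- NA_character_
  ok <- c("Archaea", "Bacteria", "Eukaryota", "Unclassified")
  bad <- !df$kingdom %in% ok
  if (any(bad)) {
    stop(sprintf("unknown kingdom label(s): %s",
                 paste(unique(df$kingdom[bad]), collapse = ", ")), call. = FALSE)
  }
  df[c("id", "kingdom", "species_group")]
}
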