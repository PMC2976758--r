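# Independent oracles used across the suite.

# Brute-force glocal Viterbi by exhaustive path enumeration.
#
# A legal path chooses a subset of model nodes as match states (the rest are
# deletions), assigns strictly increasing sequence positions to the matches,
# and may emit insertions only between matches at adjacent nodes (the engine
# topology has no delete<->insert transitions). Flanking residues outside
# the first/last emission are free. This enumerates every such path and
# returns the maximum total score in bits.
oracle_viterbi <- function(model, seq) {
  L <- model$L
  s <- famforge:::seq_to_int(seq)
  n <- length(s)
  em <- function(j, r) if (r == 0) 0 else unname(model$match_bits[j, r])
  ddrun <- function(a, b) if (b < a) 0 else sum(model$tDD[a:b])  # D_a..D_{b+1}

  # all-delete path: B -> D1 -> ... -> DL -> E
  best <- model$tBD + ddrun(1, L - 1)

  for (m in seq_len(L)) {
    subsets <- utils::combn(L, m)
    for (ci in seq_len(ncol(subsets))) {
      js <- subsets[, ci]
      # model-side transition costs independent of sequence positions
      entry <- if (js[1] == 1) model$tBM else
        model$tBD + ddrun(1, js[1] - 2) + model$tDM[js[1] - 1]
      exitc <- if (js[m] == L) 0 else
        model$tMD[js[m]] + ddrun(js[m] + 1, L - 1)
      gapcost <- numeric(0)  # cost between match k and k+1 when via deletes
      if (m >= 2) {
        gapcost <- vapply(seq_len(m - 1), function(k) {
          if (js[k + 1] == js[k] + 1) NA_real_ else
            model$tMD[js[k]] + ddrun(js[k] + 1, js[k + 1] - 2) +
              model$tDM[js[k + 1] - 1]
        }, numeric(1))
      }
      # enumerate increasing sequence positions for the m matches
      rec <- function(k, prev_i, acc) {
        if (!is.finite(acc)) return()
        if (k > m) {
          if (acc > best) best <<- acc
          return()
        }
        if (k == 1) {
          for (i in seq_len(n)) rec(2, i, acc + em(js[1], s[i]))
        } else if (is.na(gapcost[k - 1])) {
          # adjacent nodes: direct step or an insert run at I_{js[k-1]}
          jj <- js[k - 1]
          if (prev_i + 1 > n) return()
          for (i in (prev_i + 1):n) {
            gap <- i - prev_i - 1
            tc <- if (gap == 0) model$tMM[jj] else
              model$tMI[jj] +
                (if (gap > 1) (gap - 1) * model$tII[jj] else 0) +
                model$tIM[jj]
            rec(k + 1, i, acc + tc + em(js[k], s[i]))
          }
        } else {
          # nodes separated by deletions: next match consumes the next residue
          i <- prev_i + 1
          if (i <= n) rec(k + 1, i, acc + gapcost[k - 1] + em(js[k], s[i]))
        }
        invisible()
      }
      rec(1, 0, unname(entry + exitc))
    }
  }
  unname(best)
}

# random small profile model with finite transitions, for oracle comparisons
random_small_model <- function(L) {
  logs <- function(k) log2(prop.table(stats::runif(k, 0.05, 1)))
  mb <- matrix(stats::rnorm(L * 20, 0, 2), L, 20,
               dimnames = list(NULL, famforge:::AA_ALPHABET20))
  tM <- t(vapply(seq_len(L), function(j) logs(3), numeric(3)))
  tI <- t(vapply(seq_len(L), function(j) logs(2), numeric(2)))
  tD <- t(vapply(seq_len(L), function(j) logs(2), numeric(2)))
  tB <- logs(2)
  famforge:::new_profile_model(
    name = "rnd", match_bits = mb, background = rep(1 / 20, 20),
    tBM = tB[1], tBD = tB[2],
    tMM = tM[, 1], tMI = tM[, 2], tMD = tM[, 3],
    tIM = tI[, 1], tII = tI[, 2], tDM = tD[, 1], tDD = tD[, 2])
}

random_seq <- function(n) {
  paste(sample(famforge:::AA_ALPHABET20, n, replace = TRUE), collapse = "")
}

# Brute-force global affine-gap alignment (BLOSUM62, open 11 / extend 1)
# implemented directly as a three-state DP, independent of Biostrings.
# Because co-optimal alignments can carry different identity counts, the
# oracle reports the optimal score plus the min and max identity count over
# all score-optimal alignments; the implementation must land inside.
oracle_nw_identity <- function(a, b) {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  sub <- BLOSUM62
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  NEG <- -1e9
  go <- -11; ge <- -1  # open+extend charged on the first gap residue
  # cells are (score, min identities, max identities), positional
  cell <- function(s = NEG, lo = 0, hi = 0) c(s, lo, hi)
  merge2 <- function(...) {
    cs <- list(...)
    smax <- max(vapply(cs, `[`, numeric(1), 1))
    at <- Filter(function(c) c[1] == smax, cs)
    c(smax, min(vapply(at, `[`, numeric(1), 2)),
      max(vapply(at, `[`, numeric(1), 3)))
  }
  add <- function(c, ds, dn = 0) c(c[1] + ds, c[2] + dn, c[3] + dn)
  M <- X <- Y <- array(NEG, c(na + 1, nb + 1, 3))
  M[1, 1, ] <- cell(0)
  for (i in 2:(na + 1)) X[i, 1, ] <- cell(go + ge * (i - 1))
  for (j in 2:(nb + 1)) Y[1, j, ] <- cell(go + ge * (j - 1))
  for (i in 2:(na + 1)) {
    for (j in 2:(nb + 1)) {
      sc <- sub[A[i - 1], B[j - 1]]
      dn <- as.integer(A[i - 1] == B[j - 1])
      M[i, j, ] <- add(merge2(M[i - 1, j - 1, ], X[i - 1, j - 1, ],
                              Y[i - 1, j - 1, ]), sc, dn)
      X[i, j, ] <- merge2(add(M[i - 1, j, ], go + ge), add(X[i - 1, j, ], ge))
      Y[i, j, ] <- merge2(add(M[i, j - 1, ], go + ge), add(Y[i, j - 1, ], ge))
    }
  }
  fin <- merge2(M[na + 1, nb + 1, ], X[na + 1, nb + 1, ], Y[na + 1, nb + 1, ])
  list(score = fin[1], id_min = fin[2] / max(na, nb),
       id_max = fin[3] / max(na, nb))
}
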