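# Independent oracles used across the suite. These re-derive expected values
# by brute force (path enumeration, reachability, direct counting) and stay
# independent of the implementation paths they check.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

# ---- exhaustive path-sum / path-max oracle for the local profile HMM ----
# Architecture: begin uniform over (match state, sequence position); from
# M_i exit with p_end(i) = 1/(n - i + 1), else continue with damped M/I/D
# transitions; I emits background; paths end in a match state. Returns
# log2-odds (forward = sum over paths, viterbi = best path).
brute_force_scores <- function(hmm, seq) {
  n <- hmm$n_match
  x <- strsplit(seq, "")[[1]]
  Tn <- length(x)
  f <- hmm$background
  em_odds <- sweep(hmm$match_emissions, 2, f, "/")
  p_end <- 1 / (n - seq_len(n) + 1)
  tr <- hmm$transitions
  # continue(kind, i, j): list of odds of all completions from state (kind,i)
  # with sequence consumed through position j (the state has just emitted j
  # for M/I). Enumeration, no memoisation: sizes are tiny.
  continue <- function(kind, i, j) {
    out <- numeric(0)
    if (kind == "M") {
      out <- c(out, p_end[i])          # exit here
      cont <- 1 - p_end[i]
      if (i < n) {
        if (j < Tn) {
          a <- match(x[j + 1], AA20)
          out <- c(out, cont * tr$tMM[i] * em_odds[i + 1, a] *
                     continue("M", i + 1, j + 1))
          out <- c(out, cont * tr$tMI[i] * continue("I", i, j + 1))
        }
        out <- c(out, cont * tr$tMD[i] * continue("D", i + 1, j))
      }
    } else if (kind == "I") {
      if (i < n) {
        if (j < Tn) {
          a <- match(x[j + 1], AA20)
          out <- c(out, tr$tIM[i] * em_odds[i + 1, a] *
                     continue("M", i + 1, j + 1))
          out <- c(out, tr$tII[i] * continue("I", i, j + 1))
        }
      }
    } else {                           # D_i
      if (i < n) {
        if (j < Tn) {
          a <- match(x[j + 1], AA20)
          out <- c(out, tr$tDM[i] * em_odds[i + 1, a] *
                     continue("M", i + 1, j + 1))
        }
        if (i + 1 <= n) out <- c(out, tr$tDD[i] * continue("D", i + 1, j))
      }
    }
    if (!length(out)) return(0)
    out
  }
  all_paths <- numeric(0)
  for (j in seq_len(Tn)) {
    for (i in seq_len(n)) {
      a <- match(x[j], AA20)
      entry <- (1 / (n * Tn)) * em_odds[i, a]
      all_paths <- c(all_paths, entry * continue("M", i, j))
    }
  }
  all_paths <- all_paths[all_paths > 0]
  list(forward = log2(sum(all_paths)), viterbi = log2(max(all_paths)))
}

# Random small profile HMM with valid invariants.
random_small_hmm <- function(n_match, seed) {
  withr::with_seed(seed, {
    em <- matrix(rexp(n_match * 20), n_match, 20)
    em <- em / rowSums(em)
    k <- max(0, n_match - 1)
    r3 <- function() {
      m <- matrix(rexp(3 * k), k, 3)
      m / rowSums(m)
    }
    r2 <- function() {
      m <- matrix(rexp(2 * k), k, 2)
      m / rowSums(m)
    }
    m3 <- r3(); mi <- r2(); md <- r2()
    profile_hmm(em, list(tMM = m3[, 1], tMI = m3[, 2], tMD = m3[, 3],
                         tIM = mi[, 1], tII = mi[, 2],
                         tDM = md[, 1], tDD = md[, 2]))
  })
}

# ---- reachability oracle for GO descendants (matrix powers) ----
reachability_descendants <- function(edges, terms, term) {
  n <- length(terms)
  A <- matrix(0, n, n, dimnames = list(terms, terms))
  for (k in seq_len(nrow(edges))) {
    A[edges$parent_id[k], edges$term_id[k]] <- 1   # parent -> child
  }
  R <- A
  P <- A
  for (step in seq_len(n)) {
    P <- (P %*% A) > 0
    R <- R + P
  }
  sort(terms[R[term, ] > 0])
}

# ---- random protein helper ----
random_protein <- function(len, seed) {
  withr::with_seed(seed, paste0(sample(AA20, len, replace = TRUE),
                                collapse = ""))
}

# ---- brute-force PPI filter predicate (single pass) ----
brute_force_ppi <- function(records, annotations, housekeeping, contaminants,
                            min_pubs = 2) {
  repair <- unique(annotations$protein_id[annotations$term_id == "GO:0006281"])
  ddr <- unique(annotations$protein_id[
    annotations$term_id %in% c("GO:0006281", "GO:0006974")])
  keep <- logical(nrow(records))
  cand <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    a <- records$protein_a[i]; b <- records$protein_b[i]
    a_rep <- a %in% repair; b_rep <- b %in% repair
    a_ddr <- a %in% ddr; b_ddr <- b %in% ddr
    ok_ab <- a_rep && !b_ddr
    ok_ba <- b_rep && !a_ddr
    if (!ok_ab && !ok_ba) next
    cd <- if (ok_ab) b else a
    ev <- records$evidence_types[[i]]
    if (!("experimental" %in% ev)) next
    if (records$n_publications_experimental[i] < min_pubs) next
    if (cd %in% c(housekeeping, contaminants)) next
    keep[i] <- TRUE
    cand[i] <- cd
  }
  list(keep = keep, candidates = sort(unique(cand[keep])))
}
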