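test_that("profile construction matches the stated closed forms", {
  # two identical rows: Henikoff weights halve, total weight 1
  h <- hmm_from_msa(gm_msa(c("ACD", "ACD")), alpha = 1)
  expect_identical(h$n_match, 3L)
  f <- background_frequencies()
  expect_equal(unname(h$match_emissions[1, "A"]), (1 + 1 * f[["A"]]) / (1 + 1))
  expect_equal(unname(h$match_emissions[2, "C"]), (1 + 1 * f[["C"]]) / (1 + 1))

  # a column that is 60% gaps at threshold 0.5 is not a match state
  rows <- c("AC", "A-", "A-", "A-", "AC")  # col2: 60% gaps
  h2 <- hmm_from_msa(gm_msa(rows), match_gap_fraction = 0.5)
  expect_identical(h2$n_match, 1L)

  # emission and transition rows normalise on random alignments
  for (s in 1:5) {
    rows <- withr::with_seed(s, vapply(1:20, function(i) {
      r <- strsplit(random_protein(50, s * 31 + i), "")[[1]]
      r[runif(50) < 0.2] <- "-"
      paste0(r, collapse = "")
    }, character(1)))
    h3 <- hmm_from_msa(gm_msa(rows))
    expect_lt(max(abs(rowSums(h3$match_emissions) - 1)), 1e-9)
    tr <- h3$transitions
    expect_lt(max(abs(tr$tMM + tr$tMI + tr$tMD - 1)), 1e-9)
    expect_lt(max(abs(tr$tIM + tr$tII - 1)), 1e-9)
    expect_lt(max(abs(tr$tDM + tr$tDD - 1)), 1e-9)
  }
})

test_that("profile construction ignores row order", {
  rows <- withr::with_seed(8, vapply(1:10, function(i) {
    r <- strsplit(random_protein(30, 800 + i), "")[[1]]
    r[runif(30) < 0.15] <- "-"
    paste0(r, collapse = "")
  }, character(1)))
  rows[1] <- random_protein(30, 99)
  h1 <- hmm_from_msa(gm_msa(rows, ids = sprintf("r%d", 1:10)))
  perm <- c(1L, 7L, 3L, 10L, 5L, 6L, 4L, 8L, 9L, 2L)
  h2 <- hmm_from_msa(gm_msa(rows[perm], ids = sprintf("r%d", perm)))
  expect_equal(h1$match_emissions, h2$match_emissions, tolerance = 1e-12)
  expect_equal(h1$transitions, h2$transitions, tolerance = 1e-12)
})

test_that("single-path model reproduces the closed-form bit score", {
  h <- hmm_from_msa(gm_msa(c("A", "A")), alpha = 0)
  expect_equal(forward_score(h, "A"), log2(1 / 0.05), tolerance = 1e-9)
  v <- viterbi_align(h, "A")
  expect_equal(v$score, log2(1 / 0.05), tolerance = 1e-9)
  expect_identical(v$trace, matrix(c(1L, 1L), 1))
})

test_that("a background-equal profile never scores positive bits", {
  em <- matrix(1 / 20, 4, 20)
  k <- 3
  tr <- list(tMM = rep(0.8, k), tMI = rep(0.1, k), tMD = rep(0.1, k),
             tIM = rep(0.5, k), tII = rep(0.5, k),
             tDM = rep(0.5, k), tDD = rep(0.5, k))
  h <- profile_hmm(em, tr)
  for (s in 1:5) {
    expect_lte(forward_score(h, random_protein(30, s)), 0)
  }
})

test_that("forward and viterbi equal exhaustive path enumeration", {
  # 4-letter alphabet reduction: sequences over {A,C,D,E}, lengths 1..3
  seqs <- unlist(lapply(1:3, function(L) {
    apply(expand.grid(rep(list(c("A", "C", "D", "E")), L)), 1, paste0,
          collapse = "")
  }))
  for (n in 1:3) {
    h <- random_small_hmm(n, seed = 100 + n)
    for (s in seqs) {
      oracle <- brute_force_scores(h, s)
      expect_equal(forward_score(h, s), oracle$forward, tolerance = 1e-6,
                   label = sprintf("forward n=%d seq=%s", n, s))
      expect_equal(viterbi_align(h, s)$score, oracle$viterbi,
                   tolerance = 1e-6,
                   label = sprintf("viterbi n=%d seq=%s", n, s))
    }
  }
  # random 20-letter cases
  withr::with_seed(55, {
    for (rep in 1:25) {
      n <- sample(1:3, 1)
      h <- random_small_hmm(n, seed = 500 + rep)
      s <- random_protein(sample(1:4, 1), 900 + rep)
      oracle <- brute_force_scores(h, s)
      expect_equal(forward_score(h, s), oracle$forward, tolerance = 1e-6)
      expect_equal(viterbi_align(h, s)$score, oracle$viterbi,
                   tolerance = 1e-6)
    }
  })
})

test_that("viterbi never exceeds forward", {
  for (s in 1:10) {
    fam <- simulate_family(family_spec("f", 30, 5, 0.6, seed = s))
    h <- hmm_from_msa(fam$msa)
    seqs <- random_protein(40, s + 1000)
    expect_lte(viterbi_align(h, seqs)$score, forward_score(h, seqs) + 1e-9)
  }
})

test_that("non-canonical residues are scored as background, never an error", {
  h <- hmm_from_msa(gm_msa(c("ACDEF", "ACDEF")))
  expect_message(sc <- forward_score(h, "ACXEF"), "Non-canonical")
  expect_true(is.finite(sc))
  expect_message(v <- viterbi_align(h, "ACBZF"), "Non-canonical")
  expect_true(is.finite(v$score))
})

test_that("scores stay finite for very long sequences", {
  fam <- simulate_family(family_spec("f", 80, 10, 0.5, seed = 2))
  h <- hmm_from_msa(fam$msa)
  long_seq <- random_protein(10000, 77)
  expect_true(is.finite(forward_score(h, long_seq)))
  expect_true(is.finite(viterbi_align(h, long_seq)$score))
})

test_that("profile-profile column scores follow the co-emission closed form", {
  f <- background_frequencies()
  point <- function(a) {
    em <- matrix(1e-12 / 19, 1, 20, dimnames = list(NULL, names(f)))
    em[1, a] <- 1 - 1e-12
    profile_hmm(em, list(tMM = numeric(0), tMI = numeric(0),
                         tMD = numeric(0), tIM = numeric(0),
                         tII = numeric(0), tDM = numeric(0),
                         tDD = numeric(0)))
  }
  al <- hmm_hmm_align(point("A"), point("A"))
  expect_equal(al$score, log2(1 / 0.05), tolerance = 1e-6)
  # column vs background-equal column scores zero
  bg <- profile_hmm(matrix(1 / 20, 1, 20),
                    list(tMM = numeric(0), tMI = numeric(0), tMD = numeric(0),
                         tIM = numeric(0), tII = numeric(0),
                         tDM = numeric(0), tDD = numeric(0)))
  expect_equal(hmm_hmm_align(point("A"), bg)$score, 0, tolerance = 1e-9)
})

test_that("profile-profile alignment is symmetric under symmetric gap costs", {
  for (s in 1:5) {
    fa <- simulate_family(family_spec("a", 40, 8, 0.5, seed = s))
    fb <- simulate_family(family_spec("b", 35, 8, 0.5, seed = s + 50))
    ha <- hmm_from_msa(fa$msa)
    hb <- hmm_from_msa(fb$msa)
    expect_equal(hmm_hmm_align(ha, hb)$score, hmm_hmm_align(hb, ha)$score,
                 tolerance = 1e-9)
  }
})
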