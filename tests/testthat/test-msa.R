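test_that("diversity filter keeps the master and the divergent outlier", {
  # under capacity: everything kept
  small <- gm_msa(c("ACDE", "ACDF", "ACDG"), ids = c("m", "s1", "s2"))
  expect_identical(msa_nrow(msa_diff_filter(small, n_keep = 30)), 3L)

  # 99 near-copies of the master plus one divergent row, keep 3
  rows <- c("AAAAAAAA", rep("AAAAAAAC", 99), "WYWYWYWY")
  msa <- gm_msa(rows, ids = c("master", sprintf("c%02d", 1:99), "div"))
  kept <- msa_diff_filter(msa, n_keep = 3)
  expect_identical(kept$ids[1], "master")
  expect_true("div" %in% kept$ids)
})

test_that("diversity filter matches exhaustive maximin search on small inputs", {
  # brute force: best subset of size k (containing the master) that the
  # greedy maximin construction can achieve step by step
  greedy_oracle <- function(rows, k) {
    kept <- 1L
    pool <- setdiff(seq_along(rows), kept)
    while (length(kept) < k && length(pool)) {
      score <- vapply(pool, function(i) {
        max(vapply(kept, function(j) {
          a <- strsplit(rows[i], "")[[1]]; b <- strsplit(rows[j], "")[[1]]
          both <- a != "-" & b != "-"
          if (!any(both)) 0 else mean(a[both] == b[both])
        }, numeric(1)))
      }, numeric(1))
      pick <- pool[which.min(score)]
      kept <- c(kept, pick)
      pool <- setdiff(pool, pick)
    }
    kept
  }
  for (s in 1:5) {
    rows <- vapply(1:8, function(i) random_protein(10, s * 100 + i),
                   character(1))
    msa <- gm_msa(rows, ids = sprintf("r%d", 1:8))
    kept <- msa_diff_filter(msa, n_keep = 4)
    expect_identical(match(kept$ids, msa$ids), greedy_oracle(rows, 4))
  }
})

test_that("insert removal deletes master-gap columns only", {
  # gap-free master: identity
  msa <- gm_msa(c("ACD", "A-D"), ids = c("m", "s"))
  expect_identical(remove_inserts(msa)$rows, msa$rows)
  # single insert column
  msa2 <- gm_msa(c("A-C", "ABC"), ids = c("m", "s"))
  out <- remove_inserts(msa2)
  expect_identical(out$rows, c("AC", "AC"))
  # width equals the master residue count on random alignments
  for (s in 1:5) {
    base <- strsplit(random_protein(20, s), "")[[1]]
    gappy <- base
    drop <- withr::with_seed(s, sample(20, 6))
    gappy[drop] <- "-"
    msa3 <- gm_msa(c(paste0(gappy, collapse = ""),
                     random_protein(20, s + 50)), ids = c("m", "s"))
    expect_identical(msa_ncol(remove_inserts(msa3)), 20L - 6L)
  }
})

test_that("problem-region curation drops fragments then thin columns", {
  full <- gm_msa(rep("ACDEFGHIKLMN", 4), ids = sprintf("r%d", 1:4))
  expect_identical(drop_problem_regions(full)$rows, full$rows)

  withfrag <- gm_msa(c("ACDEFGHIKLMN", "ACDEFGHIKLMN", "AC----------"),
                     ids = c("m", "s", "frag"))
  expect_message(out <- drop_problem_regions(withfrag, min_seq_residues = 10),
                 "dropped")
  expect_false("frag" %in% out$ids)

  # rows-then-columns equals a brute-force application of both predicates
  for (s in 1:5) {
    rows <- withr::with_seed(s, vapply(1:6, function(i) {
      r <- strsplit(random_protein(15, s * 10 + i), "")[[1]]
      r[runif(15) < 0.3] <- "-"
      paste0(r, collapse = "")
    }, character(1)))
    rows[1] <- random_protein(15, s)  # keep the master full
    msa <- gm_msa(rows, ids = sprintf("r%d", 1:6))
    out <- suppressMessages(drop_problem_regions(msa, 0.5, 8))
    m <- do.call(rbind, strsplit(rows, ""))
    keep_rows <- rowSums(m != "-") >= 8
    keep_rows[1] <- TRUE
    m2 <- m[keep_rows, , drop = FALSE]
    keep_cols <- colMeans(m2 != "-") >= 0.5
    expect_identical(out$rows,
                     unname(apply(m2[, keep_cols, drop = FALSE], 1,
                                  paste0, collapse = "")))
  }
  # curation that would empty the alignment errors out
  tiny <- gm_msa(c("A-", "-A"), ids = c("m", "s"))
  expect_error(drop_problem_regions(tiny, min_seq_residues = 5),
               "curation emptied alignment")
})

test_that("stockholm alignments round-trip", {
  msa <- gm_msa(c("ACD-EF", "AC-DEF", "ACDDEF"), ids = c("q", "s1", "s2"))
  path <- withr::local_tempfile(fileext = ".sto")
  write_stockholm(msa, path)
  back <- read_stockholm(path)
  expect_identical(back$rows, msa$rows)
  expect_identical(back$ids, msa$ids)
  expect_error(read_stockholm(withr::local_tempfile(lines = "junk")),
               "Stockholm")
})

test_that("a3m lowercase inserts round-trip through remove_inserts semantics", {
  # master with a gap column: slave residue there becomes a lowercase insert
  msa <- gm_msa(c("AC-DE", "ACXDE", "AC--E"), ids = c("q", "s1", "s2"))
  path <- withr::local_tempfile(fileext = ".a3m")
  write_a3m(msa, path)
  lines <- readLines(path)
  expect_true(any(grepl("x", lines)))      # insert written lowercase
  back <- read_a3m(path)
  # expanding the insert reproduces the original column structure
  expect_identical(msa_ncol(back), 5L)
  expect_identical(remove_inserts(back)$rows, remove_inserts(msa)$rows)
})

test_that("fasta i/o round-trips via Biostrings", {
  seqs <- c(p1 = "ACDEFGHIKL", p2 = "MNPQRSTVWY")
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, path)
  expect_identical(read_fasta(path), seqs)
})

test_that("profile serialization round-trips exactly", {
  fam <- simulate_family(family_spec("f", 40, 8, 0.5, seed = 6))
  h <- hmm_from_msa(fam$msa, name = "roundtrip me")
  path <- withr::local_tempfile(fileext = ".hmm")
  write_profile_hmm(h, path)
  back <- read_profile_hmm(path)
  expect_identical(back$name, h$name)
  expect_identical(back$n_match, h$n_match)
  expect_equal(back$match_emissions, h$match_emissions, tolerance = 1e-15)
  expect_equal(back$transitions, h$transitions, tolerance = 1e-15)
  expect_identical(back$match_map, h$match_map)
  # a scored sequence gives the same bits either way
  s <- random_protein(60, 2)
  expect_equal(forward_score(back, s), forward_score(h, s), tolerance = 1e-12)
  expect_error(read_profile_hmm(withr::local_tempfile(lines = "nope")),
               "profile file")
})

test_that("simulation bundles serialise to plain text with a manifest", {
  fam <- simulate_family(family_spec("famX", 30, 3, 0.7, seed = 2))
  pp <- plant_proteins(list(fam), n_decoys = 2, linker_length = 10, seed = 3,
                       feature_specs = list(list(kind = "low_complexity",
                                                 length = 15, n = 1)))
  outdir <- withr::local_tempdir()
  write_simulation(pp, list(famX = fam), outdir, seed = 3)
  expect_true(file.exists(file.path(outdir, "proteins.fasta")))
  truth <- read.table(file.path(outdir, "truth_intervals.tsv"), header = TRUE,
                      sep = "\t")
  expect_identical(nrow(truth), 3L)          # one interval per planted member
  feats <- read.table(file.path(outdir, "planted_features.tsv"),
                      header = TRUE, sep = "\t")
  expect_identical(feats$kind, "low_complexity")
  man <- jsonlite::read_json(file.path(outdir, "manifest.json"))
  expect_equal(man$seed, 3)
  expect_identical(man$family_alignments[[1]], "famX.sto")
  back <- read_stockholm(file.path(outdir, "famX.sto"))
  expect_identical(back$rows, fam$msa$rows)
  # the fasta round-trips the planted sequences
  seqs <- read_fasta(file.path(outdir, "proteins.fasta"))
  expect_identical(unname(seqs[pp$protein_id[1]]), pp$sequence[1])
})
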