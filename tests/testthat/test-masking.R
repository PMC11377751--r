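test_that("ideal heptads outscore shuffles of their own residues", {
  coil <- strrep("LEALEGK", 6)
  p <- coiled_coil_profile(coil, window = 21)
  top <- max(attr(p, "score"))
  shuffled_tops <- withr::with_seed(17, {
    res <- strsplit(coil, "")[[1]]
    vapply(1:50, function(i) {
      s <- paste0(sample(res), collapse = "")
      max(attr(coiled_coil_profile(s, window = 21), "score"))
    }, numeric(1))
  })
  expect_true(all(top > shuffled_tops))
  expect_gte(max(p), 0.5)
})

test_that("proline-rich sequence never looks coiled", {
  p <- coiled_coil_profile(strrep("P", 40))
  expect_true(all(p < 0.5))
})

test_that("the profile is shift invariant in the repeat interior", {
  coil <- strrep("LEALEGK", 8)
  for (pad in c(5L, 12L)) {
    seq1 <- paste0(strrep("G", pad), coil, strrep("G", pad))
    p <- coiled_coil_profile(seq1)
    s <- attr(p, "score")
    # interior residues (fully covered by all-coil windows) score identically
    interior <- (pad + 22L):(pad + nchar(coil) - 21L)
    expect_equal(s[interior],
                 attr(coiled_coil_profile(coil), "score")[22:(nchar(coil) - 21L)],
                 tolerance = 1e-12)
  }
})

test_that("sequences shorter than the window yield an empty profile", {
  expect_message(p <- coiled_coil_profile("ACDEF"), "shorter")
  expect_length(p, 0)
  expect_error(coiled_coil_profile("ACDEF", window = 10), "14, 21 or 28")
})

test_that("entropy masking flags homopolymers and spares diverse windows", {
  m <- low_complexity_mask(strrep("A", 12))
  expect_identical(m$start, 1L)
  expect_identical(m$end, 12L)
  expect_equal(m$score, 0)
  # 12 distinct residues: entropy log2(12) > 2.2, unmasked
  expect_identical(nrow(low_complexity_mask("ACDEFGHIKLMN")), 0L)
})

test_that("random background is rarely masked", {
  masked_frac <- vapply(1:20, function(s) {
    seqs <- random_protein(200, s)
    m <- low_complexity_mask(seqs)
    if (nrow(m)) sum(m$end - m$start + 1) / 200 else 0
  }, numeric(1))
  expect_lt(mean(masked_frac), 0.05)
})

test_that("planted coiled coils are covered by the mask across seeds", {
  cov <- vapply(1:20, function(s) {
    pp <- plant_proteins(list(), n_decoys = 1, linker_length = 30,
                         feature_specs = list(list(kind = "coiled_coil",
                                                   length = 56, n = 1)),
                         seed = s)
    f <- pp$features[[1]]
    m <- coiled_coil_mask(pp$sequence[1])
    masked <- rep(FALSE, nchar(pp$sequence[1]))
    if (nrow(m)) for (k in seq_len(nrow(m))) masked[m$start[k]:m$end[k]] <- TRUE
    mean(masked[f$start:f$end])
  }, numeric(1))
  expect_true(all(cov >= 0.8))
})

test_that("searchable regions complement the masks exactly", {
  no_mask <- tibble::tibble(start = integer(), end = integer())
  expect_identical(searchable_regions(strrep("A", 100), no_mask,
                                      min_region_length = 1),
                   tibble::tibble(start = 1L, end = 100L))
  one <- tibble::tibble(start = 40L, end = 60L)
  out <- searchable_regions(strrep("A", 100), one, min_region_length = 1)
  expect_identical(out, tibble::tibble(start = c(1L, 61L), end = c(39L, 100L)))
  # random mask sets match a per-residue boolean scan
  for (s in 1:5) {
    masks <- withr::with_seed(s, {
      st <- sort(sample(1:90, 4))
      tibble::tibble(start = st, end = pmin(100L, st + sample(3:20, 4)))
    })
    out <- suppressMessages(searchable_regions(strrep("A", 100), masks,
                                               min_region_length = 1))
    boolean <- rep(TRUE, 100)
    for (k in 1:4) boolean[masks$start[k]:masks$end[k]] <- FALSE
    covered <- rep(FALSE, 100)
    if (nrow(out)) for (k in seq_len(nrow(out))) {
      covered[out$start[k]:out$end[k]] <- TRUE
    }
    expect_identical(covered, boolean)
  }
  # fully masked sequence: empty region list, reported as skipped
  expect_message(
    full <- searchable_regions(strrep("A", 50),
                               tibble::tibble(start = 1L, end = 50L)),
    "fully masked")
  expect_identical(nrow(full), 0L)
})

test_that("masked plus searchable partitions the sequence", {
  seqs <- paste0(random_protein(80, 1), strrep("LEALEGK", 8),
                 random_protein(80, 2), strrep("Q", 20), random_protein(40, 3))
  res <- suppressMessages(mask_sequence(seqs, min_region_length = 10))
  occupied <- rep(0L, nchar(seqs))
  if (nrow(res$masks)) for (k in seq_len(nrow(res$masks))) {
    occupied[res$masks$start[k]:res$masks$end[k]] <- 1L
  }
  for (k in seq_len(nrow(res$regions))) {
    seg <- res$regions$start[k]:res$regions$end[k]
    expect_true(all(occupied[seg] == 0L))  # searchable never overlaps a mask
  }
})

test_that("mask BED export shifts to 0-based half-open coordinates", {
  m <- tibble::tibble(start = 5L, end = 10L, kind = "low_complexity",
                      score = 1.0)
  path <- withr::local_tempfile(fileext = ".bed")
  write_mask_bed(m, "seq1", path)
  bed <- read.table(path, sep = "\t")
  expect_identical(bed$V2, 4L)
  expect_identical(bed$V3, 10L)
})
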