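planted_world <- function(seed, rho = 0.9, n_mod = 10, n_bg = 200,
                          n_samples = 200, n_tissues = 1) {
  mods <- if (n_mod > 0) {
    list(list(module_id = "M1", genes = sprintf("mod_%02d", seq_len(n_mod)),
              rho = rho))
  } else {
    list()
  }
  simulate_expression(expression_spec(n_tissues, n_samples, mods,
                                      n_background_genes = n_bg, seed = seed))
}

test_that("pearson matrix matches textbook two-pass computation", {
  m <- withr::with_seed(1, matrix(rnorm(50), 5, 10,
                                  dimnames = list(paste0("g", 1:5), NULL)))
  cm <- pearson_matrix(m)
  expect_true(isSymmetric(cm))
  expect_equal(unname(diag(cm)), rep(1, 5))
  # independent two-pass formula
  for (i in 1:4) for (j in (i + 1):5) {
    x <- m[i, ]; y <- m[j, ]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(cm[i, j], r, tolerance = 1e-12)
  }
  # affine and anti-affine cases
  x <- 1:10
  m2 <- rbind(x = x, y = 2 * x + 1, z = -x)
  expect_equal(pearson_matrix(m2)["x", "y"], 1)
  expect_equal(pearson_matrix(m2)["x", "z"], -1)
  # zero-variance gene dropped with a warning
  m3 <- rbind(m, const = rep(1, 10))
  expect_warning(cm3 <- pearson_matrix(m3), "zero-variance")
  expect_false("const" %in% rownames(cm3))
})

test_that("module detection recovers a planted module and rejects noise", {
  ex <- planted_world(1)
  mods <- detect_modules(ex$matrices[[1]], tissue = "t1")
  expect_identical(length(unique(mods$module_id)), 1L)
  planted <- sprintf("mod_%02d", 1:10)
  expect_gte(sum(mods$gene %in% planted), 9L)
  expect_identical(sum(!mods$gene %in% planted), 0L)

  # background-only matrix: nothing detected
  bg <- planted_world(2, n_mod = 0)
  bg$matrices[[1]] <- bg$matrices[[1]][grep("bg", rownames(bg$matrices[[1]])), ]
  expect_identical(nrow(detect_modules(bg$matrices[[1]])), 0L)

  # a threshold beyond |r| <= 1 can never form an edge
  expect_identical(nrow(detect_modules(ex$matrices[[1]], r_min = 1.01)), 0L)
})

test_that("module pairs follow the k-choose-2 count", {
  mods <- tibble::tibble(tissue = "t", module_id = "t_M01",
                         gene = c("a", "b", "c"))
  expect_identical(nrow(module_pairs(mods)), 3L)
  for (k in c(2, 5, 9)) {
    mk <- tibble::tibble(tissue = "t", module_id = "t_M01",
                         gene = sprintf("g%d", seq_len(k)))
    expect_identical(nrow(module_pairs(mk)), as.integer(k * (k - 1) / 2))
  }
  # two disjoint modules share no cross pairs
  two <- dplyr::bind_rows(
    tibble::tibble(tissue = "t", module_id = "t_M01", gene = c("a", "b")),
    tibble::tibble(tissue = "t", module_id = "t_M02", gene = c("x", "y")))
  pairs <- module_pairs(two)
  expect_identical(nrow(pairs), 2L)
  expect_false(any(pairs$gene_1 %in% c("a", "b") &
                     pairs$gene_2 %in% c("x", "y")))
})

test_that("cross-tissue recurrence counts tissues, not modules", {
  pairs <- tibble::tibble(
    gene_1 = c("a", "a", "a", "b", "b"),
    gene_2 = c("b", "b", "b", "c", "c"),
    tissue = c("t1", "t2", "t3", "t1", "t1"))
  out <- cross_tissue_filter(pairs, min_tissues = 2)
  expect_identical(out$gene_1, "a")      # b-c seen twice but in one tissue
  expect_identical(out$n_tissues, 3L)
  # boundary: a pair in exactly 1 tissue is excluded at the default
  one <- cross_tissue_filter(pairs[4:5, ], min_tissues = 2)
  expect_identical(nrow(one), 0L)
  # min_tissues = 1 is the identity on the union of pairs
  all1 <- cross_tissue_filter(pairs, min_tissues = 1)
  expect_identical(nrow(all1), 2L)
})

test_that("cross-tissue filter equals brute-force counting on random sets", {
  withr::with_seed(12, {
    genes <- sprintf("g%02d", 1:15)
    pairs <- dplyr::bind_rows(lapply(sprintf("t%d", 1:4), function(t) {
      k <- sample(20:40, 1)
      a <- sample(genes, k, replace = TRUE)
      b <- sample(genes, k, replace = TRUE)
      keep <- a != b
      tibble::tibble(gene_1 = pmin(a[keep], b[keep]),
                     gene_2 = pmax(a[keep], b[keep]), tissue = t)
    }))
  })
  out <- cross_tissue_filter(pairs, min_tissues = 2)
  key <- paste(pairs$gene_1, pairs$gene_2)
  counts <- tapply(pairs$tissue, key, function(t) length(unique(t)))
  expect_identical(sort(paste(out$gene_1, out$gene_2)),
                   sort(names(counts)[counts >= 2]))
})

test_that("the interaction filter protocol carries over to gene pairs", {
  ann <- data.frame(protein_id = c("ddr1", "ddr2", "resp"),
                    term_id = c("GO:0006281", "GO:0006281", "GO:0006974"))
  pairs <- tibble::tibble(
    gene_1 = c("ddr1", "ddr1", "ddr1", "ddr1"),
    gene_2 = c("new", "ddr2", "hk", "resp"))
  out <- filter_coexpr_pairs(pairs, ann, housekeeping_ids = "hk")
  expect_identical(out$candidates$protein_id, "new")
  expect_identical(out$candidates$provenance, "co-expression-derived")
})

test_that("full co-expression stage yields only clean candidates", {
  genes <- c("ddr_gene", sprintf("mod_%02d", 1:9))
  mats <- lapply(1:2, function(t) {
    simulate_expression(expression_spec(
      1, 150, list(list(module_id = "M1", genes = genes, rho = 0.85)),
      n_background_genes = 80, seed = 40 + t))$matrices[[1]]
  })
  names(mats) <- c("t1", "t2")
  ann <- data.frame(protein_id = "ddr_gene", term_id = "GO:0006281")
  res <- coexpr_candidates(mats, ann, housekeeping_ids = "mod_01",
                           contaminant_ids = "mod_02")
  expect_false(any(res$candidates$protein_id %in%
                     c("ddr_gene", "mod_01", "mod_02")))
  expect_gte(nrow(res$candidates), 5L)
})

test_that("co-expression ranking puts the module mate on top", {
  ex <- planted_world(3)
  rk <- rank_coexpressed(ex$matrices, "mod_01")
  planted <- sprintf("mod_%02d", 2:10)
  expect_true(all(rk$gene[1:9] %in% planted))
  expect_false("mod_01" %in% rk$gene)
  expect_identical(nrow(rank_coexpressed(ex$matrices, "mod_01", top_k = 0)),
                   0L)
  expect_error(rank_coexpressed(ex$matrices, "nope"), "not present")
  # duplicate gene ids collapse to one entry
  m <- ex$matrices[[1]]
  mdup <- rbind(m, m["mod_05", , drop = FALSE])
  expect_message(rk2 <- rank_coexpressed(list(mdup), "mod_01"), "Duplicate")
  expect_identical(sum(rk2$gene == "mod_05"), 1L)
})
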