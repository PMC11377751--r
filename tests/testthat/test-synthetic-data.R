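test_that("family simulation controls divergence and honours its seed", {
  # no-mutation case: all members identical to the ancestor, gap-free MSA
  fam0 <- simulate_family(family_spec("f", 40, 4, target_identity = 1,
                                      indel_rate = 0, seed = 1))
  expect_true(all(fam0$members == paste0(fam0$ancestor, collapse = "")))
  expect_false(any(grepl("-", fam0$msa$rows, fixed = TRUE)))

  # binomial expectation: identity 0.4 over 100 sites, 30 members
  fam <- simulate_family(family_spec("f", 100, 30, 0.4, seed = 7))
  expect_gte(mean(fam$identity), 0.34)
  expect_lte(mean(fam$identity), 0.46)

  # seed contract: same spec reproduces, different seed differs
  again <- simulate_family(family_spec("f", 100, 30, 0.4, seed = 7))
  expect_identical(fam$members, again$members)
  other <- simulate_family(family_spec("f", 100, 30, 0.4, seed = 8))
  expect_false(all(fam$members == other$members))

  expect_error(family_spec("f", 100, 30, target_identity = 0), "0 is rejected")
})

test_that("identity control concentrates for long domains across seeds", {
  for (s in 1:10) {
    fam <- simulate_family(family_spec("f", 150, 10, 0.55, seed = s))
    expect_lt(abs(mean(fam$identity) - 0.55), 0.06 + (1 - 0.55) / 20)
  }
})

test_that("indels produce gapped true alignments with bounded drift", {
  fam <- simulate_family(family_spec("f", 100, 10, 0.6, indel_rate = 0.02,
                                     seed = 3))
  expect_true(any(grepl("-", fam$msa$rows, fixed = TRUE)))
  expect_true(any(attr(fam$msa, "homologous")))
  # homologous column count equals ancestor length
  expect_identical(sum(attr(fam$msa, "homologous")), 100L)
})

test_that("plant_proteins delimits planted material exactly", {
  fam <- simulate_family(family_spec("fx", 50, 3, 0.8, seed = 2))
  pp <- plant_proteins(list(fam), n_decoys = 0, linker_length = 25, seed = 4)
  expect_identical(nchar(pp$sequence[1]),
                   50L + 50L + nchar(fam$members[[1]]) - 50L)  # 25+dom+25
  tr <- pp$truth[[1]]
  expect_identical(tr$start, 26L)
  expect_identical(tr$end, 25L + nchar(fam$members[[1]]))
  # the planted interval reproduces the member sequence
  expect_identical(substr(pp$sequence[1], tr$start, tr$end),
                   unname(fam$members[1]))
})

test_that("planted coiled coils have hydrophobic a/d positions", {
  pp <- plant_proteins(list(), n_decoys = 3, linker_length = 10,
                       feature_specs = list(list(kind = "coiled_coil",
                                                 length = 70, n = 3)),
                       seed = 11)
  for (i in 1:3) {
    f <- pp$features[[i]]
    tract <- substr(pp$sequence[i], f$start, f$end)
    res <- strsplit(tract, "")[[1]]
    pos <- (seq_along(res) - 1L) %% 7L
    expect_true(all(res[pos %in% c(0L, 3L)] %in% c("L", "I", "V", "M", "F")))
  }
})

test_that("decoy-only worlds carry empty truth", {
  pp <- plant_proteins(list(), n_decoys = 100, seed = 5)
  expect_identical(nrow(pp), 100L)
  expect_true(all(vapply(pp$truth, nrow, integer(1)) == 0L))
  expect_error(plant_proteins(list(), n_decoys = 0), "at least one")
  expect_error(
    plant_proteins(list(), n_decoys = 2, linker_length = function(n) rep(-1, n),
                   seed = 1),
    "negative support")
})

test_that("low-complexity tracts stay within 3 residue types", {
  pp <- plant_proteins(list(), n_decoys = 2, linker_length = 10,
                       feature_specs = list(list(kind = "low_complexity",
                                                 length = 30, n = 2)),
                       seed = 8)
  for (i in 1:2) {
    f <- pp$features[[i]]
    tract <- substr(pp$sequence[i], f$start, f$end)
    expect_lte(length(unique(strsplit(tract, "")[[1]])), 3L)
  }
})

test_that("expression modules reach their target correlation", {
  sp <- expression_spec(1, 200, list(list(module_id = "M1",
                                          genes = paste0("g", 1:10),
                                          rho = 0.9)),
                        n_background_genes = 0, seed = 21)
  ex <- simulate_expression(sp)
  cm <- cor(t(ex$matrices[[1]]))
  within <- cm[upper.tri(cm)]
  expect_gte(mean(within), 0.85)
  expect_lte(mean(within), 0.95)
})

test_that("background genes are uncorrelated noise", {
  sp <- expression_spec(1, 200, list(), n_background_genes = 60, seed = 22)
  ex <- simulate_expression(sp)
  cm <- cor(t(ex$matrices[[1]]))
  off <- abs(cm[upper.tri(cm)])
  expect_lte(mean(off >= 0.8), 0.001)
})

test_that("expression truth is seed-stable, values are not", {
  mk <- function(seed) simulate_expression(
    expression_spec(2, 50, list(list(module_id = "M1",
                                     genes = paste0("g", 1:5), rho = 0.8)),
                    n_background_genes = 5, seed = seed))
  a <- mk(1); b <- mk(2)
  expect_identical(a$membership, b$membership)
  expect_false(identical(a$matrices[[1]], b$matrices[[1]]))
  expect_identical(a$matrices, mk(1)$matrices)
  expect_error(expression_spec(1, 2, list()), "at least 3 samples")
  expect_error(
    expression_spec(1, 10, list(list(module_id = "M", genes = "g", rho = 1))),
    "strictly")
})

test_that("ppi generator produces records the filters understand", {
  prots <- sprintf("p%02d", 1:20)
  tp <- data.frame(protein_a = prots[1:5], protein_b = prots[6:10])
  tab <- simulate_ppi(prots, tp,
                      evidence_model = list(p_experimental = 1,
                                            mean_publications = 2,
                                            n_contaminant = 10,
                                            n_housekeeping = 5),
                      contaminant_ids = c("KRT1", "KRT2"),
                      housekeeping_ids = c("ACTB"),
                      seed = 31)
  expect_true(all(c("true_pair", "contaminant", "housekeeping") %in%
                    tab$pair_class))
  # forced experimental evidence with >= 1 publication
  has_exp <- vapply(tab$evidence_types, function(e) "experimental" %in% e,
                    logical(1))
  expect_true(all(has_exp))
  expect_true(all(tab$n_publications_experimental[has_exp] >= 1))
  expect_error(simulate_ppi(prots, data.frame(protein_a = "zz",
                                              protein_b = "p01")),
               "Unknown protein ids")
})

test_that("go simulation annotates via children and stays acyclic", {
  rules <- data.frame(protein_id = c("p1", "p2", "p3"),
                      mode = c("child", "direct", "none"),
                      term = c("GO:0006281", "GO:0006974", "GO:0006281"))
  sim <- simulate_go(3, c("p1", "p2", "p3"), rules, seed = 41)
  ann1 <- sim$annotations$term_id[sim$annotations$protein_id == "p1"]
  expect_false("GO:0006281" %in% ann1)  # child-only annotation
  expect_true(ann1 %in% go_descendants(sim$dag, "GO:0006281"))
  ann2 <- sim$annotations$term_id[sim$annotations$protein_id == "p2"]
  expect_identical(ann2, "GO:0006974")

  # depth 1: the terms of interest are leaves
  shallow <- simulate_go(1, "p1", data.frame(protein_id = "p1",
                                             mode = "direct",
                                             term = "GO:0006281"), seed = 1)
  for (t in terms_of_interest()) {
    expect_length(go_descendants(shallow$dag, t), 0)
  }

  # acyclicity holds for any seed (go_dag() would abort on a cycle)
  for (s in 1:10) {
    sim_s <- simulate_go(4, character(), rules[0, ], seed = s)
    expect_s3_class(sim_s$dag, "go_dag")
  }
})
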