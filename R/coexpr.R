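#' Gene-gene Pearson correlation matrix
#'
#' Standard Pearson correlation across the samples of one tissue. Genes with
#' zero variance have no defined correlation and are dropped with a warning.
#'
#' @param expr Genes x samples numeric matrix with rownames (gene ids), or a
#'   data frame whose first column is the gene id and remaining columns are
#'   samples.
#' @return Symmetric correlation matrix with unit diagonal.
#' @examples
#' m <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("g", 1:4), NULL))
#' pearson_matrix(m)[1:2, 1:2]
#' @export
pearson_matrix <- function(expr) {
  expr <- as_expression_matrix(expr)
  if (ncol(expr) < 3) abort("Need at least 3 samples for correlation.")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warn(paste0("Dropping ", sum(v == 0), " zero-variance gene(s): ",
                paste(head(rownames(expr)[v == 0], 5), collapse = ", ")))
    expr <- expr[v > 0, , drop = FALSE]
  }
  cor(t(expr))
}

# Accept a matrix or a first-column-gene-id data frame (the TSV layout).
as_expression_matrix <- function(expr) {
  if (is.matrix(expr)) {
    if (is.null(rownames(expr))) abort("Expression matrix needs gene rownames.")
    storage.mode(expr) <- "double"
    if (anyNA(expr)) abort("Expression matrix contains missing values.")
    return(expr)
  }
  df <- as.data.frame(expr)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  if (anyNA(m)) abort("Expression matrix contains missing values.")
  m
}

#' Detect co-expression modules in one tissue
#'
#' Default detector: connected components of the thresholded correlation
#' graph, with an edge between two genes when `|r| >= r_min`, keeping
#' components of at least `min_module_size` genes. The detector is pluggable:
#' pass any `method` function taking the correlation matrix and returning a
#' list of gene-id vectors; downstream steps only consume the gene sets.
#'
#' @param expr Expression matrix (see [pearson_matrix()]).
#' @param tissue Tissue label attached to the modules.
#' @param r_min Absolute-correlation threshold (default 0.6).
#' @param min_module_size Minimum module size (default 5).
#' @param method Optional replacement detector function.
#' @return Tibble `tissue`, `module_id`, `gene` (one row per member gene);
#'   empty when nothing passes.
#' @export
detect_modules <- function(expr, tissue = "tissue", r_min = 0.6,
                           min_module_size = 5L, method = NULL) {
  cmat <- pearson_matrix(expr)
  sets <- if (is.null(method)) {
    adj <- abs(cmat) >= r_min
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)
    keep <- which(comp$csize >= min_module_size)
    lapply(keep, function(k) sort(names(comp$membership)[comp$membership == k]))
  } else {
    method(cmat)
  }
  sets <- Filter(function(s) length(s) >= min_module_size, sets)
  if (!length(sets)) {
    return(tibble(tissue = character(), module_id = character(),
                  gene = character()))
  }
  bind_rows(lapply(seq_along(sets), function(i) {
    tibble(tissue = tissue, module_id = sprintf("%s_M%02d", tissue, i),
           gene = sets[[i]])
  }))
}

#' Enumerate within-module gene pairs
#'
#' Every unordered pair of genes inside each module, per tissue: a module of k
#' genes contributes k(k-1)/2 pairs. Pairs are canonicalised (gene_1 < gene_2)
#' so recurrence across tissues can be counted.
#'
#' @param modules Tibble from [detect_modules()] (columns `tissue`,
#'   `module_id`, `gene`).
#' @return Tibble `gene_1`, `gene_2`, `tissue`, `module_id`.
#' @export
module_pairs <- function(modules) {
  modules <- as_tibble(modules)
  if (!nrow(modules)) {
    return(tibble(gene_1 = character(), gene_2 = character(),
                  tissue = character(), module_id = character()))
  }
  out <- list()
  for (key in unique(modules$module_id)) {
    sub <- modules[modules$module_id == key, ]
    g <- sort(unique(sub$gene))
    if (length(g) < 2) next
    idx <- utils::combn(length(g), 2)
    out[[key]] <- tibble(gene_1 = g[idx[1, ]], gene_2 = g[idx[2, ]],
                         tissue = sub$tissue[1], module_id = key)
  }
  if (!length(out)) {
    return(tibble(gene_1 = character(), gene_2 = character(),
                  tissue = character(), module_id = character()))
  }
  bind_rows(out)
}

#' Keep gene pairs recurring in at least `min_tissues` tissues
#'
#' A pair counts once per tissue it appears in (however many modules of that
#' tissue contain it); pairs present in fewer than `min_tissues` distinct
#' tissues are dropped. At `min_tissues = 1` this is the identity on the
#' union of pairs.
#'
#' @param pairs Tibble with `gene_1`, `gene_2`, `tissue` (e.g. the row-bound
#'   [module_pairs()] of several tissues).
#' @param min_tissues Recurrence threshold (default 2).
#' @return Tibble `gene_1`, `gene_2`, `n_tissues` of surviving pairs.
#' @export
cross_tissue_filter <- function(pairs, min_tissues = 2L) {
  pairs <- as_tibble(pairs)
  if (!nrow(pairs)) {
    return(tibble(gene_1 = character(), gene_2 = character(),
                  n_tissues = integer()))
  }
  counts <- summarise(group_by(pairs, .data$gene_1, .data$gene_2),
                      n_tissues = length(unique(.data$tissue)),
                      .groups = "drop")
  out <- counts[counts$n_tissues >= min_tissues, , drop = FALSE]
  arrange(out, .data$gene_1, .data$gene_2)
}

#' Apply the interaction filter protocol to co-expression pairs
#'
#' Re-uses the DDR pair-asymmetry and exclusion-list filters on gene pairs
#' (the evidence filter is vacuous here: co-expression pairs carry no
#' publication field). Survivors are flagged as co-expression-derived
#' candidates.
#'
#' @param pairs Tibble `gene_1`, `gene_2` (e.g. from [cross_tissue_filter()]).
#' @param annotations Propagated annotation table `protein_id`, `term_id`.
#' @param housekeeping_ids,contaminant_ids Exclusion lists.
#' @return List with `records` (surviving pairs incl. `candidate` column) and
#'   `candidates` (tibble `protein_id`, `provenance`).
#' @export
filter_coexpr_pairs <- function(pairs, annotations,
                                housekeeping_ids = character(),
                                contaminant_ids = character()) {
  pairs <- as_tibble(pairs)
  recs <- tibble(protein_a = pairs$gene_1, protein_b = pairs$gene_2)
  extra <- pairs[setdiff(names(pairs), c("gene_1", "gene_2"))]
  recs <- bind_cols(recs, extra)
  s1 <- filter_ddr_asymmetry(recs, annotations)
  filter_lists(s1, housekeeping_ids, contaminant_ids,
               provenance = "co-expression-derived")
}

#' Full co-expression candidate stage over several tissues
#'
#' Detects modules per tissue, enumerates within-module pairs, keeps pairs
#' recurring in at least `min_tissues` tissues, and applies the interaction
#' filter protocol. Attrition is reported per stage.
#'
#' @param matrices Named list of per-tissue expression matrices.
#' @param annotations Propagated annotation table.
#' @param housekeeping_ids,contaminant_ids Exclusion lists.
#' @param r_min,min_module_size,min_tissues Detector and recurrence settings.
#' @return List `candidates`, `pairs`, `attrition`.
#' @export
coexpr_candidates <- function(matrices, annotations,
                              housekeeping_ids = character(),
                              contaminant_ids = character(),
                              r_min = 0.6, min_module_size = 5L,
                              min_tissues = 2L) {
  if (is.null(names(matrices))) {
    names(matrices) <- sprintf("tissue_%02d", seq_along(matrices))
  }
  all_pairs <- bind_rows(lapply(names(matrices), function(t) {
    module_pairs(detect_modules(matrices[[t]], tissue = t, r_min = r_min,
                                min_module_size = min_module_size))
  }))
  funnel <- tibble(stage = "module_pairs", n_records = nrow(all_pairs))
  recur <- cross_tissue_filter(all_pairs, min_tissues)
  funnel <- bind_rows(funnel, tibble(stage = "cross_tissue",
                                     n_records = nrow(recur)))
  flt <- filter_coexpr_pairs(recur, annotations, housekeeping_ids,
                             contaminant_ids)
  funnel <- bind_rows(funnel, tibble(stage = "filter_protocol",
                                     n_records = nrow(flt$records)))
  list(candidates = flt$candidates, pairs = flt$records, attrition = funnel)
}

#' Rank genes co-expressed with a query gene
#'
#' Computes the Pearson correlation of every other gene with the query in each
#' supplied tissue, averages r across tissues (arithmetic mean), and returns
#' the descending ranking — the co-expression signature of the query. Ties
#' are broken by gene id; the query is excluded from its own list.
#'
#' @param matrices Named list of per-tissue expression matrices.
#' @param query_gene Gene id present in every matrix.
#' @param top_k Number of genes to return (default all).
#' @return Tibble `gene`, `mean_r`, `rank`.
#' @export
rank_coexpressed <- function(matrices, query_gene, top_k = Inf) {
  if (!is.list(matrices)) matrices <- list(matrices)
  rs <- lapply(matrices, function(m) {
    m <- as_expression_matrix(m)
    if (!query_gene %in% rownames(m)) {
      abort(paste0("Query gene not present: ", query_gene))
    }
    if (anyDuplicated(rownames(m))) {
      inform("Duplicate gene ids submitted; keeping first occurrence of each.")
      m <- m[!duplicated(rownames(m)), , drop = FALSE]
    }
    v <- apply(m, 1, stats::var)
    m <- m[v > 0, , drop = FALSE]
    q <- m[query_gene, ]
    r <- as.numeric(cor(t(m), q))
    setNames(r, rownames(m))
  })
  genes <- sort(unique(unlist(lapply(rs, names))))
  genes <- setdiff(genes, query_gene)
  mean_r <- vapply(genes, function(g) {
    vals <- vapply(rs, function(r) if (g %in% names(r)) r[[g]] else NA_real_,
                   numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ord <- order(-mean_r, genes)
  out <- tibble(gene = genes[ord], mean_r = mean_r[ord])
  out <- head(out, top_k)
  out$rank <- seq_len(nrow(out))
  out
}
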