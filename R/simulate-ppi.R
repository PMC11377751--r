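#' Simulate a protein-protein interaction table with evidence annotation
#'
#' Emulates an integrated interaction database: each record joins two protein
#' ids and carries a set of evidence types (experimental / orthology /
#' predicted) plus the number of publications with experimental evidence.
#' Supplied true pairs are emitted with the evidence the model assigns them;
#' additional records pair random proteins with members of the contaminant and
#' housekeeping lists so the downstream exclusion filters have known targets.
#' Ground truth (pair class) is retained on every record.
#'
#' @param proteins Character vector of protein ids the table may draw from.
#' @param true_pairs Tibble/data frame with columns `protein_a`, `protein_b`:
#'   the planted interactions.
#' @param evidence_model List of generation settings:
#'   `p_experimental` (probability a record carries experimental evidence,
#'   default 0.8), `p_orthology`, `p_predicted` (defaults 0.3),
#'   `mean_publications` (Poisson mean for the publication count of records
#'   with experimental evidence, default 2.5), `n_contaminant` and
#'   `n_housekeeping` (how many extra records pair a random protein with a
#'   listed id, defaults 0).
#' @param contaminant_ids,housekeeping_ids Character vectors of listed ids.
#' @param seed Integer seed.
#' @return Tibble with columns `protein_a`, `protein_b`, `evidence_types`
#'   (list column of character vectors), `n_publications_experimental`, and
#'   the truth column `pair_class` in
#'   `{"true_pair", "contaminant", "housekeeping"}`.
#' @examples
#' simulate_ppi(c("p1", "p2", "p3"),
#'              true_pairs = data.frame(protein_a = "p1", protein_b = "p2"),
#'              seed = 1)
#' @export
simulate_ppi <- function(proteins, true_pairs,
                         evidence_model = list(),
                         contaminant_ids = character(),
                         housekeeping_ids = character(),
                         seed = 1L) {
  em <- utils::modifyList(
    list(p_experimental = 0.8, p_orthology = 0.3, p_predicted = 0.3,
         mean_publications = 2.5, n_contaminant = 0L, n_housekeeping = 0L),
    evidence_model
  )
  true_pairs <- as_tibble(true_pairs)
  bad <- setdiff(c(true_pairs$protein_a, true_pairs$protein_b), proteins)
  if (length(bad)) {
    abort(paste0("Unknown protein ids in `true_pairs`: ",
                 paste(head(bad, 3), collapse = ", ")))
  }
  if (em$n_contaminant > 0 && !length(contaminant_ids)) {
    abort("Contaminant records requested but `contaminant_ids` is empty.")
  }
  if (em$n_housekeeping > 0 && !length(housekeeping_ids)) {
    abort("Housekeeping records requested but `housekeeping_ids` is empty.")
  }
  with_seed_(seed, {
    draw_evidence <- function(n) {
      lapply(seq_len(n), function(i) {
        ev <- c("experimental", "orthology", "predicted")[
          c(runif(1) < em$p_experimental,
            runif(1) < em$p_orthology,
            runif(1) < em$p_predicted)]
        if (!length(ev)) ev <- "predicted"  # a record always has some source
        ev
      })
    }
    make_block <- function(a, b, class) {
      n <- length(a)
      ev <- draw_evidence(n)
      pubs <- integer(n)
      has_exp <- vapply(ev, function(e) "experimental" %in% e, logical(1))
      pubs[has_exp] <- 1L + rpois(sum(has_exp), em$mean_publications - 1)
      tibble(protein_a = a, protein_b = b, evidence_types = ev,
             n_publications_experimental = pubs,
             pair_class = class)
    }
    out <- make_block(true_pairs$protein_a, true_pairs$protein_b, "true_pair")
    if (em$n_contaminant > 0) {
      out <- bind_rows(out, make_block(
        sample(proteins, em$n_contaminant, replace = TRUE),
        sample(contaminant_ids, em$n_contaminant, replace = TRUE),
        "contaminant"))
    }
    if (em$n_housekeeping > 0) {
      out <- bind_rows(out, make_block(
        sample(proteins, em$n_housekeeping, replace = TRUE),
        sample(housekeeping_ids, em$n_housekeeping, replace = TRUE),
        "housekeeping"))
    }
    out <- out[out$protein_a != out$protein_b, ]
    out
  })
}
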