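#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a profile HMM into per-state emission rows
#'
#' @param x A [profile_hmm].
#' @param ... Unused.
#' @return Tibble `state`, `residue`, `probability`, `log_odds`.
#' @export
tidy.profile_hmm <- function(x, ...) {
  em <- x$match_emissions
  tibble(
    state = rep(seq_len(x$n_match), times = 20),
    residue = rep(AA, each = x$n_match),
    probability = as.numeric(em),
    log_odds = as.numeric(log2(sweep(em, 2, x$background, "/")))
  )
}

#' @rdname tidy.profile_hmm
#' @return `glance()` returns a one-row tibble: `n_match`, `mean_information`
#'   (mean per-state relative entropy vs background, bits) and `name`.
#' @export
glance.profile_hmm <- function(x, ...) {
  rel_ent <- rowSums(x$match_emissions *
                       log2(sweep(x$match_emissions, 2, x$background, "/")))
  tibble(name = x$name, n_match = x$n_match,
         mean_information = mean(rel_ent))
}

#' Tidy calibrated E-value parameters
#' @param x An `evd_params` object.
#' @param ... Unused.
#' @return One-row tibble `lambda`, `mu`, `n_db`, `mode`.
#' @export
tidy.evd_params <- function(x, ...) {
  tibble(lambda = x$lambda, mu = x$mu,
         n_db = x$n_db %||% NA_real_, mode = x$mode)
}

#' Tidy a forward search into its hit table
#' @param x A `gm_search` object.
#' @param ... Unused.
#' @return The hits tibble.
#' @export
tidy.gm_search <- function(x, ...) x$hits

#' @rdname tidy.gm_search
#' @return `glance()` returns one row: regions searched, hits, families hit.
#' @export
glance.gm_search <- function(x, ...) {
  tibble(n_regions = length(x$profiles), n_hits = nrow(x$hits),
         n_families_hit = length(unique(x$hits$family)))
}

#' Tidy a catalog report into its candidate table
#' @param x A `gm_report`.
#' @param ... Unused.
#' @return The candidates tibble.
#' @export
tidy.gm_report <- function(x, ...) x$candidates

#' @rdname tidy.gm_report
#' @export
glance.gm_report <- function(x, ...) {
  tibble(n_candidates = x$n_candidates,
         n_validated = x$status_counts$validated %||% 0L,
         n_forward_only = x$status_counts$forward_only %||% 0L,
         n_rejected = x$status_counts$rejected %||% 0L)
}

#' Per-state information-content profile of a profile HMM
#'
#' @param object A [profile_hmm].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.profile_hmm <- function(object, ...) {
  rel_ent <- rowSums(object$match_emissions *
                       log2(sweep(object$match_emissions, 2,
                                  object$background, "/")))
  df <- tibble(state = seq_len(object$n_match), information = rel_ent)
  ggplot2::ggplot(df, ggplot2::aes(.data$state, .data$information)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Match state", y = "Information (bits)",
                  title = object$name) +
    ggplot2::theme_minimal()
}

#' E-value / hit overview of a forward search
#'
#' @param object A `gm_search`.
#' @param ... Unused.
#' @return A ggplot of hit E-values per family.
#' @export
autoplot.gm_search <- function(object, ...) {
  if (!nrow(object$hits)) abort("No hits to plot.")
  ggplot2::ggplot(object$hits,
                  ggplot2::aes(.data$family, -log10(.data$evalue))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Family", y = expression(-log[10](E)),
                  title = "Forward profile-profile hits") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Attrition funnel plot
#'
#' @param attrition Tibble `stage`, `n_records` (e.g. from
#'   [ppi_candidates()] or [coexpr_candidates()]).
#' @return A ggplot bar chart preserving stage order.
#' @export
plot_attrition <- function(attrition) {
  attrition <- as_tibble(attrition)
  attrition$stage <- factor(attrition$stage, levels = attrition$stage)
  ggplot2::ggplot(attrition, ggplot2::aes(.data$stage, .data$n_records)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_records), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "Records") +
    ggplot2::theme_minimal()
}

#' Masking profile plot for one sequence
#'
#' @param seq Amino-acid string.
#' @param window,weighted Coiled-coil settings (see [coiled_coil_profile()]).
#' @return A ggplot of the per-residue coiled-coil probability with the 0.5
#'   mask cutoff.
#' @export
plot_masking <- function(seq, window = 21L, weighted = TRUE) {
  p <- coiled_coil_profile(seq, window, weighted)
  df <- tibble(position = seq_along(p), probability = as.numeric(p))
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$probability)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Residue", y = "Coiled-coil probability") +
    ggplot2::theme_minimal()
}
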