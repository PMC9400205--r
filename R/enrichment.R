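#' Hypergeometric gene-set enrichment with FDR correction
#'
#' For each functional category, tests over-representation of the
#' selected genes (e.g. genes overlapping candidate sweep regions)
#' against a background set: upper-tail hypergeometric
#' `p = P(X >= k)` with `k` selected genes in the category, `K`
#' background genes in the category, `n` selected genes and `N`
#' background genes in total, followed by Benjamini-Hochberg correction
#' across categories.
#'
#' @param selected Character vector of selected gene ids (subset of
#'   `background`).
#' @param background Character vector of background gene ids.
#' @param categories Tibble with columns `gene_id`, `category` (a gene
#'   may belong to several categories).
#' @return A tibble, one row per category present in the background:
#'   `category`, `k`, `K`, `n`, `N`, `p_value`, `fdr`, sorted by
#'   `p_value`.
#' @export
enrichment_test <- function(selected, background, categories) {
  background <- unique(background)
  selected <- unique(selected)
  if (length(background) == 0) abort("empty background gene set")
  if (!all(selected %in% background)) {
    abort("selected genes must be a subset of the background")
  }
  cats <- categories |>
    filter(.data$gene_id %in% background) |>
    dplyr::distinct(.data$gene_id, .data$category)
  if (nrow(cats) == 0) {
    return(tibble(category = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p_value = numeric(),
                  fdr = numeric()))
  }
  N <- length(background)
  n <- length(selected)
  out <- cats |>
    group_by(.data$category) |>
    summarise(K = dplyr::n_distinct(.data$gene_id),
              k = sum(unique(.data$gene_id) %in% selected),
              .groups = "drop") |>
    mutate(n = n, N = N,
           p_value = phyper(.data$k - 1, .data$K, .data$N - .data$K,
                            .data$n, lower.tail = FALSE))
  out |>
    mutate(fdr = p.adjust(.data$p_value, method = "BH")) |>
    select("category", "k", "K", "n", "N", "p_value", "fdr") |>
    arrange(.data$p_value)
}
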