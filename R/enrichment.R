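#' Hypergeometric upper-tail probability
#'
#' One-sided over-representation p-value: the probability of drawing at
#' least `k` category members when `n` proteins are sampled without
#' replacement from a background of `N` proteins of which `K` are in the
#' category. This is the p-value of the one-sided Fisher exact test on
#' the corresponding 2x2 table.
#'
#' @param k Observed overlap count(s).
#' @param n Selected-set size(s).
#' @param K Category size(s) in the background.
#' @param N Background size(s).
#' @return `P(X >= k)` under the hypergeometric null; vectorised.
#' @export
hyper_tail_p <- function(k, n, K, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fisher's exact category enrichment
#'
#' Tests each category for over-representation in a selected protein set
#' against a background set. The enrichment factor is the category
#' frequency in the selection over its frequency in the background,
#' `(k/n) / (K/N)`; a category is called significant when the factor
#' exceeds `ef_cutoff` and the exact p-value is below `p_cutoff`
#' (defaults 2 and 0.05).
#'
#' @param selected Character vector of selected protein ids (e.g. the
#'   final proximal set), a subset of `background`.
#' @param background Character vector of background protein ids
#'   (typically the presence-filtered detected set).
#' @param category_map data.frame with columns `protein_id` and
#'   `category` (a protein may carry several rows), or a named list of
#'   category vectors per protein.
#' @param ef_cutoff,p_cutoff Significance cutoffs.
#' @return A data.frame of class `EnrichmentResult` with one row per
#'   category having at least one background member, sorted by p-value:
#'   `category`, `k`, `n`, `K`, `N`, `enrichment_factor`, `p_value`,
#'   `significant`.
#' @export
fisher_enrichment <- function(selected, background, category_map,
                              ef_cutoff = 2, p_cutoff = 0.05) {
  selected <- unique(as.character(selected))
  background <- unique(as.character(background))
  extra <- setdiff(selected, background)
  if (length(extra) > 0L)
    stop("selected proteins not in background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  if (is.list(category_map) && !is.data.frame(category_map)) {
    category_map <- data.frame(
      protein_id = rep(names(category_map),
                       lengths(category_map)),
      category = unlist(category_map, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  category_map <- category_map[category_map$protein_id %in% background, ,
                               drop = FALSE]
  category_map <- unique(category_map[, c("protein_id", "category")])
  N <- length(background)
  n <- length(selected)
  cats <- sort(unique(category_map$category))
  res <- lapply(cats, function(cat) {
    members <- category_map$protein_id[category_map$category == cat]
    K <- length(members)
    k <- sum(members %in% selected)
    ef <- if (K == 0L || n == 0L) NA_real_ else (k / n) / (K / N)
    data.frame(category = cat, k = k, n = n, K = K, N = N,
               enrichment_factor = ef,
               p_value = hyper_tail_p(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(category = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(),
                      enrichment_factor = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  out$significant <- !is.na(out$enrichment_factor) &
    out$enrichment_factor > ef_cutoff & out$p_value < p_cutoff
  out <- out[order(out$p_value, out$category), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Read a protein-to-category table
#'
#' Tab-delimited columns `protein_id`, `category`, and optionally
#' `source` (e.g. GOBP / GOCC / GOMF / CyanoBase / custom).
#'
#' @param path Path to the category file.
#' @param sources Optional filter on the `source` column.
#' @return data.frame with columns `protein_id`, `category` (and
#'   `source` when present).
#' @export
read_categories <- function(path, sources = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("protein_id", "category")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop("category file is missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(sources) && "source" %in% names(tab))
    tab <- tab[tab$source %in% sources, , drop = FALSE]
  tab
}
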