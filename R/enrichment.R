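KINGDOMS <- c("Eukaryota", "Archaea", "Viruses", "Bacteria")

#' Tally source-organism kingdoms of template chains
#'
#' Counts, with multiplicity, how many chains in a chain usage set come from
#' each kingdom. Microbial = Viruses + Bacteria. Chains with an unknown
#' organism are excluded from the total and reported separately.
#'
#' @param chains A tibble (`template_id`, `chain`) of chain usages (rows may
#'   repeat when the same template chain is used for several models), or a
#'   character vector of `"<template_id>:<chain>"` keys.
#' @param organism_index A tibble (`template_id`, `chain`, `kingdom`).
#' @return A tibble of class `organism_tally` with one row per kingdom plus
#'   `Microbial (Viruses+Bacteria)` and `Total`; attribute `n_unknown`.
#' @export
tally_organisms <- function(chains, organism_index) {
  if (is.character(chains)) {
    parts <- stringr::str_split_fixed(chains, ":", 2)
    chains <- tibble(template_id = parts[, 1], chain = parts[, 2])
  }
  chains <- as_tibble(chains)
  joined <- chains |>
    left_join(organism_index |> select("template_id", "chain", "kingdom"),
              by = c("template_id", "chain"))
  unknown <- sum(is.na(joined$kingdom) | !(joined$kingdom %in% KINGDOMS))
  if (unknown > 0) {
    inform(sprintf("tally_organisms: %d chain(s) with unknown organism excluded", unknown))
  }
  known <- joined |> filter(.data$kingdom %in% KINGDOMS)
  counts <- table(factor(known$kingdom, levels = KINGDOMS))
  out <- tibble(
    group = c(KINGDOMS, "Microbial (Viruses+Bacteria)", "Total"),
    count = c(as.integer(counts),
              as.integer(counts[["Viruses"]] + counts[["Bacteria"]]),
              as.integer(sum(counts)))
  )
  structure(out, class = c("organism_tally", class(out)), n_unknown = unknown)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' `k` or more marked items in `n` draws without replacement from a
#' population of `N` items of which `K` are marked. Computed in log space
#' from the exact point masses.
#'
#' @param k Observed count of marked draws.
#' @param n Number of draws.
#' @param K Number of marked items in the population.
#' @param N Population size.
#' @return The upper-tail probability.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > n || n > N || K > N) {
    abort("invalid margins: need 0 <= k <= n <= N and 0 <= K <= N")
  }
  if (k == 0) return(1)
  support <- seq(k, min(n, K))
  if (length(support) == 0) return(0)
  lp <- dhyper(support, m = K, n = N - K, k = n, log = TRUE)
  mx <- max(lp)
  exp(mx + log(sum(exp(lp - mx))))
}

#' Template usage statistics
#'
#' The average template-interface frequency: number of model predictions
#' divided by the number of distinct template interfaces used.
#'
#' @param models A model table with a `template_id` column, or a list with
#'   numeric `n_predictions` and `n_distinct_templates`.
#' @return A tibble (`n_predictions`, `n_distinct_templates`,
#'   `avg_frequency`), the frequency reported to two decimals.
#' @export
template_usage_stats <- function(models) {
  if (is.data.frame(models)) {
    if (nrow(models) == 0) abort("empty model table")
    n_pred <- nrow(models)
    n_templ <- length(unique(models$template_id))
  } else {
    n_pred <- models$n_predictions
    n_templ <- models$n_distinct_templates
  }
  tibble(n_predictions = n_pred, n_distinct_templates = n_templ,
         avg_frequency = round(n_pred / n_templ, 2))
}

#' Gene-set term enrichment with step-down correction
#'
#' Right-sided hypergeometric test per term: the probability of observing at
#' least the seen overlap between the query and the term, drawing the query
#' from the background. P-values are adjusted by the Bonferroni step-down
#' (Holm) procedure over all tested terms by default.
#'
#' @param query Character vector of query genes (must lie in `background`).
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]); each set is intersected with the background.
#' @param background Character vector: the gene universe.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param adjust `"holm"` (Bonferroni step-down, default) or `"bonferroni"`.
#' @return A tibble (`term`, `k`, `n`, `K`, `N`, `p`, `p_adjusted`,
#'   `significant`), ordered by raw p.
#' @export
term_enrichment <- function(query, gene_sets, background, alpha = 0.05,
                            adjust = c("holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  query <- unique(query)
  background <- unique(background)
  if (length(query) == 0) abort("empty query")
  stray <- setdiff(query, background)
  if (length(stray) > 0) {
    abort(paste0("query gene(s) not in background: ",
                 paste(head(stray, 5), collapse = ", ")))
  }
  N <- length(background)
  n <- length(query)
  res <- imap(gene_sets, function(genes, term) {
    set <- intersect(unique(genes), background)
    K <- length(set)
    k <- length(intersect(query, set))
    tibble(term = term, k = k, n = n, K = K, N = N,
           p = hypergeom_upper_tail(k, n, K, N))
  }) |> bind_rows()
  res |>
    mutate(p_adjusted = p.adjust(.data$p, method = adjust),
           significant = .data$p_adjusted < alpha) |>
    arrange(.data$p, .data$term)
}

#' Two-tailed Fisher exact test on a 2 x 2 table
#'
#' Conditional exact test: with all margins fixed, the two-tailed p-value is
#' the sum of hypergeometric point probabilities of all tables at most as
#' probable as the observed one (with the customary relative tolerance on
#' the comparison). The odds ratio is the sample odds ratio `ad / bc`; a
#' zero cell makes it 0 or infinite and is flagged.
#'
#' @param tab A 2 x 2 matrix or data frame of non-negative counts.
#' @return A tibble (`odds_ratio`, `p`, `zero_cell`).
#' @export
fisher_two_tailed <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    abort("`tab` must be a 2 x 2 table of non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("zero row or column margin")
  }
  a <- tab[1, 1]
  m <- sum(tab[1, ])          # row-1 margin
  K <- sum(tab[, 1])          # column-1 margin
  N <- sum(tab)
  support <- max(0, K + m - N):min(m, K)
  pmass <- dhyper(support, m = K, n = N - K, k = m)
  obs <- dhyper(a, m = K, n = N - K, k = m)
  p <- min(1, sum(pmass[pmass <= obs * (1 + 1e-7)]))
  zero <- any(tab == 0)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (zero) inform("fisher_two_tailed: zero cell, odds ratio degenerate")
  tibble(odds_ratio = or, p = p, zero_cell = zero)
}

#' Read gene sets in GMT format
#'
#' Each line: term, description, then member genes, tab-separated.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(map(parts, ~ unique(.x[-(1:2)])), map_chr(parts, 1))
}

#' Write gene sets in GMT format
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- imap_chr(gene_sets, function(genes, term) {
    paste(c(term, term, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}
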