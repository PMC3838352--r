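#' Resolve a seed list against a network
#'
#' Seeds may be given as unified node ids, gene identifiers or UniProt
#' accessions; each is matched against the node table in that order of
#' precedence. Unresolved seeds are reported with a warning, never silently
#' dropped.
#'
#' @param net A [ppi_network].
#' @param seeds Character vector of seed identifiers, or a one-column data
#'   frame of them.
#' @return A list with `node_ids` (resolved unified ids) and `unresolved`
#'   (input identifiers that matched nothing).
#' @export
resolve_seeds <- function(net, seeds) {
  stopifnot(inherits(net, "ppi_network"))
  if (is.data.frame(seeds)) seeds <- seeds[[1]]
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0) abort("seed set is empty")
  nodes <- net$nodes
  split_col <- function(col) {
    if (!col %in% names(nodes)) return(vector("list", nrow(nodes)))
    strsplit(ifelse(is.na(nodes[[col]]), "", nodes[[col]]), ";", fixed = TRUE)
  }
  genes <- split_col("gene_ids")
  accs <- split_col("accessions")
  hit <- map_chr(seeds, function(s) {
    i <- which(nodes$node_id == s)
    if (length(i) == 0) i <- which(map_lgl(genes, ~ s %in% .x))
    if (length(i) == 0) i <- which(map_lgl(accs, ~ s %in% .x))
    if (length(i) == 0) NA_character_ else nodes$node_id[min(i)]
  })
  unresolved <- seeds[is.na(hit)]
  if (length(unresolved) > 0) {
    warn(paste0("unresolved seed(s): ", paste(unresolved, collapse = ", ")))
  }
  list(node_ids = unique(hit[!is.na(hit)]), unresolved = unresolved)
}

node_scores <- function(net, score, seed_ids, method, unresolved = character()) {
  out <- tibble(node_id = net$nodes$node_id,
                score = unname(score[net$nodes$node_id]),
                is_seed = net$nodes$node_id %in% seed_ids)
  structure(out, class = c("node_scores", class(out)),
            method = method, unresolved = unresolved)
}

#' @export
print.node_scores <- function(x, ...) {
  cat(sprintf("<node_scores> method = %s, %d nodes (%d seeds)\n",
              attr(x, "method"), nrow(x), sum(x$is_seed)))
  NextMethod()
}

# min-max normalization to [0,1]; a flat score vector maps to 1.0 everywhere
minmax <- function(x, context = "scores") {
  rng <- range(x)
  if (!all(is.finite(rng))) abort("non-finite scores before normalization")
  if (rng[1] == rng[2]) {
    warn(paste0("degenerate ", context, ": all values equal; normalized to 1"))
    return(rep(1, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

net_setup <- function(net, seeds) {
  res <- resolve_seeds(net, seeds)
  g <- as_igraph(net)
  list(g = g, ids = igraph::V(g)$name, seed_ids = res$node_ids,
       unresolved = res$unresolved)
}

# one neighbour-averaging pass used by netscore and netzcore
propagate_once <- function(g, s) {
  adj <- igraph::as_adj_list(g, mode = "all")
  vapply(adj, function(nb) if (length(nb) == 0) 0 else mean(s[nb]),
         numeric(1))
}

#' Score nodes by iterative message passing from seeds (NetScore-style)
#'
#' Seeds start at `seed_score`, everything else at `nonseed_score`. Within a
#' repetition the score field relaxes for `n_iterations` steps of
#' `s <- (s + neighbour mean of s) / 2`; at the end of each repetition the
#' seeds are re-initialized to `seed_score`, so seed identity is never washed
#' out. The final field is min-max normalized to \[0, 1\].
#'
#' @param net A [ppi_network].
#' @param seeds Seed identifiers (see [resolve_seeds()]).
#' @param n_repetitions,n_iterations Positive integers; defaults 3 and 2.
#' @param seed_score,nonseed_score Initial scores (defaults 1 and 0.01).
#' @return A `node_scores` tibble (`node_id`, `score`, `is_seed`).
#' @export
netscore <- function(net, seeds, n_repetitions = 3, n_iterations = 2,
                     seed_score = 1, nonseed_score = 0.01) {
  stopifnot(n_repetitions >= 1, n_iterations >= 1)
  st <- net_setup(net, seeds)
  if (length(st$seed_ids) == 0) abort("no seed resolved to a network node")
  s <- setNames(rep(nonseed_score, length(st$ids)), st$ids)
  for (rep_i in seq_len(n_repetitions)) {
    s[st$seed_ids] <- seed_score
    for (it in seq_len(n_iterations)) {
      s <- (s + propagate_once(st$g, s)) / 2
    }
  }
  s[st$seed_ids] <- seed_score
  node_scores(net, setNames(minmax(s), names(s)), st$seed_ids,
              "netscore", st$unresolved)
}

#' Score nodes by z-scores against degree-preserving random networks
#' (NetZcore-style)
#'
#' Runs one neighbour-averaging propagation pass on the real network and the
#' same pass on `n_random_networks` degree-preserving randomizations (edge
#' swaps, 10 x |E| attempted swaps each). Each node's score is the z-score of
#' its real propagated value against the randomized mean and standard
#' deviation; nodes with zero variance across randomizations get z = 0.
#' Results are min-max normalized and fully reproducible for a given
#' `rng_seed`.
#'
#' @inheritParams netscore
#' @param n_random_networks Number of randomized replicates (>= 10).
#' @param rng_seed Integer seed governing the randomizations.
#' @return A `node_scores` tibble.
#' @export
netzcore <- function(net, seeds, n_random_networks = 100, rng_seed = 1,
                     seed_score = 1, nonseed_score = 0.01) {
  stopifnot(n_random_networks >= 10)
  st <- net_setup(net, seeds)
  if (length(st$seed_ids) == 0) abort("no seed resolved to a network node")
  s0 <- setNames(rep(nonseed_score, length(st$ids)), st$ids)
  s0[st$seed_ids] <- seed_score
  real <- propagate_once(st$g, s0)

  n_swaps <- max(1L, 10L * igraph::ecount(st$g))
  rand <- with_rng_seed(rng_seed, {
    vapply(seq_len(n_random_networks), function(i) {
      gr <- igraph::rewire(st$g, igraph::keeping_degseq(niter = n_swaps))
      propagate_once(gr, s0)
    }, numeric(length(s0)))
  })
  mu <- rowMeans(rand)
  sdv <- apply(rand, 1, sd)
  z <- ifelse(sdv > 0, (real - mu) / sdv, 0)
  if (any(sdv == 0)) {
    inform(sprintf("netzcore: %d node(s) had zero variance across randomizations; z set to 0",
                   sum(sdv == 0)))
  }
  node_scores(net, setNames(minmax(z), st$ids), st$seed_ids,
              "netzcore", st$unresolved)
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Score nodes by seed-aware shortest paths (NetShort-style)
#'
#' Edges through seed neighbourhoods are shortened: the length of edge (u, v)
#' is `1 / (1 + seed(u) + seed(v))` with `seed()` the 0/1 seed indicator.
#' Each node's raw score is `1 / (1 + mean squared weighted distance to the
#' seeds)`, so nodes centrally placed among the seeds outrank peripheral ones;
#' distances to unreachable seeds are set to the largest finite distance + 1.
#' Scores are min-max normalized.
#'
#' @inheritParams netscore
#' @return A `node_scores` tibble.
#' @export
netshort <- function(net, seeds) {
  st <- net_setup(net, seeds)
  if (length(st$seed_ids) == 0) {
    warn("no resolved seeds: netshort scores are uniform")
    return(node_scores(net, setNames(rep(1, length(st$ids)), st$ids),
                       character(), "netshort", st$unresolved))
  }
  ind <- setNames(as.numeric(st$ids %in% st$seed_ids), st$ids)
  ends <- igraph::ends(st$g, igraph::E(st$g))
  w <- 1 / (1 + ind[ends[, 1]] + ind[ends[, 2]])
  d <- igraph::distances(st$g, to = st$seed_ids, weights = w)
  finite <- d[is.finite(d)]
  cap <- if (length(finite) > 0) max(finite) + 1 else 1
  d[!is.finite(d)] <- cap
  raw <- 1 / (1 + rowMeans(d^2))
  node_scores(net, setNames(minmax(raw), st$ids), st$seed_ids,
              "netshort", st$unresolved)
}

#' Consensus prioritization combining NetScore, NetZcore and NetShort
#'
#' Each component score vector is standardized (z-score over nodes), the
#' three standardized vectors are averaged, and the average is min-max
#' normalized to \[0, 1\]. Standardization puts the three methods, whose raw
#' scales are not comparable, on an equal footing before averaging.
#'
#' @inheritParams netzcore
#' @param n_repetitions,n_iterations NetScore parameters.
#' @param n_random_networks NetZcore randomization count.
#' @return A `node_scores` tibble with method `"netcombo"`.
#' @export
netcombo <- function(net, seeds, n_repetitions = 3, n_iterations = 2,
                     n_random_networks = 100, rng_seed = 1) {
  parts <- list(
    netscore(net, seeds, n_repetitions, n_iterations),
    netzcore(net, seeds, n_random_networks, rng_seed),
    netshort(net, seeds)
  )
  zstd <- function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  combined <- rowMeans(vapply(parts, function(p) zstd(p$score),
                              numeric(nrow(parts[[1]]))))
  seed_ids <- parts[[1]]$node_id[parts[[1]]$is_seed]
  node_scores(net, setNames(minmax(combined), parts[[1]]$node_id), seed_ids,
              "netcombo", attr(parts[[1]], "unresolved"))
}

#' Transfer node scores to edges
#'
#' The score of an edge is exactly the arithmetic mean of its two endpoint
#' scores.
#'
#' @param net A [ppi_network].
#' @param scores A `node_scores` tibble covering every node of `net`.
#' @return A tibble (`from`, `to`, `score`) of class `edge_scores`.
#' @export
score_edges <- function(net, scores) {
  s <- setNames(scores$score, scores$node_id)
  missing <- setdiff(c(net$edges$from, net$edges$to), names(s))
  if (length(missing) > 0) {
    abort(paste0("unscored edge endpoint(s): ", paste(head(missing, 5), collapse = ", ")))
  }
  out <- net$edges |>
    mutate(score = unname(s[.data$from] + s[.data$to]) / 2) |>
    select("from", "to", "score")
  structure(out, class = c("edge_scores", class(out)))
}

#' Scan edge-score cutoffs
#'
#' For each cutoff, counts the edges whose score exceeds the cutoff (strict
#' inequality) and the nodes those edges touch. Used to pick a common cutoff
#' that yields sub-networks of comparable size.
#'
#' @param edge_scores Output of [score_edges()].
#' @param grid Ascending numeric vector of cutoffs.
#' @return A tibble (`cutoff`, `n_edges`, `n_nodes`) of class
#'   `threshold_curve`; both counts are non-increasing in the cutoff.
#' @export
threshold_scan <- function(edge_scores, grid) {
  if (is.unsorted(grid)) abort("`grid` must be sorted ascending")
  out <- tibble(
    cutoff = grid,
    n_edges = map_int(grid, ~ sum(edge_scores$score > .x)),
    n_nodes = map_int(grid, function(ct) {
      kept <- edge_scores |> filter(.data$score > ct)
      length(unique(c(kept$from, kept$to)))
    })
  )
  structure(out, class = c("threshold_curve", class(out)))
}

#' Extract the sub-network above an edge-score cutoff
#'
#' Keeps edges with score strictly greater than `cutoff` and only the nodes
#' those edges touch.
#'
#' @param net A [ppi_network].
#' @param edge_scores Output of [score_edges()].
#' @param cutoff Edge-score cutoff in \[0, 1\]; the field default elsewhere in
#'   the pipeline is 0.178.
#' @return A [ppi_network].
#' @export
extract_subnetwork <- function(net, edge_scores, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  kept <- edge_scores |> filter(.data$score > cutoff)
  if (nrow(kept) == 0) warn("no edge exceeds the cutoff: empty sub-network")
  keep_nodes <- unique(c(kept$from, kept$to))
  out <- ppi_network(
    net$nodes |> filter(.data$node_id %in% keep_nodes),
    net$edges |>
      inner_join(kept |> select("from", "to", "score"), by = c("from", "to"))
  )
  out$log <- c(net$log, list(cutoff = cutoff))
  out
}

#' Find hub nodes
#'
#' Hubs are nodes with degree at or above `min_degree` (default 12).
#'
#' @param net A [ppi_network].
#' @param min_degree Degree threshold, inclusive.
#' @return Character vector of hub node ids.
#' @export
find_hubs <- function(net, min_degree = 12) {
  deg <- igraph::degree(as_igraph(net))
  sort(names(deg)[deg >= min_degree])
}

#' Average node degree of a network
#'
#' `2 |E| / |V|`, reported to one decimal place.
#'
#' @param net A [ppi_network], or a list with numeric `n_nodes`/`n_edges`.
#' @return A number rounded to one decimal.
#' @export
average_degree <- function(net) {
  if (inherits(net, "ppi_network")) {
    n <- nrow(net$nodes); e <- nrow(net$edges)
  } else {
    n <- net$n_nodes; e <- net$n_edges
  }
  if (n == 0) abort("empty network")
  round(2 * e / n, 1)
}
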