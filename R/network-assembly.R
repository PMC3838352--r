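#' Protein-protein interaction network container
#'
#' A `ppi_network` bundles a node table and an edge table. Nodes carry at
#' least a `node_id` column; edges carry `from` and `to` columns referring to
#' node ids, stored in canonical order (`from < to`), with no self loops and
#' no duplicate pairs. Extra columns (merged identifiers, provenance, scores)
#' travel with the tables.
#'
#' @param nodes A data frame with at least a `node_id` column.
#' @param edges A data frame with at least `from` and `to` columns.
#' @return An object of class `ppi_network`: a list with elements `nodes` and
#'   `edges` (both tibbles) and `log` (a list of bookkeeping counts).
#' @export
ppi_network <- function(nodes, edges) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  if (!"node_id" %in% names(nodes)) abort("`nodes` must have a `node_id` column")
  if (!all(c("from", "to") %in% names(edges))) {
    abort("`edges` must have `from` and `to` columns")
  }
  if (anyDuplicated(nodes$node_id) > 0) abort("duplicate node ids")
  edges <- canonicalize_edges(edges)
  missing <- setdiff(c(edges$from, edges$to), nodes$node_id)
  if (length(missing) > 0) {
    abort(paste0("edge endpoint(s) not in node table: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  structure(list(nodes = nodes, edges = edges, log = list()),
            class = "ppi_network")
}

# order endpoints, drop self loops and duplicates; provenance-free variant
canonicalize_edges <- function(edges) {
  if (nrow(edges) == 0) return(as_tibble(edges))
  edges |>
    mutate(.a = pmin(.data$from, .data$to), .b = pmax(.data$from, .data$to)) |>
    mutate(from = .data$.a, to = .data$.b) |>
    select(-".a", -".b") |>
    filter(.data$from != .data$to) |>
    distinct(.data$from, .data$to, .keep_all = TRUE) |>
    arrange(.data$from, .data$to)
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                directed = FALSE,
                                vertices = net$nodes["node_id"])
}

#' Unify protein records across source databases
#'
#' Partitions protein records into unified nodes: two records belong to the
#' same node if they are linked, directly or transitively, by sharing a
#' UniProt accession, an identical amino-acid sequence, or a gene identifier.
#' The partition is the transitive closure over the three equivalence keys
#' and does not depend on the order of the input rows.
#'
#' @param records A data frame with columns `source_db`, `local_id`,
#'   `uniprot_accessions` (";"-separated, may be empty), `sequence` (may be
#'   empty) and `gene_id` (may be empty). Each record needs at least one
#'   non-empty key among accessions, sequence and gene id.
#' @return The input tibble with two added columns: `node_id` (the unified
#'   node each record belongs to) and `record_key`
#'   (`source_db:local_id`, unique per record).
#' @export
unify_proteins <- function(records) {
  records <- as_tibble(records)
  needed <- c("source_db", "local_id", "uniprot_accessions", "sequence", "gene_id")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0("records are missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(records) == 0) abort("`records` is empty")
  records <- records |>
    mutate(across(all_of(needed), ~ ifelse(is.na(.x), "", as.character(.x))),
           sequence = toupper(gsub("[[:space:]]", "", .data$sequence)),
           record_key = paste(.data$source_db, .data$local_id, sep = ":"))
  if (anyDuplicated(records$record_key) > 0) {
    abort("duplicate (source_db, local_id) record keys")
  }
  bad_seq <- records$sequence != "" &
    !grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", records$sequence)
  if (any(bad_seq)) {
    abort(paste0("invalid amino-acid sequence in record(s): ",
                 paste(head(records$record_key[bad_seq], 5), collapse = ", ")))
  }

  acc_list <- strsplit(records$uniprot_accessions, ";", fixed = TRUE)
  acc_list <- map(acc_list, ~ unique(.x[nzchar(.x)]))
  empty <- lengths(acc_list) == 0 & records$sequence == "" & records$gene_id == ""
  if (any(empty)) {
    abort(paste0("record(s) with no identifier key: ",
                 paste(records$record_key[empty], collapse = ", ")))
  }

  # bipartite record--key graph; connected components give the partition
  key_edges <- bind_rows(
    tibble(rec = rep(records$record_key, lengths(acc_list)),
           key = paste0("acc:", unlist(acc_list))),
    records |> filter(nzchar(.data$sequence)) |>
      transmute(rec = .data$record_key, key = paste0("seq:", .data$sequence)),
    records |> filter(nzchar(.data$gene_id)) |>
      transmute(rec = .data$record_key, key = paste0("gene:", .data$gene_id))
  )
  g <- igraph::graph_from_data_frame(
    key_edges,
    directed = FALSE,
    vertices = tibble(name = unique(c(records$record_key, key_edges$key)))
  )
  comp <- igraph::components(g)$membership
  records$.comp <- comp[records$record_key]

  records |>
    mutate(.acc = acc_list) |>
    group_by(.data$.comp) |>
    mutate(node_id = unified_node_id(unlist(.data$.acc), .data$gene_id,
                                     .data$record_key)) |>
    ungroup() |>
    select(-".comp", -".acc")
}

# deterministic node label: smallest accession, else smallest gene id,
# else smallest record key
unified_node_id <- function(accs, gene_ids, record_keys) {
  accs <- accs[nzchar(accs)]
  gene_ids <- gene_ids[nzchar(gene_ids)]
  if (length(accs) > 0) return(min(accs))
  if (length(gene_ids) > 0) return(paste0("gene:", min(gene_ids)))
  min(record_keys)
}

#' Build a unified interaction network from source interaction tables
#'
#' Maps each interaction's endpoints through the record partition produced by
#' [unify_proteins()], drops pairs that collapse onto a single unified node
#' (self interactions after unification), and deduplicates edges across
#' sources while keeping their provenance.
#'
#' @param interactions A data frame with columns `source_db`, `local_id_a`,
#'   `local_id_b`.
#' @param partition The output of [unify_proteins()].
#' @return A [ppi_network]. The node table aggregates the merged identifier
#'   sets per node; `log` records `n_input_pairs`, `n_self_dropped` and
#'   `n_duplicates_merged`.
#' @export
build_network <- function(interactions, partition) {
  interactions <- as_tibble(interactions)
  needed <- c("source_db", "local_id_a", "local_id_b")
  if (!all(needed %in% names(interactions))) {
    abort("interactions need columns source_db, local_id_a, local_id_b")
  }
  lookup <- setNames(partition$node_id, partition$record_key)
  key_a <- paste(interactions$source_db, interactions$local_id_a, sep = ":")
  key_b <- paste(interactions$source_db, interactions$local_id_b, sep = ":")
  unknown <- unique(c(key_a[!key_a %in% names(lookup)],
                      key_b[!key_b %in% names(lookup)]))
  if (length(unknown) > 0) {
    abort(paste0("interaction endpoint(s) with no protein record: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }

  mapped <- tibble(from = unname(lookup[key_a]), to = unname(lookup[key_b]),
                   source_db = interactions$source_db) |>
    mutate(.a = pmin(.data$from, .data$to), .b = pmax(.data$from, .data$to),
           from = .data$.a, to = .data$.b) |>
    select(-".a", -".b")
  n_self <- sum(mapped$from == mapped$to)
  mapped <- filter(mapped, .data$from != .data$to)
  edges <- mapped |>
    group_by(.data$from, .data$to) |>
    summarise(sources = paste(sort(unique(.data$source_db)), collapse = ";"),
              .groups = "drop") |>
    arrange(.data$from, .data$to)

  nodes <- partition |>
    group_by(.data$node_id) |>
    summarise(
      accessions = merge_ids(.data$uniprot_accessions),
      gene_ids = merge_ids(.data$gene_id),
      members = paste(sort(.data$record_key), collapse = ";"),
      n_records = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(.data$node_id)

  net <- ppi_network(nodes, edges)
  net$log <- list(n_input_pairs = nrow(interactions),
                  n_self_dropped = n_self,
                  n_duplicates_merged = nrow(mapped) - nrow(edges))
  net
}

merge_ids <- function(x) {
  ids <- unique(unlist(strsplit(x[nzchar(x)], ";", fixed = TRUE)))
  paste(sort(ids[nzchar(ids)]), collapse = ";")
}

#' Extract the major connected component of a network
#'
#' Returns the connected component with the most nodes. If several components
#' tie on size, the one containing the lexicographically smallest node id is
#' returned, so the result is deterministic.
#'
#' @param net A [ppi_network].
#' @return A [ppi_network] restricted to the major component.
#' @export
major_component <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  if (nrow(net$nodes) == 0) abort("network has no nodes")
  g <- as_igraph(net)
  comp <- igraph::components(g)
  membership <- comp$membership[net$nodes$node_id]
  sizes <- tabulate(membership, nbins = comp$no)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # tie: component holding the smallest node id among tied components
    tied_nodes <- net$nodes$node_id[membership %in% best]
    best <- membership[[min(tied_nodes)]]
  }
  keep <- net$nodes$node_id[membership == best]
  subset_network(net, keep)
}

subset_network <- function(net, node_ids) {
  out <- ppi_network(
    net$nodes |> filter(.data$node_id %in% node_ids),
    net$edges |> filter(.data$from %in% node_ids & .data$to %in% node_ids)
  )
  out$log <- net$log
  out
}

#' Read the tab-separated protein and interaction tables
#'
#' @param path Path to a tab-separated file. Protein tables carry columns
#'   `source_db`, `local_id`, `uniprot_accessions`, `sequence`, `gene_id`;
#'   interaction tables carry `source_db`, `local_id_a`, `local_id_b`.
#' @return A tibble.
#' @export
read_protein_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = character()) |>
    mutate(across(everything(), ~ tidyr::replace_na(.x, "")))
}

#' @rdname read_protein_table
#' @export
read_interaction_table <- read_protein_table

#' Write a network's node and edge tables
#'
#' Writes `<prefix>_nodes.tsv`, `<prefix>_edges.tsv` and a JSON run summary
#' `<prefix>_summary.json` with the bookkeeping counts from assembly.
#'
#' @param net A [ppi_network].
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "ppi_network"))
  paths <- paste0(prefix, c("_nodes.tsv", "_edges.tsv", "_summary.json"))
  readr::write_tsv(net$nodes, paths[1])
  readr::write_tsv(net$edges, paths[2])
  summary <- c(net$log, list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges)))
  jsonlite::write_json(summary, paths[3], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
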