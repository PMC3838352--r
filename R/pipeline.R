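#' Default pipeline configuration
#'
#' All tunable constants of the pipeline in one named list: network and
#' module simulation sizes, propagation parameters, the edge-score cutoff
#' (0.178) and hub degree (12), structural thresholds (5.0 A interface
#' contact, TM > 0.5 / RMSD < 2.5 A redundancy, 2.0 A / 50% template-match
#' acceptance, energy < 0), accessibility settings (1.4 A probe, 5% core
#' cutoff) and the 0.05 significance level.
#'
#' @return A named list of parameters.
#' @export
default_config <- function() {
  list(
    rng_seed = 1,
    n_nodes = 500, attachment = 2, module_size = 20, enrichment_factor = 8,
    n_repetitions = 3, n_iterations = 2, n_random_networks = 100,
    edge_cutoff = 0.178, hub_min_degree = 12,
    n_templates = 6, microbial_fraction = 4918 / 11255, template_n_res = 30,
    n_model_pairs = 4, target_noise_sd = 0.3,
    contact_cutoff = 5.0, match_rmsd_cutoff = 2.0, match_min_coverage = 0.5,
    energy_cutoff = 0,
    probe_radius = 1.4, asa_points = 480, core_threshold = 5,
    n_variants = 200,
    variant_probs = c(core = 0.35, surface = 0.58, interface = 0.07),
    n_gene_sets = 10, alpha = 0.05,
    report_digits = 4
  )
}

validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  config <- modifyList(base, config)
  if (config$edge_cutoff < 0 || config$edge_cutoff > 1) {
    abort("edge_cutoff must lie in [0, 1]")
  }
  if (config$alpha <= 0 || config$alpha >= 1) abort("alpha must lie in (0, 1)")
  config
}

#' Run the full synthetic pipeline
#'
#' Executes every stage in dependency order on synthetic inputs: network
#' generation with a planted module, consensus prioritization and
#' sub-network extraction, template-based complex modelling with energy
#' filtering, source-organism and term-enrichment statistics, and variant
#' location mapping with the Fisher preference test. All stage outputs are
#' written as tab-separated tables under `out_dir` together with a JSON
#' manifest recording parameters, seeds and output checksums.
#'
#' @param config A named list overriding entries of [default_config()], or a
#'   path to a YAML file of such overrides.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading a YAML config requires the yaml package")
    }
    config <- yaml::read_yaml(config)
    if (!is.null(config$variant_probs)) {
      config$variant_probs <- unlist(config$variant_probs)
    }
  }
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, paste0(name, ".tsv")))
    paste0(name, ".tsv")
  }
  outputs <- character(0)

  # --- network + prioritization -------------------------------------------
  sim <- gen_network(cfg$n_nodes, cfg$attachment, cfg$module_size,
                     cfg$enrichment_factor, cfg$rng_seed)
  net <- major_component(sim$network)
  seeds_in <- intersect(sim$seeds, net$nodes$node_id)
  scores <- netcombo(net, seeds_in, cfg$n_repetitions, cfg$n_iterations,
                     cfg$n_random_networks, cfg$rng_seed)
  escores <- score_edges(net, scores)
  curve <- threshold_scan(escores, seq(0, 1, by = 0.02))
  subnet <- extract_subnetwork(net, escores, cfg$edge_cutoff)
  hubs <- find_hubs(subnet, cfg$hub_min_degree)
  outputs <- c(outputs, tsv(tidy(scores), "node_scores"),
               tsv(escores, "edge_scores"), tsv(curve, "threshold_curve"),
               tsv(subnet$edges, "subnetwork_edges"),
               tsv(tibble(node_id = hubs), "hubs"))

  # --- structural overlay --------------------------------------------------
  lib <- gen_template_library(cfg$n_templates, cfg$microbial_fraction,
                              cfg$rng_seed, n_res = cfg$template_n_res)
  pairs <- escores |> arrange(desc(.data$score)) |> head(cfg$n_model_pairs)
  models <- list()
  used_chains <- tibble(template_id = character(), chain = character())
  with_rng_seed(cfg$rng_seed + 1, {
    for (k in seq_len(nrow(pairs))) {
      tmpl_id <- names(lib$templates)[(k - 1) %% length(lib$templates) + 1]
      tmpl <- template_interface(lib$templates[[tmpl_id]]$atoms, tmpl_id,
                                 lib$index, cfg$contact_cutoff)
      noisy <- function(chain_id) {
        at <- lib$templates[[tmpl_id]]$atoms |> filter(.data$chain == chain_id)
        at |> mutate(x = .data$x + stats::rnorm(dplyr::n(), 0, cfg$target_noise_sd),
                     y = .data$y + stats::rnorm(dplyr::n(), 0, cfg$target_noise_sd),
                     z = .data$z + stats::rnorm(dplyr::n(), 0, cfg$target_noise_sd))
      }
      t1 <- noisy("A"); t2 <- noisy("B")
      m1 <- match_template(tmpl, 1, t1, rmsd_cutoff = cfg$match_rmsd_cutoff,
                           min_coverage = cfg$match_min_coverage)
      m2 <- match_template(tmpl, 2, t2, rmsd_cutoff = cfg$match_rmsd_cutoff,
                           min_coverage = cfg$match_min_coverage)
      if (is.null(m1) || is.null(m2)) next
      mdl <- build_model(tmpl, m1, m2, t1, t2,
                         pair = c(pairs$from[k], pairs$to[k]))
      models[[length(models) + 1]] <- score_energy(mdl)
      used_chains <- bind_rows(used_chains,
                               tibble(template_id = tmpl_id, chain = c("A", "B")))
    }
  })
  mtable <- if (length(models) > 0) model_table(models) else
    tibble(pair_id = character(), template_id = character(),
           accepted = logical(), energy = numeric())
  best <- select_best_models(mtable, cfg$energy_cutoff)
  usage <- if (nrow(best) > 0) template_usage_stats(best) else
    tibble(n_predictions = 0, n_distinct_templates = 0, avg_frequency = NA_real_)
  outputs <- c(outputs, tsv(mtable, "models"), tsv(best, "best_models"),
               tsv(usage, "template_usage"))

  # --- organism composition ------------------------------------------------
  tally <- tally_organisms(used_chains, lib$index)
  k_mic <- tally$count[tally$group == "Microbial (Viruses+Bacteria)"]
  n_tot <- tally$count[tally$group == "Total"]
  bg <- tally_organisms(lib$index |> select("template_id", "chain"), lib$index)
  K_mic <- bg$count[bg$group == "Microbial (Viruses+Bacteria)"]
  N_tot <- bg$count[bg$group == "Total"]
  organism_test <- tibble(
    k = k_mic, n = n_tot, K = K_mic, N = N_tot,
    p = if (n_tot > 0) hypergeom_upper_tail(k_mic, n_tot, K_mic, N_tot) else NA_real_
  )
  outputs <- c(outputs, tsv(tally, "organism_tally"),
               tsv(organism_test, "organism_test"))

  # --- term enrichment -----------------------------------------------------
  background <- net$nodes$node_id
  sets <- with_rng_seed(cfg$rng_seed + 2, {
    random_sets <- lapply(seq_len(cfg$n_gene_sets - 1), function(i) {
      sample(background, min(25, length(background)))
    })
    c(list(planted_module = intersect(sim$module, background)),
      setNames(random_sets, sprintf("random_set_%02d", seq_along(random_sets))))
  })
  enr <- term_enrichment(subnet$nodes$node_id, sets, background, cfg$alpha)
  outputs <- c(outputs, tsv(enr, "term_enrichment"))

  # --- variants ------------------------------------------------------------
  cx <- gen_complex(n_res = cfg$template_n_res, gap = 4.5, id = "variant_target")
  chain_a <- cx$atoms |> filter(.data$chain == "A")
  rasa_mono <- relative_asa(compute_asa(chain_a, cfg$probe_radius, cfg$asa_points))
  glob <- gen_globule()
  rasa_glob <- relative_asa(compute_asa(glob, cfg$probe_radius, cfg$asa_points))
  prot <- function(rasa_tbl, seq_struct, chain, interface_resno) {
    cs <- chain_sequence(seq_struct, chain)
    info <- rasa_tbl |> mutate(in_interface = .data$resno %in% interface_resno)
    pos_of <- function(sel) match(info$resno[sel], cs$resno)
    list(sequence = cs$seq,
         locations = list(
           interface = pos_of(info$in_interface),
           surface = pos_of(!info$in_interface & info$rasa >= cfg$core_threshold),
           core = pos_of(!info$in_interface & info$rasa < cfg$core_threshold)
         ),
         info = info)
  }
  p1 <- prot(rasa_mono, cx$atoms, "A", cx$truth$res_a)
  p2 <- prot(rasa_glob, glob, "G", integer(0))
  proteins <- list(VP1 = p1, VP2 = p2)
  variants <- gen_variants(cfg$n_variants, proteins, cfg$variant_probs,
                           cfg$rng_seed + 3)
  maps <- list(VP1 = map_residues(p1$sequence, cx$atoms, "A"),
               VP2 = map_residues(p2$sequence, glob, "G"))
  infos <- list(VP1 = p1$info, VP2 = p2$info)
  located <- locate_variants(variants, maps, infos, cfg$core_threshold)
  residue_counts <- tibble(
    n_interface = sum(lengths(map(proteins, ~ .x$locations$interface))),
    n_surface_noninterface = sum(lengths(map(proteins, ~ .x$locations$surface))),
    n_core = sum(lengths(map(proteins, ~ .x$locations$core)))
  )
  pref <- location_preference_test(located$counts, residue_counts)
  outputs <- c(outputs, tsv(located$calls, "variant_calls"),
               tsv(located$counts, "variant_counts"),
               tsv(tidy(pref), "location_preference"))

  # --- manifest ------------------------------------------------------------
  paths <- file.path(out_dir, outputs)
  manifest <- list(
    package_version = as.character(utils::packageVersion("strucnet")),
    rng_seed = cfg$rng_seed,
    parameters = cfg[order(names(cfg))],
    outputs = as.list(setNames(unname(tools::md5sum(paths)), outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(network = net, scores = scores, subnetwork = subnet,
                 hubs = hubs, models = mtable, best_models = best,
                 organism_test = organism_test, enrichment = enr,
                 variants = located, preference_test = pref,
                 manifest = manifest))
}
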