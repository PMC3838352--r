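#' Generate a scale-free network with a planted phenotype module
#'
#' The background is a preferential-attachment (scale-free) graph whose mean
#' degree, at the default attachment parameter, matches the integrated human
#' interactome the pipeline emulates (about 27 interactions per protein). A
#' module of `module_size` nodes is planted by resampling its internal
#' connectivity: every within-module pair is connected with probability
#' `enrichment_factor` times the background edge density (existing
#' background edges inside the module are replaced, so factor 1 reproduces
#' the background exactly and the module is statistically invisible). Half
#' of the module (rounded down) is exported as the seed list; the other half
#' is the withheld recovery truth.
#'
#' @param n_nodes Number of nodes (default 500).
#' @param attachment Preferential-attachment parameter: edges added per new
#'   node (default 13, giving mean degree about 26). Set `model = "er"` for
#'   an Erdos-Renyi background of matching density (null checks).
#' @param module_size Planted module size (default 20), < `n_nodes`.
#' @param enrichment_factor Module edge enrichment over background density
#'   (default 8, >= 1). `enrichment_factor * density` must not exceed 1.
#' @param rng_seed Integer seed.
#' @param model `"pa"` (default) or `"er"`.
#' @return A list: `network` ([ppi_network]), `module`, `seeds`, `withheld`
#'   (character vectors of node ids).
#' @export
gen_network <- function(n_nodes = 500, attachment = 13, module_size = 20,
                        enrichment_factor = 8, rng_seed = 1, model = c("pa", "er")) {
  model <- match.arg(model)
  stopifnot(module_size < n_nodes, enrichment_factor >= 1, attachment >= 1)
  with_rng_seed(rng_seed, {
    g <- if (model == "pa") {
      igraph::sample_pa(n_nodes, power = 1, m = attachment, directed = FALSE)
    } else {
      igraph::sample_gnm(n_nodes, attachment * n_nodes - attachment)
    }
    ids <- sprintf("P%04d", seq_len(n_nodes))
    igraph::V(g)$name <- ids
    density <- igraph::edge_density(g)
    p_module <- enrichment_factor * density
    if (p_module > 1) {
      abort(sprintf("infeasible module density: %.1f x background density = %.2f > 1",
                    enrichment_factor, p_module))
    }
    module <- sort(sample(ids, module_size))
    pairs <- t(utils::combn(module, 2))
    add <- stats::runif(nrow(pairs)) < p_module
    background <- as_tibble(igraph::as_data_frame(g, what = "edges")) |>
      filter(!(.data$from %in% module & .data$to %in% module))
    edges <- bind_rows(background, tibble(from = pairs[add, 1], to = pairs[add, 2]))
    net <- ppi_network(tibble(node_id = ids), edges)
    seeds <- sort(sample(module, floor(module_size / 2)))
    list(network = net, module = module,
         seeds = seeds, withheld = setdiff(module, seeds))
  })
}

# idealized alpha-helix: 1.5 A rise and 100 degrees per residue, CA radius
# 2.3 A; backbone N/C/O and an outward C-beta stub give each residue five
# heavy atoms
helix_atoms <- function(n_res, chain = "A", start_resno = 1, phase = 0,
                        resnames = NULL) {
  i <- seq_len(n_res) - 1
  theta <- phase + i * 100 * pi / 180
  rise <- 1.5
  pos <- function(ang, radius, z) cbind(radius * cos(ang), radius * sin(ang), z)
  ca <- pos(theta, 2.3, rise * i)
  nn <- pos(theta - 0.35 * (100 * pi / 180), 1.9, rise * (i - 0.35))
  cc <- pos(theta + 0.35 * (100 * pi / 180), 2.0, rise * (i + 0.35))
  oo <- cc + pos(theta + 0.35 * (100 * pi / 180), 1.2, 0)
  cb <- pos(theta, 3.8, rise * i)
  if (is.null(resnames)) resnames <- rep("ALA", n_res)
  one <- function(xyz, name, el) {
    tibble(chain = chain, resno = start_resno + i, ins = "",
           resname = resnames, atom = name, element = el,
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1)
  }
  bind_rows(one(nn, "N", "N"), one(ca, "CA", "C"), one(cc, "C", "C"),
            one(oo, "O", "O"), one(cb, "CB", "C")) |>
    arrange(.data$resno, match(.data$atom, c("N", "CA", "C", "O", "CB")))
}

rigid_move <- function(atoms, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2, shift, "+")
  atoms |> mutate(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

#' Generate a toy two-chain complex with a known interface
#'
#' Two idealized polyalanine helices (optionally with residue substitutions)
#' are placed side by side with their C-beta faces opposed, and chain B is
#' translated so that the closest inter-chain heavy-atom distance equals
#' `gap` exactly. The ground-truth contact residue sets at `contact_cutoff`
#' are computed by direct enumeration and returned alongside.
#'
#' @param n_res Residues per chain (>= 10; default 30).
#' @param gap Closest inter-chain heavy-atom distance in Angstrom
#'   (default 4.5; must be >= 2).
#' @param substitutions Optional tibble (`chain`, `resno`, `resname`)
#'   replacing residue names (geometry is unchanged: stub side chains).
#' @param contact_cutoff Truth contact cutoff (default 5.0).
#' @param id Structure id for the emitted atom table.
#' @return A list: `atoms` (atom table, chains `A` and `B`), `truth`
#'   (`res_a`, `res_b`: contact residue numbers), `gap`, `id`.
#' @export
gen_complex <- function(n_res = 30, gap = 4.5, substitutions = NULL,
                        contact_cutoff = 5.0, id = "toy_complex") {
  if (n_res < 10) abort("need at least 10 residues per chain")
  if (gap < 2) abort("gap below 2 A is unphysical")
  a <- helix_atoms(n_res, "A", phase = 0)
  # B faces A: rotated around z so its C-beta stubs point back at A
  b <- helix_atoms(n_res, "B", phase = pi) |>
    rigid_move(shift = c(20, 0, 0))
  cur <- min(cross_dist(as.matrix(a[, c("x", "y", "z")]),
                        as.matrix(b[, c("x", "y", "z")])))
  b <- rigid_move(b, shift = c(gap - cur, 0, 0))
  atoms <- bind_rows(a, b)
  if (!is.null(substitutions)) {
    for (k in seq_len(nrow(substitutions))) {
      sel <- atoms$chain == substitutions$chain[k] &
        atoms$resno == substitutions$resno[k]
      atoms$resname[sel] <- substitutions$resname[k]
    }
  }
  # ground truth by direct enumeration, independent of extract_interface
  am <- atoms[atoms$chain == "A" & atoms$element != "H", ]
  bm <- atoms[atoms$chain == "B" & atoms$element != "H", ]
  res_a <- integer(0); res_b <- integer(0)
  for (ra in unique(am$resno)) {
    pa <- as.matrix(am[am$resno == ra, c("x", "y", "z")])
    for (rb in unique(bm$resno)) {
      pb <- as.matrix(bm[bm$resno == rb, c("x", "y", "z")])
      dmin <- sqrt(min(outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)))
      if (dmin <= contact_cutoff) {
        res_a <- union(res_a, ra); res_b <- union(res_b, rb)
      }
    }
  }
  attr(atoms, "structure_id") <- id
  list(atoms = atoms, truth = list(res_a = sort(res_a), res_b = sort(res_b)),
       gap = gap, id = id)
}

#' Generate a compact single-chain helix bundle
#'
#' Four parallel helices on a square, written as one chain with continuous
#' residue numbering. Inward-facing residues are buried, giving the chain a
#' genuine core for accessibility tests.
#'
#' @param n_res Residues per helix (default 12).
#' @param spacing Axis-to-axis distance in Angstrom (default 7).
#' @param chain Chain id (default "G").
#' @return An atom table.
#' @export
gen_globule <- function(n_res = 12, spacing = 7, chain = "G") {
  corners <- list(c(0, 0, 0), c(spacing, 0, 0), c(spacing, spacing, 0),
                  c(0, spacing, 0))
  # C-beta stubs point at the bundle centre so they pack
  centre_phase <- c(45, 135, -135, -45) * pi / 180
  bind_rows(lapply(seq_along(corners), function(k) {
    helix_atoms(n_res, chain, start_resno = 1 + (k - 1) * n_res,
                phase = centre_phase[k]) |>
      rigid_move(shift = corners[[k]])
  }))
}

#' Generate a template library with controlled organism composition
#'
#' Each template is a toy two-chain complex; each chain's source-organism
#' kingdom is microbial (Bacteria or Viruses) with probability
#' `microbial_fraction`, non-microbial (Eukaryota or Archaea) otherwise,
#' with the within-group split matching the background composition of
#' structural templates (Bacteria:Viruses about 5.9:1, Eukaryota:Archaea
#' about 11.3:1).
#'
#' @param n_templates Number of templates (default 20).
#' @param microbial_fraction Probability a chain is microbial
#'   (default 0.437, the background microbial share 4918/11255).
#' @param rng_seed Integer seed.
#' @param with_structures Generate coordinates too (default TRUE); the index
#'   alone suffices for composition tests.
#' @param n_res,gap_range Geometry of the underlying toy complexes.
#' @return A list: `index` (tibble `template_id`, `chain`, `kingdom`,
#'   `protein_name`), `templates` (named list of `gen_complex` results, or
#'   `NULL`).
#' @export
gen_template_library <- function(n_templates = 20, microbial_fraction = 4918 / 11255,
                                 rng_seed = 1, with_structures = TRUE,
                                 n_res = 30, gap_range = c(3.0, 3.8)) {
  stopifnot(n_templates >= 1, microbial_fraction >= 0, microbial_fraction <= 1)
  hydrophobic <- c("LEU", "ILE", "VAL", "PHE", "MET", "TRP")
  with_rng_seed(rng_seed, {
    ids <- paste0(sprintf("t%03d", seq_len(n_templates)), "AB")
    n_chain <- 2 * n_templates
    micro <- stats::runif(n_chain) < microbial_fraction
    kingdom <- ifelse(micro,
                      sample(c("Bacteria", "Viruses"), n_chain, TRUE,
                             prob = c(4202, 716)),
                      sample(c("Eukaryota", "Archaea"), n_chain, TRUE,
                             prob = c(5822, 515)))
    index <- tibble(
      template_id = rep(ids, each = 2),
      chain = rep(c("A", "B"), n_templates),
      kingdom = kingdom,
      protein_name = paste0("synthetic_protein_", seq_len(n_chain))
    )
    templates <- NULL
    if (with_structures) {
      templates <- lapply(seq_len(n_templates), function(i) {
        gap <- stats::runif(1, gap_range[1], gap_range[2])
        cx <- gen_complex(n_res = n_res, gap = gap, id = ids[i])
        # hydrophobic substitutions at the contact residues so interfaces
        # score favorably under the contact potential
        subs <- tibble(
          chain = c(rep("A", length(cx$truth$res_a)), rep("B", length(cx$truth$res_b))),
          resno = c(cx$truth$res_a, cx$truth$res_b),
          resname = sample(hydrophobic,
                           length(cx$truth$res_a) + length(cx$truth$res_b), TRUE)
        )
        for (k in seq_len(nrow(subs))) {
          sel <- cx$atoms$chain == subs$chain[k] & cx$atoms$resno == subs$resno[k]
          cx$atoms$resname[sel] <- subs$resname[k]
        }
        cx
      })
      names(templates) <- ids
    }
    list(index = index, templates = templates)
  })
}

#' Generate a variant table with controlled structural placement
#'
#' Draws variants over proteins with known core/surface/interface residue
#' sets: for each variant a protein is chosen uniformly, a location class is
#' drawn from `location_probs`, and the position is drawn uniformly from
#' that class's residue set. The generating truth label is emitted so that
#' downstream classification can be checked against it.
#'
#' @param n_variants Number of variants (default 300).
#' @param proteins Named list; each element has `sequence` (one-letter
#'   string) and `locations`, a list of integer position vectors named
#'   `core`, `surface`, `interface`.
#' @param location_probs Placement probabilities, named, summing to 1
#'   (default `c(core = 0.35, surface = 0.58, interface = 0.07)`, the
#'   observed split of mapped cancer variants).
#' @param rng_seed Integer seed.
#' @return A tibble (`accession`, `position`, `wt`, `mut`, `class`,
#'   `source`, `truth_location`).
#' @export
gen_variants <- function(n_variants = 300, proteins,
                         location_probs = c(core = 0.35, surface = 0.58,
                                            interface = 0.07),
                         rng_seed = 1) {
  stopifnot(abs(sum(location_probs) - 1) < 1e-8, n_variants >= 1)
  classes <- names(location_probs)
  # a protein is eligible for a class when its residue set is non-empty;
  # a positive-probability class with no eligible protein is an error
  eligible <- map(setNames(classes, classes), function(cl) {
    names(proteins)[map_int(proteins, ~ length(.x$locations[[cl]]) %||% 0L) > 0]
  })
  empty <- classes[location_probs > 0 & lengths(eligible) == 0]
  if (length(empty) > 0) {
    abort(sprintf("no protein provides residue class(es) %s requested with positive probability",
                  paste(empty, collapse = ",")))
  }
  aa20 <- names(REF_ASA)
  with_rng_seed(rng_seed, {
    loc <- sample(classes, n_variants, replace = TRUE, prob = location_probs)
    acc <- map_chr(loc, function(cl) {
      cand <- eligible[[cl]]
      cand[sample.int(length(cand), 1)]
    })
    rows <- map(seq_len(n_variants), function(i) {
      p <- proteins[[acc[i]]]
      cand <- p$locations[[loc[i]]]
      pos <- cand[sample.int(length(cand), 1)]
      wt <- substr(p$sequence, pos, pos)
      mut <- sample(setdiff(aa20, wt), 1)
      tibble(accession = acc[i], position = pos, wt = wt, mut = mut,
             class = sample(c("polymorphism", "disease", "cancer-somatic"), 1),
             source = sample(c("humsavar", "cosmic"), 1),
             truth_location = loc[i])
    })
    bind_rows(rows)
  })
}
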