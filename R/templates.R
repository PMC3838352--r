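#' Load the residue-contact potential table
#'
#' A symmetric 20 x 20 residue-pair contact potential shipped with the
#' package (`extdata/contact_potential.tsv`). Entries are
#' `-(h_i + h_j) / 2` on a consensus hydrophobicity scale, so hydrophobic
#' pairings are favorable (negative) and charged/polar pairings unfavorable.
#' Units are arbitrary; only the sign convention (negative = favorable) and
#' the ranking of models matter downstream.
#'
#' @param path Optional path to an alternative table with the same layout.
#' @return A 20 x 20 numeric matrix with one-letter amino-acid dimnames.
#' @export
load_contact_potential <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "contact_potential.tsv", package = "strucnet")
  }
  m <- as.matrix(readr::read_tsv(path, col_types = readr::cols(
    aa = readr::col_character(), .default = readr::col_double()
  )) |> tibble::column_to_rownames("aa"))
  if (!isTRUE(all.equal(m, t(m)))) abort("contact potential must be symmetric")
  m
}

#' Parse a template identifier
#'
#' Template ids are a 4-character PDB id followed by the two chain letters,
#' e.g. `"2b8nAB"`.
#'
#' @param template_id Character vector of template ids.
#' @return A tibble (`template_id`, `pdb_id`, `chain_1`, `chain_2`).
#' @export
parse_template_id <- function(template_id) {
  ok <- grepl("^[A-Za-z0-9]{4}[A-Za-z][A-Za-z]$", template_id)
  if (any(!ok)) {
    abort(paste0("malformed template id(s): ",
                 paste(head(template_id[!ok], 5), collapse = ", ")))
  }
  tibble(template_id = template_id,
         pdb_id = substr(template_id, 1, 4),
         chain_1 = substr(template_id, 5, 5),
         chain_2 = substr(template_id, 6, 6))
}

#' Build a template interface from a complex structure
#'
#' Extracts the two half-interfaces of a two-chain template and carries the
#' per-chain source-organism kingdom from the organism index.
#'
#' @param struct Atom table of the template complex.
#' @param template_id Template id (PDB id + two chain letters).
#' @param organism_index Optional tibble (`template_id`, `chain`, `kingdom`).
#' @param contact_cutoff Interface contact cutoff in Angstrom.
#' @return A list of class `template_interface`: `template_id`, `halves` (a
#'   list of two interface-residue tibbles), `struct`, `kingdoms`.
#' @export
template_interface <- function(struct, template_id, organism_index = NULL,
                               contact_cutoff = 5.0) {
  pt <- parse_template_id(template_id)
  iface <- extract_interface(struct, pt$chain_1, pt$chain_2, contact_cutoff)
  if (iface$empty) abort(paste0("template ", template_id, " has an empty interface"))
  kingdoms <- c(NA_character_, NA_character_)
  if (!is.null(organism_index)) {
    idx <- organism_index |> filter(.data$template_id == !!template_id)
    kingdoms <- c(idx$kingdom[match(pt$chain_1, idx$chain)],
                  idx$kingdom[match(pt$chain_2, idx$chain)])
  }
  structure(list(template_id = template_id, struct = struct,
                 halves = list(iface$res_a, iface$res_b),
                 chains = c(pt$chain_1, pt$chain_2), kingdoms = kingdoms),
            class = "template_interface")
}

#' @export
print.template_interface <- function(x, ...) {
  cat(sprintf("<template_interface> %s: %d + %d interface residues\n",
              x$template_id, nrow(x$halves[[1]]), nrow(x$halves[[2]])))
  invisible(x)
}

half_ca_coords <- function(template, half) {
  ca <- ca_table(template$struct) |>
    filter(.data$chain == template$chains[half])
  key <- paste(template$halves[[half]]$resno, template$halves[[half]]$ins)
  ca |> filter(paste(.data$resno, .data$ins) %in% key)
}

#' Match a template half-interface onto a target chain
#'
#' Searches residue-index offsets of the target chain for the placement of
#' the template half-interface (its residues keep their relative spacing but
#' need not be contiguous) that minimizes the C-alpha superposition RMSD. A
#' match is accepted when RMSD <= `rmsd_cutoff` and the fraction of template
#' half residues paired to target residues is >= `min_coverage`. The
#' returned transform maps the *target* chain into the template frame.
#'
#' @param template A `template_interface`.
#' @param half 1 or 2: which half-interface to match.
#' @param target Atom table of the target protein (single chain used).
#' @param target_chain Chain of `target` to use (default: its first chain).
#' @param rmsd_cutoff Acceptance RMSD in Angstrom (default 2.0).
#' @param min_coverage Minimum matched fraction of the half (default 0.5).
#' @param min_target_residues Minimum target chain length (default 15).
#' @return A list (`residue_map`, `rotation`, `translation`, `rmsd`,
#'   `coverage`, `offset`) or `NULL` when no acceptable match exists.
#' @export
match_template <- function(template, half, target, target_chain = NULL,
                           rmsd_cutoff = 2.0, min_coverage = 0.5,
                           min_target_residues = 15) {
  half_ca <- half_ca_coords(template, half)
  t_ca <- ca_table(target)
  if (is.null(target_chain)) target_chain <- t_ca$chain[1]
  t_ca <- t_ca |> filter(.data$chain == target_chain)
  if (nrow(t_ca) < min_target_residues) {
    abort(sprintf("target chain %s has %d residues (< %d)", target_chain,
                  nrow(t_ca), min_target_residues))
  }
  # spacing of the half residues within their chain, in residue-number units
  delta <- half_ca$resno - min(half_ca$resno)
  n_half <- nrow(half_ca)
  t_resno <- t_ca$resno
  best <- NULL
  for (o in seq(min(t_resno) - max(delta), max(t_resno))) {
    idx <- match(o + delta, t_resno)
    keep <- !is.na(idx)
    if (sum(keep) < 3) next
    coverage <- sum(keep) / n_half
    if (coverage < min_coverage) next
    p <- as.matrix(t_ca[idx[keep], c("x", "y", "z")])
    q <- as.matrix(half_ca[keep, c("x", "y", "z")])
    tr <- tryCatch(kabsch_superpose(p, q), error = function(e) NULL)
    if (is.null(tr)) next
    if (tr$rmsd > rmsd_cutoff) next
    # prefer the most complete placement; RMSD only breaks coverage ties
    # (tiny partial matches can superpose spuriously well)
    if (is.null(best) || coverage > best$coverage ||
        (coverage == best$coverage && tr$rmsd < best$rmsd)) {
      best <- list(
        residue_map = tibble(template_resno = half_ca$resno[keep],
                             target_resno = t_ca$resno[idx[keep]],
                             target_chain = target_chain),
        rotation = tr$rotation, translation = tr$translation,
        rmsd = tr$rmsd, coverage = coverage, offset = o
      )
    }
  }
  best
}

#' Assemble a binary complex model from two half-interface matches
#'
#' Places each target chain into the template frame with its half's rigid
#' transform and screens the placement for steric clashes (heavy-atom pairs
#' closer than `clash_dist` between the two partners). Models exceeding
#' `max_clashes` are rejected.
#'
#' @param template A `template_interface`.
#' @param match_1,match_2 Accepted matches from [match_template()] for halves
#'   1 and 2.
#' @param target_1,target_2 Atom tables of the two target proteins.
#' @param pair Character vector of length 2 naming the target proteins.
#' @param clash_dist Clash distance in Angstrom (default 2.5).
#' @param max_clashes Maximum tolerated clash count (default 5).
#' @return A list of class `complex_model`: transformed `atoms` (chains
#'   relabelled `A`/`B`), `pair`, `template_id`, per-half `rmsd` and
#'   `coverage`, `n_clashes`, `accepted`, and `energy` (`NA` until scored).
#' @export
build_model <- function(template, match_1, match_2, target_1, target_2,
                        pair = c("target1", "target2"),
                        clash_dist = 2.5, max_clashes = 5) {
  if (is.null(match_1) || is.null(match_2)) abort("both matches must be accepted")
  place <- function(target, match, new_chain) {
    at <- target |> filter(.data$chain == match$residue_map$target_chain[1])
    xyz <- apply_transform(at[, c("x", "y", "z")], match)
    at |> mutate(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], chain = new_chain)
  }
  a <- place(target_1, match_1, "A")
  b <- place(target_2, match_2, "B")
  d <- cross_dist(as.matrix(heavy_atoms(a)[, c("x", "y", "z")]),
                  as.matrix(heavy_atoms(b)[, c("x", "y", "z")]))
  n_clashes <- sum(d < clash_dist)
  accepted <- n_clashes <= max_clashes
  if (!accepted) {
    inform(sprintf("model %s-%s on %s rejected: %d steric clashes (max %d)",
                   pair[1], pair[2], template$template_id, n_clashes, max_clashes))
  }
  structure(list(atoms = bind_rows(a, b), pair = pair,
                 template_id = template$template_id,
                 rmsd = c(match_1$rmsd, match_2$rmsd),
                 coverage = c(match_1$coverage, match_2$coverage),
                 n_clashes = n_clashes, accepted = accepted, energy = NA_real_),
            class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  cat(sprintf("<complex_model> %s-%s via %s: rmsd %.2f/%.2f, %d clashes, energy %s\n",
              x$pair[1], x$pair[2], x$template_id, x$rmsd[1], x$rmsd[2],
              x$n_clashes, ifelse(is.na(x$energy), "unscored", sprintf("%.2f", x$energy))))
  invisible(x)
}

cb_coords <- function(struct, chain) {
  # contact centre per residue: C-beta, falling back to C-alpha (glycine)
  struct |>
    filter(.data$chain == !!chain, .data$atom %in% c("CA", "CB")) |>
    group_by(.data$resno, .data$ins, .data$resname) |>
    arrange(desc(.data$atom), .by_group = TRUE) |>   # CB before CA
    slice(1) |>
    ungroup()
}

#' Score a complex model with the residue-contact potential
#'
#' Sums the pair potential over all inter-chain residue contacts whose
#' contact centres (C-beta, C-alpha for glycine) lie within
#' `contact_cutoff`. Negative totals are favorable; a model without any
#' inter-chain contact scores 0.
#'
#' @param model A `complex_model`.
#' @param potential A potential matrix from [load_contact_potential()].
#' @param contact_cutoff Contact-centre distance cutoff in Angstrom
#'   (default 7.0).
#' @return The model with its `energy` field set.
#' @export
score_energy <- function(model, potential = load_contact_potential(),
                         contact_cutoff = 7.0) {
  a <- cb_coords(model$atoms, "A")
  b <- cb_coords(model$atoms, "B")
  d <- cross_dist(as.matrix(a[, c("x", "y", "z")]),
                  as.matrix(b[, c("x", "y", "z")]))
  hit <- which(d <= contact_cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    model$energy <- 0
    return(model)
  }
  aa_a <- aa_three_to_one(a$resname[hit[, 1]])
  aa_b <- aa_three_to_one(b$resname[hit[, 2]])
  known <- aa_a %in% rownames(potential) & aa_b %in% colnames(potential)
  model$energy <- sum(potential[cbind(aa_a[known], aa_b[known])])
  model
}

#' Tabulate complex models
#'
#' @param models A list of scored `complex_model` objects.
#' @return A tibble with one row per model (`pair_id`, `target_1`,
#'   `target_2`, `template_id`, `rmsd_1`, `rmsd_2`, `coverage_1`,
#'   `coverage_2`, `n_clashes`, `accepted`, `energy`).
#' @export
model_table <- function(models) {
  map(models, function(m) {
    tibble(pair_id = paste(sort(m$pair), collapse = "|"),
           target_1 = m$pair[1], target_2 = m$pair[2],
           template_id = m$template_id,
           rmsd_1 = m$rmsd[1], rmsd_2 = m$rmsd[2],
           coverage_1 = m$coverage[1], coverage_2 = m$coverage[2],
           n_clashes = m$n_clashes, accepted = m$accepted, energy = m$energy)
  }) |> bind_rows()
}

#' Filter models by energy and keep the best model per target pair
#'
#' Applies the energy criterion (keep models with energy strictly below
#' `energy_cutoff`, default 0) and then selects, per target pair, the model
#' with the lowest energy; ties go to the lexicographically smaller template
#' id. Pairs with no surviving model yield no row.
#'
#' @param models A model table from [model_table()] (or a list of models).
#' @param energy_cutoff Energy filter threshold (default 0; strict `<`).
#' @return The filtered model table, one row per `pair_id`.
#' @export
select_best_models <- function(models, energy_cutoff = 0) {
  if (!is.data.frame(models)) models <- model_table(models)
  models |>
    filter(.data$accepted, !is.na(.data$energy),
           .data$energy < energy_cutoff) |>
    group_by(.data$pair_id) |>
    arrange(.data$energy, .data$template_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}
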