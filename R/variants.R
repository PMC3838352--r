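# extended-state (Gly-X-Gly) reference areas in A^2, used to normalize
# residue ASA into relative accessibility
REF_ASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
             G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
             P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)

chain_sequence <- function(struct, chain) {
  ca <- ca_table(struct) |> filter(.data$chain == !!chain)
  list(seq = paste(aa_three_to_one(ca$resname), collapse = ""),
       resno = ca$resno, ins = ca$ins)
}

#' Map sequence positions onto structure residues
#'
#' Globally aligns the full protein sequence against the sequence read off a
#' structure chain and returns the one-to-one residue-level correspondence.
#' Positions aligned to gaps are unmapped. The map is rejected when the
#' identity over aligned columns falls below `min_identity`.
#'
#' @param sequence One-letter amino-acid string (length >= 20).
#' @param struct Atom table of the structure.
#' @param chain Chain to map against (>= 10 residues with coordinates).
#' @param min_identity Identity threshold over aligned columns (default 0.9).
#' @return A list of class `residue_map`: `map` (tibble `position`, `chain`,
#'   `resno`, `ins`, `seq_aa`, `struct_aa`) and `identity`.
#' @export
map_residues <- function(sequence, struct, chain, min_identity = 0.9) {
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (nchar(sequence) < 20) abort("sequence shorter than 20 residues")
  cs <- chain_sequence(struct, chain)
  if (nchar(cs$seq) < 10) abort(sprintf("chain %s has fewer than 10 residues with coordinates", chain))
  al <- align_global(sequence, cs$seq)
  cols <- tibble(seq_aa = al$a, struct_aa = al$b,
                 position = al$pos_a, chain_idx = al$pos_b) |>
    filter(!is.na(.data$position), !is.na(.data$chain_idx))
  identity <- mean(cols$seq_aa == cols$struct_aa)
  if (is.nan(identity) || identity < min_identity) {
    abort(sprintf("sequence/chain %s alignment identity %.2f below %.2f: map rejected",
                  chain, ifelse(is.nan(identity), 0, identity), min_identity))
  }
  map <- cols |>
    transmute(position = .data$position, chain = !!chain,
              resno = cs$resno[.data$chain_idx], ins = cs$ins[.data$chain_idx],
              seq_aa = .data$seq_aa, struct_aa = .data$struct_aa)
  structure(list(map = map, identity = identity), class = "residue_map")
}

# global pairwise alignment; Biostrings when available, otherwise plain
# Needleman-Wunsch (match 2, mismatch -1, gap -2)
align_global <- function(a, b) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    letters20 <- c(names(REF_ASA), "X")
    sm <- matrix(-1, length(letters20), length(letters20),
                 dimnames = list(letters20, letters20))
    diag(sm) <- 2
    al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                        substitutionMatrix = sm,
                                        gapOpening = 2, gapExtension = 2)
    ga <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    gb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  } else {
    nw <- needleman_wunsch(a, b)
    ga <- nw$a; gb <- nw$b
  }
  pos_a <- cumsum(ga != "-"); pos_a[ga == "-"] <- NA
  pos_b <- cumsum(gb != "-"); pos_b[gb == "-"] <- NA
  list(a = ga, b = gb, pos_a = pos_a, pos_b = pos_b)
}

needleman_wunsch <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  f <- matrix(0, n + 1, m + 1)
  f[, 1] <- gap * (0:n); f[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    s <- ifelse(av[i] == bv, match, mismatch)
    for (j in seq_len(m)) {
      f[i + 1, j + 1] <- max(f[i, j] + s[j], f[i, j + 1] + gap, f[i + 1, j] + gap)
    }
  }
  ga <- character(0); gb <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        f[i + 1, j + 1] == f[i, j] + ifelse(av[i] == bv[j], match, mismatch)) {
      ga <- c(av[i], ga); gb <- c(bv[j], gb); i <- i - 1; j <- j - 1
    } else if (i > 0 && f[i + 1, j + 1] == f[i, j + 1] + gap) {
      ga <- c(av[i], ga); gb <- c("-", gb); i <- i - 1
    } else {
      ga <- c("-", ga); gb <- c(bv[j], gb); j <- j - 1
    }
  }
  list(a = ga, b = gb)
}

# deterministic near-uniform points on the unit sphere (Fibonacci spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area by spherical point sampling
#'
#' For each heavy atom, `n_points` near-uniform points are placed on the
#' sphere of radius (van der Waals radius + probe radius); the accessible
#' fraction is the share of points falling outside every other atom's
#' expanded sphere, and the atom's ASA is that fraction of the expanded
#' sphere area. Residue ASA sums over the residue's atoms. This implements
#' the rolling-probe accessibility contract with a water-sized probe.
#'
#' @param struct Atom table with element types.
#' @param probe_radius Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sample points per atom (default 960).
#' @param chains Optional chain subset to compute on (e.g. one chain for
#'   monomer accessibility).
#' @return A tibble (`chain`, `resno`, `ins`, `resname`, `asa`) in A^2.
#' @export
compute_asa <- function(struct, probe_radius = 1.4, n_points = 960,
                        chains = NULL) {
  at <- heavy_atoms(struct)
  if (!is.null(chains)) at <- at |> filter(.data$chain %in% chains)
  if (nrow(at) == 0) abort("no heavy atoms")
  known <- at$element %in% names(VDW_RADII)
  if (any(!known)) {
    warn(paste0("unknown element(s) ", paste(unique(at$element[!known]), collapse = ","),
                ": using 1.8 A van der Waals radius"))
  }
  radii <- unname(ifelse(known, VDW_RADII[at$element], 1.8)) + probe_radius
  xyz <- as.matrix(at[, c("x", "y", "z")])
  pts <- sphere_points(n_points)
  n <- nrow(at)
  d <- cross_dist(xyz, xyz)
  asa_atom <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < radii[i] + radii & seq_len(n) != i)
    p <- sweep(pts * radii[i], 2, xyz[i, ], "+")
    if (length(nb) == 0) {
      frac <- 1
    } else {
      d2 <- cross_dist(p, xyz[nb, , drop = FALSE])
      buried <- rowSums(d2 < rep(radii[nb], each = n_points)) > 0
      frac <- mean(!buried)
    }
    asa_atom[i] <- frac * 4 * pi * radii[i]^2
  }
  at |>
    mutate(.asa = asa_atom) |>
    group_by(.data$chain, .data$resno, .data$ins, .data$resname) |>
    summarise(asa = sum(.data$.asa), .groups = "drop")
}

#' Relative solvent accessibility
#'
#' Residue ASA divided by its extended-state (Gly-X-Gly) reference area, as
#' a percentage. Unknown residue types get `NA`.
#'
#' @param asa_table Output of [compute_asa()].
#' @return The input with an added `rasa` column (percent).
#' @export
relative_asa <- function(asa_table) {
  aa <- aa_three_to_one(asa_table$resname)
  ref <- REF_ASA[aa]
  asa_table |> mutate(rasa = 100 * .data$asa / unname(ref))
}

#' Classify a residue location
#'
#' Interface membership takes precedence; otherwise residues with monomer
#' relative accessibility at or above `core_threshold` percent are surface,
#' and the rest are core.
#'
#' @param rasa Monomer relative accessibility (percent).
#' @param in_interface Logical: is the residue in any interface set?
#' @param core_threshold Core cutoff in percent (default 5, exclusive:
#'   `rasa >= core_threshold` is surface).
#' @return `"interface"`, `"surface"` or `"core"` (vectorized).
#' @export
classify_location <- function(rasa, in_interface, core_threshold = 5) {
  dplyr::case_when(
    in_interface ~ "interface",
    rasa >= core_threshold ~ "surface",
    TRUE ~ "core"
  )
}

#' Map variants to structural locations
#'
#' Each variant is carried through its protein's residue map and classified
#' as core, surface or interface from monomer accessibility and interface
#' membership; variants without structural coverage are `unmapped`.
#' Variants whose annotated wild-type residue disagrees with the mapped
#' structure residue are flagged as mismatches and excluded from the counts.
#'
#' @param variants Tibble (`accession`, `position`, `wt`, `mut`, `class`,
#'   `source`).
#' @param maps Named list (by accession) of `residue_map` objects.
#' @param residue_info Named list (by accession) of tibbles (`resno`, `ins`,
#'   `rasa`, `in_interface`) describing the mapped chain's residues.
#' @param core_threshold Core cutoff in percent (default 5).
#' @return A list: `calls` (per-variant tibble with `location`, `rasa`,
#'   `mismatch`) and `counts` (tibble `n_core`, `n_surface_noninterface`,
#'   `n_interface`, `n_unmapped`, `n_mismatch`).
#' @export
locate_variants <- function(variants, maps, residue_info, core_threshold = 5) {
  variants <- as_tibble(variants)
  calls <- variants |>
    mutate(location = NA_character_, rasa = NA_real_, mismatch = FALSE)
  for (i in seq_len(nrow(calls))) {
    acc <- calls$accession[i]
    pos <- calls$position[i]
    rm <- maps[[acc]]
    if (is.null(rm)) { calls$location[i] <- "unmapped"; next }
    row <- rm$map |> filter(.data$position == pos)
    if (nrow(row) == 0) {
      calls$location[i] <- "unmapped"
      if (pos > max(rm$map$position, 0)) {
        warn(sprintf("variant %s:%d beyond mapped sequence", acc, pos))
      }
      next
    }
    if (row$struct_aa[1] != calls$wt[i]) {
      calls$mismatch[i] <- TRUE
      calls$location[i] <- "mismatch"
      next
    }
    info <- residue_info[[acc]] |>
      filter(.data$resno == row$resno[1], .data$ins == row$ins[1])
    if (nrow(info) == 0) { calls$location[i] <- "unmapped"; next }
    calls$rasa[i] <- info$rasa[1]
    calls$location[i] <- classify_location(info$rasa[1], info$in_interface[1],
                                           core_threshold)
  }
  if (any(calls$mismatch)) {
    inform(sprintf("locate_variants: %d wild-type mismatch(es) excluded from counts",
                   sum(calls$mismatch)))
  }
  counts <- tibble(
    n_core = sum(calls$location == "core"),
    n_surface_noninterface = sum(calls$location == "surface"),
    n_interface = sum(calls$location == "interface"),
    n_unmapped = sum(calls$location == "unmapped"),
    n_mismatch = sum(calls$mismatch)
  )
  list(calls = calls, counts = counts)
}

#' Test variant location preference (Fisher exact)
#'
#' Builds a 2 x 2 table of variant counts against residue availability and
#' delegates to [fisher_two_tailed()]. Under the `"surface_only"` convention
#' interface residues are treated as a subset of the surface and the
#' contrast is interface vs non-interface surface; under `"all_mapped"` the
#' contrast is interface vs all non-interface residues (core included).
#'
#' @param variant_counts Tibble with `n_interface`, `n_surface_noninterface`
#'   and `n_core` (from [locate_variants()]).
#' @param residue_counts Same three columns counting the available residues.
#' @param convention `"surface_only"` (default) or `"all_mapped"`.
#' @return A list of class `location_pref_test`: the 2 x 2 `table`,
#'   `odds_ratio`, `p`, `convention`.
#' @export
location_preference_test <- function(variant_counts, residue_counts,
                                     convention = c("surface_only", "all_mapped")) {
  convention <- match.arg(convention)
  pick <- function(cnt) {
    other <- if (convention == "surface_only") cnt$n_surface_noninterface
             else cnt$n_surface_noninterface + cnt$n_core
    c(interface = cnt$n_interface, other = other)
  }
  tab <- rbind(variants = pick(variant_counts), residues = pick(residue_counts))
  res <- fisher_two_tailed(tab)
  structure(list(table = tab, odds_ratio = res$odds_ratio, p = res$p,
                 convention = convention),
            class = "location_pref_test")
}

#' @export
print.location_pref_test <- function(x, ...) {
  cat(sprintf("<location_pref_test> (%s) OR = %.3f, two-tailed p = %.4g\n",
              x$convention, x$odds_ratio, x$p))
  print(x$table)
  invisible(x)
}

#' Flag interface hot-spot residues
#'
#' A simple empirical rule: an interface residue is a hot spot when it is
#' buried in the complex (relative accessibility in the complex at or below
#' `rasa_cutoff` percent) and its summed residue-contact potential over
#' cross-interface contacts is strongly favorable (total energy at or below
#' `-potential_cutoff`).
#'
#' @param model A `complex_model`.
#' @param potential Contact potential matrix.
#' @param rasa_cutoff Complex-state accessibility cutoff in percent
#'   (default 20).
#' @param potential_cutoff Magnitude of favorable contact energy required
#'   (default 1.0, potential units).
#' @param contact_cutoff Contact-centre cutoff in Angstrom (default 7.0).
#' @param n_points ASA sampling density (default 960).
#' @return A tibble of interface residues (`chain`, `resno`, `ins`,
#'   `resname`, `rasa_complex`, `contact_energy`, `hotspot`).
#' @export
predict_hotspots <- function(model, potential = load_contact_potential(),
                             rasa_cutoff = 20, potential_cutoff = 1.0,
                             contact_cutoff = 7.0, n_points = 960) {
  iface <- extract_interface(model$atoms, "A", "B")
  iface_res <- bind_rows(iface$res_a, iface$res_b)
  if (nrow(iface_res) == 0) {
    return(tibble(chain = character(), resno = integer(), ins = character(),
                  resname = character(), rasa_complex = numeric(),
                  contact_energy = numeric(), hotspot = logical()))
  }
  rasa_cx <- relative_asa(compute_asa(model$atoms, n_points = n_points))

  a <- cb_coords(model$atoms, "A"); b <- cb_coords(model$atoms, "B")
  d <- cross_dist(as.matrix(a[, c("x", "y", "z")]),
                  as.matrix(b[, c("x", "y", "z")]))
  hit <- which(d <= contact_cutoff, arr.ind = TRUE)
  energy <- tibble(
    chain = c(rep("A", nrow(hit)), rep("B", nrow(hit))),
    resno = c(a$resno[hit[, 1]], b$resno[hit[, 2]]),
    ins = c(a$ins[hit[, 1]], b$ins[hit[, 2]]),
    e = rep(potential[cbind(aa_three_to_one(a$resname[hit[, 1]]),
                            aa_three_to_one(b$resname[hit[, 2]]))], 2)
  ) |>
    group_by(.data$chain, .data$resno, .data$ins) |>
    summarise(contact_energy = sum(.data$e), .groups = "drop")

  iface_res |>
    left_join(rasa_cx |> select("chain", "resno", "ins", rasa_complex = "rasa"),
              by = c("chain", "resno", "ins")) |>
    left_join(energy, by = c("chain", "resno", "ins")) |>
    mutate(contact_energy = tidyr::replace_na(.data$contact_energy, 0),
           hotspot = .data$rasa_complex <= rasa_cutoff &
             .data$contact_energy <= -potential_cutoff) |>
    arrange(.data$chain, .data$resno, .data$ins)
}
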