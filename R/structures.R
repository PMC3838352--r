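AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

aa_three_to_one <- function(resname) {
  out <- AA3[toupper(resname)]
  out[is.na(out)] <- "X"
  unname(out)
}

# van der Waals radii (A) by element; unknowns fall back to 1.8 with a warning
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
               SE = 1.90)

#' Parse a structure in PDB format
#'
#' Reads ATOM records into an atom table. Alternate locations are resolved by
#' keeping the highest-occupancy conformer (ties go to altloc "A");
#' HETATM records are excluded except selenomethionine (MSE), which is mapped
#' to methionine. Hydrogens are retained in the table but all downstream
#' geometry uses heavy atoms only.
#'
#' @param x Path to a PDB file, or a character scalar/vector of PDB text.
#' @param id Structure identifier; defaults to the file base name.
#' @return A tibble with columns `chain`, `resno`, `ins`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z`, `occ`, and attribute `structure_id`.
#' @export
parse_structure <- function(x, id = NULL) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    path <- x
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(unlist(strsplit(x, "\n", fixed = TRUE)), path)
    if (is.null(id)) id <- "structure"
  }
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e) abort(paste0("no ATOM records parsed: ", conditionMessage(e))))
  at <- as_tibble(pdb$atom)
  if (nrow(at) == 0) abort("no ATOM records parsed")
  at <- at |>
    filter(.data$type == "ATOM" | (.data$type == "HETATM" & .data$resid == "MSE")) |>
    mutate(resid = ifelse(.data$resid == "MSE", "MET", .data$resid),
           elety = ifelse(.data$resid == "MET" & .data$elety == "SE", "SD", .data$elety))
  if (nrow(at) == 0) abort("no ATOM records parsed")
  unknown <- setdiff(unique(at$resid), names(AA3))
  if (length(unknown) > 0) {
    warn(paste0("unknown residue name(s) kept: ", paste(unknown, collapse = ", ")))
  }
  at <- at |>
    mutate(alt = ifelse(is.na(.data$alt) | .data$alt == "", "", .data$alt),
           insert = ifelse(is.na(.data$insert), "", .data$insert),
           o = ifelse(is.na(.data$o), 1, .data$o),
           element = infer_element(.data$elesy, .data$elety)) |>
    # altloc: highest occupancy wins, ties go to the alphabetically first altloc
    group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    arrange(desc(.data$o), .data$alt, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$chain, .data$resno, .data$insert)
  out <- at |>
    transmute(chain = .data$chain, resno = .data$resno, ins = .data$insert,
              resname = .data$resid, atom = .data$elety,
              element = .data$element, x = .data$x, y = .data$y, z = .data$z,
              occ = .data$o)
  attr(out, "structure_id") <- id
  out
}

infer_element <- function(elesy, elety) {
  el <- toupper(ifelse(is.na(elesy) | elesy == "", NA, elesy))
  guess <- toupper(substr(gsub("[0-9]", "", elety), 1, 1))
  out <- ifelse(is.na(el), guess, el)
  ifelse(out %in% c("SE"), "SE", substr(out, 1, ifelse(out == "SE", 2, 1)))
}

#' Write an atom table to PDB format
#'
#' @param struct An atom table from [parse_structure()] or the generators.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(struct, path) {
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(struct[, c("x", "y", "z")]))),
    resno = struct$resno, chain = struct$chain, resid = struct$resname,
    elety = struct$atom, o = struct$occ %||% rep(1, nrow(struct)),
    insert = struct$ins
  )
  invisible(path)
}

heavy_atoms <- function(struct) filter(struct, .data$element != "H")

#' Extract the contact interface between two chains
#'
#' A residue of chain A belongs to the interface iff any of its heavy atoms
#' lies within `contact_cutoff` (inclusive) of any heavy atom of chain B, and
#' symmetrically for chain B.
#'
#' @param struct An atom table.
#' @param chain_a,chain_b Chain identifiers present in `struct`.
#' @param contact_cutoff Heavy-atom distance cutoff in Angstrom (default 5.0).
#' @return A list with tibbles `res_a` and `res_b` (`chain`, `resno`, `ins`,
#'   `resname`), `contacts` (the residue-pair contact list) and `empty`
#'   (flag set when no contacts exist).
#' @export
extract_interface <- function(struct, chain_a, chain_b, contact_cutoff = 5.0) {
  a <- heavy_atoms(struct) |> filter(.data$chain == chain_a)
  b <- heavy_atoms(struct) |> filter(.data$chain == chain_b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    abort(paste0("chain(s) absent or empty: ", chain_a, "/", chain_b))
  }
  d <- cross_dist(as.matrix(a[, c("x", "y", "z")]),
                  as.matrix(b[, c("x", "y", "z")]))
  hit <- which(d <= contact_cutoff, arr.ind = TRUE)
  res_key <- function(df) paste(df$resno, df$ins)
  contacts <- tibble(
    resno_a = a$resno[hit[, 1]], ins_a = a$ins[hit[, 1]],
    resno_b = b$resno[hit[, 2]], ins_b = b$ins[hit[, 2]]
  ) |> distinct()
  take <- function(df, keys) {
    df |> mutate(.k = res_key(df)) |> filter(.data$.k %in% keys) |>
      distinct(.data$chain, .data$resno, .data$ins, .data$resname) |>
      arrange(.data$resno, .data$ins)
  }
  out <- list(
    res_a = take(a, unique(paste(contacts$resno_a, contacts$ins_a))),
    res_b = take(b, unique(paste(contacts$resno_b, contacts$ins_b))),
    contacts = contacts,
    empty = nrow(contacts) == 0
  )
  if (out$empty) inform(paste0("no contacts between chains ", chain_a, " and ",
                               chain_b, " at ", contact_cutoff, " A"))
  out
}

cross_dist <- function(p, q) {
  # ||p_i - q_j|| for all pairs, without forming explicit loops
  pp <- rowSums(p^2); qq <- rowSums(q^2)
  d2 <- outer(pp, qq, "+") - 2 * p %*% t(q)
  sqrt(pmax(d2, 0))
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired coordinate sets, via singular value decomposition of the
#' cross-covariance matrix with a determinant correction so the rotation is
#' never a reflection.
#'
#' @param p,q Numeric matrices (n x 3), row i of `p` paired with row i of
#'   `q`; n >= 3 and `p` must not be collinear.
#' @return A list with `rotation` (3 x 3, determinant +1), `translation`
#'   (length 3) and `rmsd`, such that `p %*% rotation + translation` best
#'   superposes `p` onto `q`.
#' @export
kabsch_superpose <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (nrow(p) != nrow(q) || ncol(p) != 3 || ncol(q) != 3) {
    abort("`p` and `q` must be equal-length n x 3 matrices")
  }
  if (nrow(p) < 3) abort("need at least 3 paired points")
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  sv <- svd(crossprod(pc, qc))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)) {
    abort("degenerate (collinear) coordinates: superposition is not unique")
  }
  s <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
  rot <- sv$u %*% s %*% t(sv$v)
  rmsd <- sqrt(mean(rowSums((pc %*% rot - qc)^2)))
  list(rotation = rot, translation = as.numeric(cq - cp %*% rot), rmsd = rmsd)
}

apply_transform <- function(coords, transform) {
  sweep(as.matrix(coords) %*% transform$rotation, 2, -transform$translation)
}

#' Template-modelling score of an alignment
#'
#' `TM = (1 / L_norm) * sum_i 1 / (1 + (d_i / d0)^2)` over aligned residue
#' pairs with distances `d_i`, where `d0 = 1.24 (L_norm - 15)^(1/3) - 1.8`,
#' floored at 0.5 A. Values above 0.5 indicate a shared fold.
#'
#' @param p,q Superposed paired coordinate matrices (n x 3), or pass
#'   `superpose = TRUE` to Kabsch-superpose first.
#' @param l_norm Normalization length (>= number of aligned pairs). In the
#'   redundancy-clustering context this is the length of the longer
#'   structure.
#' @param superpose If `TRUE`, optimally superpose `p` onto `q` first.
#' @return A number in (0, 1].
#' @export
tm_score <- function(p, q, l_norm, superpose = FALSE) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (nrow(p) < 3) abort("need at least 3 aligned pairs")
  if (l_norm < nrow(p)) abort("`l_norm` must be >= the number of aligned pairs")
  if (superpose) {
    tr <- kabsch_superpose(p, q)
    p <- apply_transform(p, tr)
  }
  d0 <- 1.24 * (l_norm - 15)^(1/3) - 1.8
  if (is.na(d0) || d0 < 0.5) {
    d0 <- 0.5
    inform("tm_score: short normalization length, d0 floored at 0.5 A")
  }
  di <- sqrt(rowSums((p - q)^2))
  sum(1 / (1 + (di / d0)^2)) / l_norm
}

ca_table <- function(struct) {
  struct |> filter(.data$atom == "CA") |> arrange(.data$chain, .data$resno, .data$ins)
}

#' Cluster redundant structures of the same protein
#'
#' Pairs of structures are compared on their common C-alpha residues
#' (matched by chain and residue number) after optimal superposition; two
#' structures are redundant when TM-score > 0.5 (normalized by the longer of
#' the two) and RMSD < 2.5 A. Redundancy groups are single-linkage
#' components of this relation, and each group's representative is its
#' longest structure (ties broken by the lexicographically smallest id).
#' Pairs with fewer than 3 common residues are treated as dissimilar.
#'
#' @param structures Named list of atom tables.
#' @param tm_cutoff,rmsd_cutoff Redundancy thresholds (defaults 0.5 and 2.5).
#' @return A tibble (`id`, `n_residues`, `cluster`, `representative`).
#' @export
cluster_redundant <- function(structures, tm_cutoff = 0.5, rmsd_cutoff = 2.5) {
  if (length(structures) == 0) abort("no structures to cluster")
  if (is.null(names(structures)) || any(!nzchar(names(structures)))) {
    abort("`structures` must be a named list")
  }
  ids <- names(structures)
  cas <- map(structures, ca_table)
  lens <- map_int(cas, nrow)

  similar <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  if (length(ids) > 1) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq(i + 1, length(ids))) {
        m <- inner_join(cas[[i]], cas[[j]], by = c("chain", "resno", "ins"),
                        suffix = c("_i", "_j"))
        if (nrow(m) < 3) {
          inform(sprintf("cluster_redundant: %s vs %s unalignable (<3 common residues)",
                         ids[i], ids[j]))
          next
        }
        p <- as.matrix(m[, c("x_i", "y_i", "z_i")])
        q <- as.matrix(m[, c("x_j", "y_j", "z_j")])
        tr <- tryCatch(kabsch_superpose(p, q), error = function(e) NULL)
        if (is.null(tr)) next
        tm <- tm_score(apply_transform(p, tr), q, l_norm = max(lens[i], lens[j]))
        similar[i, j] <- similar[j, i] <- tm > tm_cutoff && tr$rmsd < rmsd_cutoff
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(similar, mode = "undirected")
  cl <- igraph::components(g)$membership
  tibble(id = ids, n_residues = unname(lens), cluster = unname(cl[ids])) |>
    group_by(.data$cluster) |>
    mutate(representative = .data$id ==
             .data$id[order(-.data$n_residues, .data$id)][1]) |>
    ungroup() |>
    arrange(.data$cluster, desc(.data$representative), .data$id)
}
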