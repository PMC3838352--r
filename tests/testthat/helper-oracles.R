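# Independent oracles and small builders shared across the suite.

# rank-based AUROC
auroc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# brute-force partition of records by repeated pairwise merging on shared keys
oracle_unify <- function(records) {
  keysets <- lapply(seq_len(nrow(records)), function(i) {
    accs <- strsplit(records$uniprot_accessions[i], ";")[[1]]
    accs <- accs[nzchar(accs)]
    keys <- c(paste0("a:", accs),
              if (nzchar(records$sequence[i])) paste0("s:", toupper(records$sequence[i])),
              if (nzchar(records$gene_id[i])) paste0("g:", records$gene_id[i]))
    keys
  })
  groups <- as.list(seq_len(nrow(records)))
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      if (is.null(groups[[i]])) next
      for (j in seq_along(groups)) {
        if (j <= i || is.null(groups[[j]])) next
        ki <- unique(unlist(keysets[groups[[i]]]))
        kj <- unique(unlist(keysets[groups[[j]]]))
        if (length(intersect(ki, kj)) > 0) {
          groups[[i]] <- c(groups[[i]], groups[[j]])
          groups[j] <- list(NULL)   # keep list length stable while merging
          merged <- TRUE
        }
      }
    }
    if (!merged) break
  }
  Filter(Negate(is.null), groups)
}

# plain BFS connected components over an edge list (no igraph)
oracle_components <- function(node_ids, from, to) {
  adj <- setNames(vector("list", length(node_ids)), node_ids)
  for (i in seq_along(from)) {
    adj[[from[i]]] <- c(adj[[from[i]]], to[i])
    adj[[to[i]]] <- c(adj[[to[i]]], from[i])
  }
  comp <- setNames(rep(NA_integer_, length(node_ids)), node_ids)
  cur <- 0L
  for (start in node_ids) {
    if (!is.na(comp[[start]])) next
    cur <- cur + 1L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[[v]])) next
      comp[[v]] <- cur
      queue <- c(queue, adj[[v]])
    }
  }
  comp
}

# quaternion (Horn) absolute-orientation oracle for optimal-superposition RMSD
oracle_rmsd_quaternion <- function(p, q) {
  pc <- sweep(p, 2, colMeans(p)); qc <- sweep(q, 2, colMeans(q))
  M <- crossprod(pc, qc)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,      Szx-Sxz,      Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz,  Sxy+Syx,      Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz,  Syz+Szy,
    Sxy-Syx,     Szx+Sxz,      Syz+Szy,     -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE)$values)
  e2 <- (sum(pc^2) + sum(qc^2) - 2 * lambda) / nrow(p)
  sqrt(max(e2, 0))
}

# combinatorial upper-tail hypergeometric via explicit binomial sums
oracle_hyper_upper <- function(k, n, K, N) {
  if (k == 0) return(1)
  js <- k:min(n, K)
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# two-tailed Fisher p by full enumeration of tables with fixed margins
oracle_fisher_two_tailed <- function(tab) {
  m <- sum(tab[1, ]); K <- sum(tab[, 1]); N <- sum(tab)
  support <- max(0, K + m - N):min(m, K)
  probs <- choose(K, support) * choose(N - K, m - support) / choose(N, m)
  obs <- choose(K, tab[1, 1]) * choose(N - K, m - tab[1, 1]) / choose(N, m)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# tiny protein-record table linked A-B by accession and B-C by sequence
make_record_chain <- function() {
  tibble::tibble(
    source_db = c("dip", "hprd", "mint"),
    local_id = c("r1", "r2", "r3"),
    uniprot_accessions = c("P10000", "P10000;P20000", ""),
    sequence = c("", "MKVLAT", "MKVLAT"),
    gene_id = c("", "", "9999")
  )
}

make_path_network <- function(ids = c("a", "b", "c")) {
  ppi_network(tibble::tibble(node_id = ids),
              tibble::tibble(from = ids[-length(ids)], to = ids[-1]))
}

make_star_network <- function(n_leaves = 6) {
  leaves <- sprintf("L%02d", seq_len(n_leaves))
  ppi_network(tibble::tibble(node_id = c("hub", leaves)),
              tibble::tibble(from = rep("hub", n_leaves), to = leaves))
}

# helix with varied residue names so sequence alignments are unambiguous
make_varied_helix <- function(n_res = 30, chain = "A", seed = 42) {
  aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  set.seed(seed)
  resnames <- sample(aa3, n_res, replace = TRUE)
  cx <- gen_complex(n_res = n_res, gap = 40, id = "varied")
  at <- dplyr::filter(cx$atoms, chain == "A")
  at$chain <- chain
  at$resname <- resnames[match(at$resno, sort(unique(at$resno)))]
  at
}
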