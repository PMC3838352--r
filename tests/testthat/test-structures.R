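pdb_line <- function(serial, name, resn, chain, resno, x, y, z, occ = 1,
                     alt = " ", el = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resn, chain, resno, x, y, z, occ, 0, el)
}

test_that("parse_structure round-trips generated complexes and applies the altloc rule", {
  cx <- gen_complex(n_res = 12, gap = 4.0)
  tmp <- tempfile(fileext = ".pdb")
  write_structure(cx$atoms, tmp)
  parsed <- parse_structure(tmp)
  expect_setequal(unique(parsed$chain), c("A", "B"))
  expect_equal(nrow(dplyr::distinct(parsed, chain, resno)), 24)
  expect_equal(nrow(parsed), nrow(cx$atoms))

  # altloc A at 0.6 beats B at 0.4; HETATM water excluded
  txt <- paste(c(
    pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "ALA", "A", 1, 1.0, 0, 0, occ = 0.6, alt = "A"),
    pdb_line(3, "CA", "ALA", "A", 1, 9.0, 0, 0, occ = 0.4, alt = "B"),
    pdb_line(4, "C", "ALA", "A", 1, 2.0, 0, 0),
    sub("^ATOM  ", "HETATM", pdb_line(5, "O", "HOH", "A", 90, 8, 8, 8)),
    "END"), collapse = "\n")
  s <- parse_structure(txt)
  ca <- s[s$atom == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1.0)
  expect_false("HOH" %in% s$resname)

  expect_error(parse_structure("REMARK nothing here\nEND"), "ATOM")
})

test_that("interface extraction matches brute-force distances, with inclusive boundary", {
  cx <- gen_complex(n_res = 20, gap = 4.5)
  iface <- extract_interface(cx$atoms, "A", "B")
  expect_identical(sort(iface$res_a$resno), cx$truth$res_a)
  expect_identical(sort(iface$res_b$resno), cx$truth$res_b)

  far <- gen_complex(n_res = 20, gap = 50)
  expect_message(ifar <- extract_interface(far$atoms, "A", "B"), "no contacts")
  expect_true(ifar$empty)
  expect_equal(nrow(ifar$res_a), 0)

  # one atom pair exactly at the cutoff is included
  two <- tibble::tibble(
    chain = c("A", "B"), resno = c(1L, 1L), ins = "", resname = "ALA",
    atom = "CA", element = "C", x = c(0, 5), y = 0, z = 0, occ = 1
  )
  ii <- extract_interface(two, "A", "B", contact_cutoff = 5.0)
  expect_equal(nrow(ii$res_a), 1)
})

test_that("Kabsch superposition is exact on rigid copies and agrees with a quaternion oracle", {
  set.seed(4)
  p <- matrix(rnorm(36), ncol = 3)

  self <- kabsch_superpose(p, p)
  expect_lt(self$rmsd, 1e-10)
  expect_equal(self$rotation, diag(3), tolerance = 1e-8)

  for (i in 1:20) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    q <- p %*% t(R) + matrix(rnorm(3, sd = 10), nrow(p), 3, byrow = TRUE)
    fit <- kabsch_superpose(p, q)
    expect_lt(fit$rmsd, 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
    expect_lt(max(abs(p %*% fit$rotation +
                        matrix(fit$translation, nrow(p), 3, byrow = TRUE) - q)), 1e-8)
  }

  # perturbed 4-point set: optimal RMSD equals the quaternion-method value
  p4 <- matrix(c(0, 0, 0, 3, 0, 0, 0, 4, 0, 1, 1, 5), ncol = 3, byrow = TRUE)
  q4 <- p4; q4[4, ] <- q4[4, ] + c(0.8, -0.4, 0.3)
  fit4 <- kabsch_superpose(p4, q4)
  expect_equal(fit4$rmsd, oracle_rmsd_quaternion(p4, q4), tolerance = 1e-10)

  collinear <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(collinear, collinear), "degenerate")
})

test_that("TM-score follows its closed form and direct-summation oracle", {
  cx <- gen_complex(n_res = 40, gap = 40)
  ca <- dplyr::filter(cx$atoms, chain == "A", atom == "CA")
  p <- as.matrix(ca[, c("x", "y", "z")])
  expect_equal(tm_score(p, p, l_norm = 40), 1.0)

  # all distances equal to d0 give 0.5 * pairs / L
  d0 <- 1.24 * (40 - 15)^(1/3) - 1.8
  q <- p; q[, 1] <- q[, 1] + d0
  expect_equal(tm_score(p, q, l_norm = 40), 0.5)
  l2 <- 50
  d0b <- 1.24 * (l2 - 15)^(1/3) - 1.8
  qb <- p; qb[, 1] <- qb[, 1] + d0b
  expect_equal(tm_score(p, qb, l_norm = l2), 0.5 * 40 / 50)

  # kinked copy scores as the brute-force sum says
  kink <- p
  kink[21:40, ] <- kink[21:40, ] %*% matrix(c(cos(0.3), 0, sin(0.3),
                                              0, 1, 0,
                                              -sin(0.3), 0, cos(0.3)), 3, 3)
  di <- sqrt(rowSums((p - kink)^2))
  expect_equal(tm_score(p, kink, l_norm = 40),
               sum(1 / (1 + (di / d0)^2)) / 40, tolerance = 1e-12)

  # symmetry at fixed normalization length
  expect_equal(tm_score(p, kink, l_norm = 45), tm_score(kink, p, l_norm = 45))

  # short-alignment floor
  expect_message(tm <- tm_score(p[1:5, ], p[1:5, ], l_norm = 16), "floored")
  expect_equal(tm, 5 / 16)
})

test_that("redundancy clustering groups by TM > 0.5 and RMSD < 2.5 with single linkage", {
  cx <- gen_complex(n_res = 30, gap = 40)
  helix <- dplyr::filter(cx$atoms, chain == "A")

  # identical copies collapse to one cluster
  cl <- cluster_redundant(list(s1 = helix, s2 = helix))
  expect_equal(length(unique(cl$cluster)), 1)
  expect_equal(sum(cl$representative), 1)

  # graded deformation: A~B and B~C but A is too far from C
  set.seed(8)
  delta <- matrix(rnorm(nrow(helix) * 3, sd = 0.75), ncol = 3)
  shift <- function(at, d) {
    at$x <- at$x + d[, 1]; at$y <- at$y + d[, 2]; at$z <- at$z + d[, 3]; at
  }
  A <- helix; B <- shift(helix, delta); C <- shift(helix, 2 * delta)
  cl3 <- cluster_redundant(list(A = A, B = B, C = C))
  expect_equal(length(unique(cl3$cluster)), 1)   # single linkage chains them

  # unrelated folds (helix vs zig-zag strand) stay apart
  n <- 30
  strand <- helix
  strand$x <- 3.3 * seq_len(nrow(strand)) / 5
  strand$y <- rep(c(0, 1), length.out = nrow(strand))
  strand$z <- 0.1 * seq_len(nrow(strand))
  cl2 <- cluster_redundant(list(helix = helix, strand = strand))
  expect_equal(length(unique(cl2$cluster)), 2)

  # every structure lands in exactly one cluster; longest is representative
  mixed <- list(long = helix, short = dplyr::filter(helix, resno <= 20))
  clm <- cluster_redundant(mixed)
  expect_setequal(clm$id, c("long", "short"))
  expect_equal(clm$id[clm$representative][1], "long")
})
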