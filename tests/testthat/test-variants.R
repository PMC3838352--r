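test_that("residue maps recover substring offsets and reject unrelated sequences", {
  helix <- make_varied_helix(30)
  chain_seq <- paste(sapply(dplyr::filter(helix, atom == "CA")$resname,
                            function(r) c(ALA="A",ARG="R",ASN="N",ASP="D",CYS="C",
                                          GLN="Q",GLU="E",GLY="G",HIS="H",ILE="I",
                                          LEU="L",LYS="K",MET="M",PHE="F",PRO="P",
                                          SER="S",THR="T",TRP="W",TYR="Y",VAL="V")[r]),
                     collapse = "")
  full <- paste0("MSTAY", chain_seq, "KLHNE")   # chain is an interior substring
  rm <- map_residues(full, helix, "A")
  expect_equal(rm$identity, 1.0)
  expect_equal(nrow(rm$map), 30)
  expect_equal(rm$map$position, 6:35)           # offset of 5
  expect_equal(rm$map$resno, 1:30)

  # one point difference: still mapped, identity just below 1
  mutated <- full
  substr(mutated, 10, 10) <- if (substr(full, 10, 10) == "A") "W" else "A"
  rm2 <- map_residues(mutated, helix, "A")
  expect_lt(rm2$identity, 1.0)
  expect_gte(rm2$identity, 29 / 30)

  # unrelated random sequence is rejected
  set.seed(5)
  junk <- paste(sample(c("D", "E", "K", "R", "H", "Q", "N"), 40, TRUE),
                collapse = "")
  expect_error(map_residues(junk, helix, "A"), "identity")
  expect_error(map_residues("MKV", helix, "A"), "shorter")
})

test_that("sampled accessibility matches closed-form sphere results", {
  # a lone sulfur-like atom: ASA = 4 pi (r + probe)^2
  one <- tibble::tibble(chain = "A", resno = 1L, ins = "", resname = "ALA",
                        atom = "S", element = "S", x = 0, y = 0, z = 0, occ = 1)
  vdw <- 1.80
  got <- compute_asa(one, probe_radius = 1.4, n_points = 960)$asa
  expect_equal(got, 4 * pi * (vdw + 1.4)^2, tolerance = 0.02)

  # two identical partially overlapping spheres: analytic cap formula
  d <- 2.0
  two <- dplyr::bind_rows(one, dplyr::mutate(one, resno = 2L, x = d))
  r <- vdw + 1.4
  cap <- 2 * pi * r * (r - d / 2)               # buried cap on each sphere
  expected <- 4 * pi * r^2 - cap
  got2 <- compute_asa(two, probe_radius = 1.4, n_points = 960)
  expect_equal(got2$asa, rep(expected, 2), tolerance = 0.03)

  # convergence: doubling the sampling from the default changes residue ASA
  # by < 2% on the two-chain fixture, and relative accessibility by < 2
  # percentage points on the tightly packed bundle
  cxc <- gen_complex(n_res = 20, gap = 3.5)
  a1 <- compute_asa(cxc$atoms, n_points = 960)$asa
  a2 <- compute_asa(cxc$atoms, n_points = 1920)$asa
  expect_lt(max(abs(a1 - a2) / pmax(a2, 1)), 0.02)
  glob <- gen_globule()
  g1 <- relative_asa(compute_asa(glob, n_points = 960))$rasa
  g2 <- relative_asa(compute_asa(glob, n_points = 1920))$rasa
  expect_lt(max(abs(g1 - g2)), 2)

  # the bundle interior is buried
  rasa <- relative_asa(compute_asa(glob, n_points = 480))
  expect_gt(sum(rasa$rasa < 5), 0)
  expect_lt(min(rasa$asa), 2)
})

test_that("location classification applies interface precedence and the inclusive surface boundary", {
  expect_equal(classify_location(0.0, FALSE), "core")
  expect_equal(classify_location(40, TRUE), "interface")
  expect_equal(classify_location(5.0, FALSE), "surface")
  expect_equal(classify_location(4.99, FALSE), "core")
})

test_that("variant location calls partition the input and recover generator truth", {
  cx <- gen_complex(n_res = 30, gap = 3.5, id = "vt")
  chain_a <- dplyr::filter(cx$atoms, chain == "A")
  rasa <- relative_asa(compute_asa(chain_a, n_points = 480))
  glob <- gen_globule()
  rasa_g <- relative_asa(compute_asa(glob, n_points = 480))

  build_protein <- function(struct, chain, rasa_tbl, iface) {
    cs_ca <- dplyr::filter(struct, atom == "CA", chain == !!chain)
    seq <- paste(rep("A", nrow(cs_ca)), collapse = "")
    info <- dplyr::mutate(rasa_tbl, in_interface = resno %in% iface)
    list(sequence = seq,
         locations = list(
           interface = which(cs_ca$resno %in% iface),
           surface = which(!(cs_ca$resno %in% iface) & info$rasa >= 5),
           core = which(!(cs_ca$resno %in% iface) & info$rasa < 5)
         ),
         info = info)
  }
  p1 <- build_protein(cx$atoms, "A", rasa, cx$truth$res_a)
  p2 <- build_protein(glob, "G", rasa_g, integer(0))
  proteins <- list(VP1 = p1, VP2 = p2)

  variants <- gen_variants(250, proteins, rng_seed = 10)
  maps <- list(VP1 = map_residues(p1$sequence, cx$atoms, "A"),
               VP2 = map_residues(p2$sequence, glob, "G"))
  infos <- list(VP1 = p1$info, VP2 = p2$info)
  res <- locate_variants(variants, maps, infos)

  expect_equal(sum(unlist(res$counts)), 250)            # calls partition input
  expect_identical(res$calls$location, variants$truth_location)  # exact recovery
  expect_equal(res$counts$n_mismatch, 0)

  # observed proportions sit within sampling error of the placement law
  probs <- c(core = 0.35, surface = 0.58, interface = 0.07)
  obs <- c(res$counts$n_core, res$counts$n_surface_noninterface,
           res$counts$n_interface)
  se <- sqrt(probs * (1 - probs) * 250)
  expect_true(all(abs(obs - 250 * probs) <= 4 * se))

  # all-interface placement gives all-interface calls
  vi <- gen_variants(40, proteins,
                     location_probs = c(core = 0, surface = 0, interface = 1),
                     rng_seed = 11)
  ri <- locate_variants(vi, maps, infos)
  expect_equal(ri$counts$n_interface, 40)

  # a variant beyond structural coverage is unmapped
  outside <- tibble::tibble(accession = "VP1", position = 2000L, wt = "A",
                            mut = "V", class = "disease", source = "humsavar")
  expect_warning(out <- locate_variants(outside, maps, infos), "beyond")
  expect_equal(out$counts$n_unmapped, 1)

  # wild-type disagreement is flagged and excluded from location counts
  wrong <- tibble::tibble(accession = "VP1", position = 5L, wt = "W",
                          mut = "V", class = "disease", source = "cosmic")
  suppressMessages(mm <- locate_variants(wrong, maps, infos))
  expect_equal(mm$counts$n_mismatch, 1)
  expect_equal(mm$calls$location, "mismatch")
})

test_that("the Fisher location-preference test keeps size and detects planted interface excess", {
  residue_counts <- tibble::tibble(n_interface = 30,
                                   n_surface_noninterface = 170, n_core = 100)
  # balanced variants against availability give p = 1 on proportional counts
  bal <- location_preference_test(
    tibble::tibble(n_interface = 3, n_surface_noninterface = 17, n_core = 10),
    residue_counts
  )
  expect_equal(bal$p, 1.0, tolerance = 1e-9)

  draw_counts <- function(p_iface, n = 300) {
    loc <- sample(c("i", "s"), n, replace = TRUE,
                  prob = c(p_iface, 1 - p_iface))
    tibble::tibble(n_interface = sum(loc == "i"),
                   n_surface_noninterface = sum(loc == "s"), n_core = 0)
  }
  p_avail <- 30 / 200
  set.seed(41)
  type1 <- replicate(200, {
    location_preference_test(draw_counts(p_avail), residue_counts)$p
  })
  expect_gte(mean(type1 > 0.05), 0.93)

  # interface odds raised fivefold
  p_alt <- 5 * p_avail / (1 - p_avail + 5 * p_avail)
  power <- replicate(200, {
    location_preference_test(draw_counts(p_alt), residue_counts)$p
  })
  expect_gte(mean(power < 0.05), 0.80)

  # convention switch uses core counts too
  alt <- location_preference_test(
    tibble::tibble(n_interface = 3, n_surface_noninterface = 17, n_core = 10),
    residue_counts, convention = "all_mapped"
  )
  expect_equal(sum(alt$table["residues", ]), 300)
})

test_that("hot-spot calls require burial and favorable contacts, and stay inside the interface", {
  # tight complex with a buried tryptophan-rich contact core
  subs <- tibble::tibble(
    chain = rep(c("A", "B"), each = 3),
    resno = rep(c(8, 12, 15), 2),
    resname = c("TRP", "TRP", "ILE", "ILE", "TRP", "PHE")
  )
  cx <- gen_complex(n_res = 30, gap = 3.0, substitutions = subs, id = "hs")
  mdl <- structure(list(atoms = cx$atoms, pair = c("a", "b"),
                        template_id = "hs00AB", rmsd = c(0, 0),
                        coverage = c(1, 1), n_clashes = 0, accepted = TRUE,
                        energy = NA_real_), class = "complex_model")
  hs <- predict_hotspots(mdl, n_points = 480)
  iface <- extract_interface(cx$atoms, "A", "B")
  iface_keys <- c(paste("A", iface$res_a$resno), paste("B", iface$res_b$resno))

  # flags are a subset of interface residues
  expect_true(all(paste(hs$chain, hs$resno) %in% iface_keys))
  # the buried contact-rich tryptophan is flagged
  expect_true(any(hs$hotspot & hs$resname == "TRP"))
  # exposed residues are never flagged
  expect_true(all(hs$rasa_complex[hs$hotspot] <= 20))

  # an empty interface yields no flags
  far <- gen_complex(n_res = 15, gap = 50)
  mdl_far <- mdl; mdl_far$atoms <- far$atoms
  suppressMessages(hs_far <- predict_hotspots(mdl_far, n_points = 240))
  expect_equal(nrow(hs_far), 0)
})
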