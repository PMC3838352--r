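test_that("netscore follows the message-passing update rule on a 3-node path", {
  # hand-run: init (1, .01, .01); two iterations of s <- (s + nbr mean)/2 give
  # (0.38125, 0.2575, 0.13375); the seed is then re-set to 1 and min-max
  # normalization maps b to 0.12375/0.86625 and c to 0
  net <- make_path_network(c("a", "b", "c"))
  sc <- netscore(net, "a", n_repetitions = 1, n_iterations = 2)
  s <- setNames(sc$score, sc$node_id)
  expect_equal(unname(s["a"]), 1)
  expect_equal(unname(s["b"]), 0.12375 / 0.86625, tolerance = 1e-12)
  expect_equal(unname(s["c"]), 0)
  expect_gt(s["b"], s["c"])
})

test_that("netscore respects symmetry and handles the all-seed degenerate case", {
  star <- make_star_network(6)
  sc <- netscore(star, "hub")
  s <- setNames(sc$score, sc$node_id)
  expect_equal(unname(s["hub"]), max(s))
  leaves <- s[startsWith(names(s), "L")]
  expect_true(all(abs(leaves - leaves[1]) < 1e-12))

  expect_warning(all_seeds <- netscore(star, star$nodes$node_id), "degenerate")
  expect_true(all(all_seeds$score == 1))
})

test_that("netzcore is reproducible, zeroes invariant networks, and is stable in the replicate count", {
  tri <- ppi_network(tibble::tibble(node_id = c("a", "b", "c")),
                     tibble::tibble(from = c("a", "a", "b"), to = c("b", "c", "c")))
  # a triangle is invariant under degree-preserving swaps: no variance, all z = 0
  suppressMessages(expect_warning(sc <- netzcore(tri, "a", n_random_networks = 10),
                                  "degenerate"))
  expect_true(all(sc$score == sc$score[1]))

  sim <- gen_network(n_nodes = 150, attachment = 4, module_size = 12, rng_seed = 5)
  net <- major_component(sim$network)
  seeds <- intersect(sim$seeds, net$nodes$node_id)
  z1 <- suppressMessages(netzcore(net, seeds, n_random_networks = 100, rng_seed = 9))
  z2 <- suppressMessages(netzcore(net, seeds, n_random_networks = 100, rng_seed = 9))
  expect_identical(z1$score, z2$score)

  # seed-adjacent module nodes outrank the module-external median
  s <- setNames(z1$score, z1$node_id)
  withheld <- intersect(sim$withheld, names(s))
  outside <- setdiff(names(s), sim$module)
  expect_gt(mean(s[withheld]), median(s[outside]))

  # doubling the randomization count moves normalized scores by < 0.1
  z3 <- suppressMessages(netzcore(net, seeds, n_random_networks = 200, rng_seed = 9))
  expect_lt(max(abs(z1$score - z3$score)), 0.1)
})

test_that("netshort favours nodes central to the seed set", {
  # seeds at both ends of a 5-path: the middle node beats quarter positions
  path <- make_path_network(c("a", "b", "c", "d", "e"))
  sc <- netshort(path, c("a", "e"))
  s <- setNames(sc$score, sc$node_id)
  # hand computation with edge lengths 1/(1+seed_u+seed_v):
  # d(c, seeds) = 1.5 both, d(b, a) = 0.5, d(b, e) = 2.5
  expect_gt(s["c"], s["b"])
  expect_equal(unname(s["b"]), unname(s["d"]))

  # seed clique plus pendant: pendant lowest
  net <- ppi_network(
    tibble::tibble(node_id = c("s1", "s2", "s3", "pend")),
    tibble::tibble(from = c("s1", "s1", "s2", "s3"),
                   to = c("s2", "s3", "s3", "pend"))
  )
  sc2 <- netshort(net, c("s1", "s2", "s3"))
  expect_equal(sc2$node_id[which.min(sc2$score)], "pend")

  # no resolvable seeds: degenerate uniform scores, loudly
  suppressWarnings(sc3 <- netshort(path, "not_a_node"))
  expect_true(all(sc3$score == 1))
})

test_that("netcombo standardizes and combines the three component methods", {
  sim <- gen_network(n_nodes = 200, attachment = 4, module_size = 14, rng_seed = 3)
  net <- major_component(sim$network)
  seeds <- intersect(sim$seeds, net$nodes$node_id)
  nc <- suppressMessages(netcombo(net, seeds, n_random_networks = 50, rng_seed = 3))
  expect_true(all(nc$score >= 0 & nc$score <= 1))
  expect_equal(attr(nc, "method"), "netcombo")

  # seeds rank in the top quartile
  s <- setNames(nc$score, nc$node_id)
  expect_gte(min(rank(-s)[seeds] <= length(s) / 4), 1)

  # combination is no worse than the worst single method at ranking the module
  withheld <- intersect(sim$withheld, names(s))
  outside <- setdiff(names(s), sim$module)
  parts <- list(
    netscore(net, seeds),
    suppressMessages(netzcore(net, seeds, n_random_networks = 50, rng_seed = 3)),
    netshort(net, seeds)
  )
  worst <- min(sapply(parts, function(p) {
    v <- setNames(p$score, p$node_id)
    auroc(v[withheld], v[outside])
  }))
  expect_gte(auroc(s[withheld], s[outside]), worst)
})

test_that("edge scores are exact endpoint means and stay within node-score bounds", {
  net <- make_path_network(c("a", "b", "c"))
  sc <- tibble::tibble(node_id = c("a", "b", "c"), score = c(0.2, 0.4, 1.0),
                       is_seed = FALSE)
  es <- score_edges(net, sc)
  expect_equal(es$score, c(0.3, 0.7))
  expect_true(all(es$score >= min(sc$score) & es$score <= max(sc$score)))

  missing <- sc[1:2, ]
  expect_error(score_edges(net, missing), "unscored")
})

test_that("threshold scan counts strictly-above edges and is monotone", {
  set.seed(21)
  ids <- sprintf("n%02d", 1:30)
  net <- ppi_network(tibble::tibble(node_id = ids),
                     tibble::tibble(from = sample(ids[1:15], 40, TRUE),
                                    to = sample(ids[16:30], 40, TRUE)))
  sc <- tibble::tibble(node_id = ids, score = runif(30), is_seed = FALSE)
  es <- score_edges(net, sc)
  curve <- threshold_scan(es, seq(0, 1, 0.05))
  expect_true(all(diff(curve$n_edges) <= 0))
  expect_true(all(diff(curve$n_nodes) <= 0))
  expect_equal(curve$n_edges[1], sum(es$score > 0))
  expect_equal(curve$n_edges[nrow(curve)], 0)
  expect_equal(curve$n_nodes[nrow(curve)], 0)
  expect_error(threshold_scan(es, c(0.5, 0.1)), "sorted")
})

test_that("extract_subnetwork keeps strictly-above edges and their endpoints only", {
  net <- make_path_network(c("a", "b", "c", "d"))
  es <- score_edges(net, tibble::tibble(node_id = c("a", "b", "c", "d"),
                                        score = c(0.1, 0.3, 0.5, 0.7),
                                        is_seed = FALSE))
  # edge scores: ab = 0.2, bc = 0.4, cd = 0.6
  sub <- extract_subnetwork(net, es, 0.4)   # boundary edge bc excluded
  expect_equal(nrow(sub$edges), 1)
  expect_setequal(sub$nodes$node_id, c("c", "d"))
  full <- extract_subnetwork(net, es, 0)
  expect_equal(nrow(full$edges), 3)
  expect_warning(extract_subnetwork(net, es, 0.99), "empty")
})

test_that("a calibrated cutoff on the planted-module simulation keeps mostly module nodes", {
  sim <- gen_network(rng_seed = 2)
  net <- major_component(sim$network)
  sc <- suppressMessages(netcombo(net, intersect(sim$seeds, net$nodes$node_id),
                                  rng_seed = 2))
  es <- score_edges(net, sc)
  # calibrate the cutoff to retain about twice as many edges as module nodes
  cutoff <- sort(es$score, decreasing = TRUE)[2 * length(sim$module)]
  sub <- extract_subnetwork(net, es, cutoff)
  expect_gte(mean(sub$nodes$node_id %in% sim$module), 0.8)
})

test_that("hub calling uses the inclusive degree-12 rule", {
  leaves12 <- sprintf("m%02d", 1:12)
  net <- ppi_network(tibble::tibble(node_id = c("ctr", leaves12)),
                     tibble::tibble(from = "ctr", to = leaves12))
  expect_identical(find_hubs(net), "ctr")           # degree 12 is a hub
  net11 <- ppi_network(tibble::tibble(node_id = c("ctr", leaves12[1:11])),
                       tibble::tibble(from = "ctr", to = leaves12[1:11]))
  expect_length(find_hubs(net11), 0)                # degree 11 is not
  star <- make_star_network(15)
  expect_identical(find_hubs(star, min_degree = 12), "hub")
})

test_that("average degree is 2E/V to one decimal", {
  expect_equal(average_degree(list(n_nodes = 2, n_edges = 1)), 1.0)
  net <- make_path_network(c("a", "b", "c"))
  expect_equal(average_degree(net), round(2 * 2 / 3, 1))
})
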