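test_that("edges require the shared-feature threshold", {
  lex <- toy_lexicon()
  net2 <- build_network(c("w1", "w2", "w3"), lex, min_shared = 2)
  expect_setequal(apply(network_edges(net2), 1, paste, collapse = "-"),
                  "w1-w2")
  net1 <- build_network(c("w1", "w2", "w3"), lex, min_shared = 1)
  expect_setequal(apply(network_edges(net1), 1, paste, collapse = "-"),
                  c("w1-w2", "w1-w3"))
  single <- build_network("w1", lex)
  expect_equal(network_size(single), 1)
  expect_equal(nrow(network_edges(single)), 0)
  expect_warning(empty <- build_network("unknown", lex), "empty network")
  expect_equal(network_size(empty), 0)
})

test_that("lexicon lookup is case-folded and duplicates collapse", {
  net <- build_network(c(" W1 ", "w1", "W2"), toy_lexicon())
  expect_setequal(net$nodes, c("w1", "w2"))
  expect_equal(nrow(network_edges(net)), 1)
})

test_that("the worked four-noun example reproduces its printed measures", {
  net <- example_network()
  expect_equal(network_size(net), 4)
  expect_equal(nrow(network_edges(net)), 5)
  expect_equal(unname(node_degree(net)["eye"]), 3)
  expect_equal(path_length(net, "apple", "balloon"), 2)
  expect_equal(round_half_up(unname(local_clustering(net)["eye"]), 2), 0.67)
  m <- compute_all_metrics(net)
  expect_equal(round_half_up(m$MPL, 2), 1.17)
  expect_equal(m$MPL, 7 / 6)
  expect_equal(round_half_up(m$GCC, 2), 0.83)
  expect_equal(m$MD, 2.5)
  expect_equal(m$meanBC, 0.25)
  expect_equal(m$meanHC, 11 / 12)
  expect_equal(m$quality_flag, "ok")
})

test_that("transitivity variant differs from mean-local on the example", {
  net <- example_network()
  expect_equal(global_clustering(net, "transitivity"), 0.75)
  expect_equal(global_clustering(net, "mean-local"), 5 / 6)
})

test_that("hand-checked small graphs", {
  tri <- semnet(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c"),
                                        c("a", "c")))
  expect_equal(mean_path_length(tri), 1)
  expect_equal(global_clustering(tri), 1)
  expect_equal(mean_harmonic_centrality(tri), 1)

  path <- semnet(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  expect_equal(mean_path_length(path), 4 / 3)
  expect_equal(global_clustering(path), 0)
  expect_equal(mean_betweenness(path), 1 / 3)

  k4 <- semnet(letters[1:4], t(utils::combn(letters[1:4], 2)))
  expect_equal(mean_betweenness(k4), 0)

  star <- semnet(c("h", "l1", "l2", "l3"),
                 cbind("h", c("l1", "l2", "l3")))
  expect_equal(mean_degree(star), 1.5)

  iso <- semnet(c("a", "b", "c"))
  expect_equal(mean_harmonic_centrality(iso), 0)
  expect_equal(mean_path_length(iso), 0)
})

test_that("empty and singleton networks return all-zero flagged metrics", {
  e <- compute_all_metrics(semnet(character(0)))
  expect_equal(unlist(e[c("MPL", "GCC", "MD", "meanBC", "meanHC")]),
               c(MPL = 0, GCC = 0, MD = 0, meanBC = 0, meanHC = 0))
  expect_equal(e$quality_flag, "empty")
  s <- compute_all_metrics(semnet("solo"))
  expect_equal(unlist(s[c("MPL", "GCC", "MD", "meanBC", "meanHC")]),
               c(MPL = 0, GCC = 0, MD = 0, meanBC = 0, meanHC = 0))
  expect_equal(s$quality_flag, "singleton")
  edgeless <- compute_all_metrics(semnet(c("a", "b")))
  expect_equal(edgeless$quality_flag, "no_edges")
})

test_that("metrics match brute-force oracles on random graphs", {
  cases <- expand.grid(n = c(2, 4, 6, 8, 10, 12), p = seq(0.1, 0.9, 0.2))
  reps <- ceiling(200 / nrow(cases))
  cnt <- 0
  for (i in seq_len(nrow(cases))) {
    for (r in seq_len(reps)) {
      if (cnt >= 200) break
      net <- random_semnet(cases$n[i], cases$p[i], seed = 1000 * i + r)
      expect_equal(mean_path_length(net), oracle_mpl(net), tolerance = 1e-9)
      expect_equal(global_clustering(net), oracle_gcc_meanlocal(net),
                   tolerance = 1e-9)
      expect_equal(mean_degree(net), oracle_md(net), tolerance = 1e-9)
      expect_equal(mean_betweenness(net), oracle_mean_bc(net),
                   tolerance = 1e-9)
      expect_equal(mean_harmonic_centrality(net), oracle_mean_hc(net),
                   tolerance = 1e-9)
      cnt <- cnt + 1
    }
  }
  expect_gte(cnt, 200)
})

test_that("metrics are invariant under node relabeling", {
  net <- random_semnet(9, 0.4, seed = 7)
  perm <- setNames(sprintf("x%02d", sample(9)), net$nodes)
  relab <- semnet(unname(perm[net$nodes]),
                  cbind(perm[net$edges[, 1]], perm[net$edges[, 2]]))
  a <- compute_all_metrics(net)
  b <- compute_all_metrics(relab)
  for (v in c("MPL", "GCC", "MD", "meanBC", "meanHC")) {
    expect_equal(a[[v]], b[[v]], tolerance = 1e-12)
  }
})

test_that("adding an edge never decreases MD nor increases MPL on fixed graphs", {
  base <- semnet(letters[1:5], rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  for (new_edge in list(c("a", "c"), c("d", "e"), c("a", "e"))) {
    bigger <- semnet(base$nodes, rbind(base$edges, new_edge))
    expect_gte(mean_degree(bigger), mean_degree(base))
    # over pairs connected before the addition, distances cannot grow
    d0 <- oracle_distances(base)
    d1 <- oracle_distances(bigger)
    conn <- is.finite(d0) & upper.tri(d0)
    expect_true(all(d1[conn] <= d0[conn]))
  }
})

test_that("edge sets shrink monotonically in the min-shared threshold", {
  lex <- generate_lexicon(25, 15, c(2, 6), seed = 42)
  words <- names(lex)
  prev <- NULL
  for (m in 1:4) {
    net <- suppressWarnings(build_network(words, lex, min_shared = m))
    keys <- apply(network_edges(net), 1, paste, collapse = "|")
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("metric bounds hold on random graphs", {
  for (s in 1:20) {
    net <- random_semnet(sample(2:12, 1), runif(1, 0.1, 0.9), seed = 500 + s)
    m <- compute_all_metrics(net)
    expect_gte(m$GCC, 0); expect_lte(m$GCC, 1)
    expect_gte(m$meanHC, 0); expect_lte(m$meanHC, 1)
    expect_gte(m$MD, 0); expect_lte(m$MD, network_size(net) - 1)
    if (nrow(network_edges(net)) > 0) expect_gte(m$MPL, 1)
  }
})

test_that("betweenness normalization switch rescales by (n-1)(n-2)/2", {
  net <- example_network()
  expect_equal(mean_betweenness(net, normalized = TRUE),
               mean_betweenness(net) / 3)
})
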