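test_that("initial_families drops families below the size floor", {
  ids1 <- sprintf("a%02d", 1:30)
  ids2 <- sprintf("b%02d", 1:30)
  ids3 <- sprintf("c%d", 1:5)
  hits <- rbind(clique_hits(ids1, 120), clique_hits(ids2, 120),
                clique_hits(ids3, 120))
  g <- build_graph(hits, 50)
  fams <- initial_families(g, mining_config())
  expect_length(fams, 2L)
  expect_setequal(unlist(fams), c(ids1, ids2))

  expect_length(initial_families(build_graph(parse_hits(character()), 50),
                                 mining_config()), 0L)

  # 30-node path: single linkage gives one family of 30
  path <- data.frame(query_id = sprintf("p%02d", 1:29),
                     subject_id = sprintf("p%02d", 2:30), bitscore = 120)
  expect_equal(lengths(initial_families(build_graph(path, 50), mining_config())),
               30L)
})

test_that("size_ratio_ok implements the order-of-magnitude test", {
  cfg <- mining_config()
  expect_true(size_ratio_ok(184, 80, cfg))    # ratio 2.3
  expect_false(size_ratio_ok(5, 100, cfg))    # 0.05 < 0.1
  expect_true(size_ratio_ok(50, 50, cfg))
  expect_true(size_ratio_ok(10, 100, cfg))    # boundary inclusive
  expect_true(size_ratio_ok(100, 10, cfg))
  expect_error(size_ratio_ok(0, 10, cfg))
})

test_that("largest_precursor_family is the biggest induced component", {
  # 2 BGCs x 2 ORFs, all four mutually similar above 10 bits
  orf_g <- build_graph(clique_hits(c("o1", "o2", "o3", "o4"), 40), 10)
  nbs <- list(A1 = c("o1", "o2"), A2 = c("o3", "o4"))
  cfg <- mining_config()
  expect_setequal(largest_precursor_family(c("A1", "A2"), orf_g, nbs, cfg),
                  c("o1", "o2", "o3", "o4"))

  # ORFs similar only to another family's ORFs are excluded by induction
  orf_g2 <- build_graph(clique_hits(c("o1", "x1", "x2"), 40), 10)
  expect_equal(largest_precursor_family("A1", orf_g2, list(A1 = c("o1", "o2")),
                                        cfg),
               "o1")  # o1's only partners are outside; singletons tie -> smallest id

  # no qualifying edges: largest family is a singleton
  lone <- build_graph(data.frame(query_id = "o1", subject_id = "o2",
                                 bitscore = 5), 0, drop_self = FALSE)
  expect_length(largest_precursor_family("A1", lone, list(A1 = c("o1", "o2")),
                                         cfg), 1L)

  expect_warning(
    largest_precursor_family(c("A1", "A9"), orf_g, nbs, cfg),
    "lack a neighborhood")
})

test_that("pair_families accepts a clean planted clique at the first threshold", {
  anchors <- sprintf("a%02d", 1:40)
  rre_g <- build_graph(clique_hits(anchors, 120), 50)
  orfs <- sprintf("o%03d", 1:80)
  orf_g <- build_graph(clique_hits(orfs, 60), 10)
  nbs <- split(orfs, rep(anchors, each = 2))
  res <- pair_families(rre_g, orf_g, nbs, mining_config())
  expect_length(res, 1L)
  expect_equal(res[[1]]$members, sort(anchors))
  expect_length(res[[1]]$precursor_members, 80L)
  expect_equal(res[[1]]$threshold_history, 50)
  expect_true(res[[1]]$accepted)
})

test_that("low-connectivity families fragment at the escalated threshold", {
  # chain of five 5-cliques (within 120 bits) linked by 55-bit bridges:
  # connectivity at t=50 is 54/300 = 0.18 <= 0.2, so the family re-enters
  # at t=60 where the bridges drop and the cliques separate
  cliques <- lapply(1:5, function(i) sprintf("c%d_%d", i, 1:5))
  hits <- do.call(rbind, lapply(cliques, clique_hits, bits = 120))
  bridges <- data.frame(query_id = vapply(cliques[-5], `[[`, "", 5L),
                        subject_id = vapply(cliques[-1], `[[`, "", 1L),
                        bitscore = 55)
  rre_g <- build_graph(rbind(hits, bridges), 50)
  all_ids <- unlist(cliques)
  expect_equal(connectivity(all_ids, rre_g, 50), 54 / 300)

  orfs <- paste0("orf_", all_ids)
  orf_g <- build_graph(do.call(rbind, lapply(cliques, function(cl)
    clique_hits(paste0("orf_", cl), 60))), 10)
  nbs <- as.list(setNames(paste0("orf_", all_ids), all_ids))

  res <- pair_families(rre_g, orf_g, nbs, mining_config(min_family = 5L))
  expect_length(res, 5L)
  for (r in res) {
    expect_length(r$members, 5L)
    expect_equal(r$threshold_history, c(50, 60))
    expect_equal(r$threshold, 60)
  }
  # each emitted family is exactly one planted clique
  expect_setequal(vapply(res, function(r) paste(r$members, collapse = ","), ""),
                  vapply(cliques, function(cl) paste(sort(cl), collapse = ","), ""))
})

test_that("pair_families on empty graphs yields no results", {
  g0 <- build_graph(parse_hits(character()), 50)
  expect_length(pair_families(g0, g0, list(), mining_config()), 0L)
})

test_that("accepted results satisfy all gates; histories increase; branches terminate", {
  set.seed(31)
  cfg <- mining_config(min_family = 2L, t0_rre = 50)
  for (rep in 1:100) {
    n <- sample(4:14, 1)
    g <- random_graph(n, p = runif(1, 0.2, 0.8), wmin = 0, wmax = 130)
    orfs <- paste0("orf_", g$nodes)
    orf_g <- build_graph(clique_hits(orfs, 60), 10)
    nbs <- as.list(setNames(orfs, g$nodes))
    res <- pair_families(g, orf_g, nbs, cfg)  # must return (termination)
    init <- initial_families(g, cfg)
    for (r in res) {
      expect_true(all(diff(r$threshold_history) > 0))
      expect_gt(r$connectivity, cfg$connectivity_min)
      expect_gte(length(r$members), cfg$min_family)
      expect_true(size_ratio_ok(length(r$precursor_members),
                                length(r$members), cfg))
      # recursion soundness: members sit inside exactly one initial family
      parent <- vapply(init, function(f) all(r$members %in% f), NA)
      expect_equal(sum(parent), 1L)
    }
  }
})

test_that("planted families are recovered exactly at the default configuration", {
  b <- simulate_daptides(sim_config(seed = 42))
  res <- mine_bundle(b)
  labs <- pairing_labels(res)
  expect_length(labs, 105L)
  expect_equal(mclust::adjustedRandIndex(labs, b$truth$protein_family[names(labs)]),
               1.0)
  expect_length(res, 3L)
  expect_equal(sort(vapply(res, function(r) length(r$members), 0L)),
               c(30L, 35L, 40L))
})

test_that("recovery stays high under documented stress configurations", {
  for (nm in names(stress_variants())) {
    sc <- stress_variants(sim_config(seed = 42))[[nm]]
    b <- simulate_daptides(sc)
    res <- mine_bundle(b)
    labs <- pairing_labels(res)
    ari <- mclust::adjustedRandIndex(labs, b$truth$protein_family[names(labs)])
    expect_gte(ari, 0.9)
  }
})
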