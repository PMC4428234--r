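test_that("jaccard overlap behaves as a set similarity", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard(character(0), character(0)), 1)
  expect_equal(jaccard(c("a", "a", "b"), c("b", "c")), 1 / 3)
  for (seed in 1:5) {
    set.seed(seed)
    a <- sample(letters, 8)
    b <- sample(letters, 12)
    expect_equal(jaccard(a, b), jaccard(b, a))
    expect_equal(jaccard(a, a), 1)
  }
})

test_that("attack curves track fragmentation after each deletion", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("s", 1:5)
  curve <- attack_curve(star, "s1")
  expect_equal(curve$k, c(0L, 1L))
  expect_equal(curve$components, c(1L, 4L))
  expect_equal(curve$lcc_fraction, c(1, 0.2))

  g <- make_figure1_fixture()
  curve <- attack_curve(g, c("5", "6"))
  expect_equal(curve[1, ], data.frame(k = 0L, components = 1L,
                                      lcc_fraction = 1))
  expect_equal(curve$components[3], 2L)
  expect_equal(curve$lcc_fraction[3], 0.4)

  expect_error(attack_curve(g, c("5", "5")), "distinct")
  expect_error(attack_curve(g, "zz"), "not in the network")
})

test_that("attack curve invariants hold for random targets", {
  for (seed in 1:5) {
    g <- random_network("preferential-attachment", 40, 2, seed = seed)
    n <- igraph::vcount(g)
    set.seed(seed)
    targets <- sample(igraph::V(g)$name, 15)
    curve <- attack_curve(g, attack_order(g, targets))
    expect_true(all(diff(curve$lcc_fraction) <= 1e-12))
    expect_true(all(curve$components >= 1 | curve$k == n))
    expect_true(all(curve$components <= n - curve$k))
  }
})

test_that("attack order sorts by decreasing degree then label", {
  g <- make_figure1_fixture()
  expect_equal(attack_order(g, c("2", "5", "1", "10")),
               c("5", "1", "10", "2"))
})

test_that("rank-sum test matches hand values and degenerate cases", {
  r <- rank_sum_compare(c(1, 2, 3), c(4, 5, 6))
  expect_true(r$exact)
  expect_equal(r$p_value, 0.1)
  expect_equal(rank_sum_compare(5, 5)$p_value, 1)
  expect_equal(rank_sum_compare(1:10, 1:10)$p_value, 1)
  expect_error(rank_sum_compare(numeric(0), 1), "non-empty")
})

test_that("exact rank-sum branch equals full permutation enumeration", {
  for (seed in 1:12) {
    set.seed(seed)
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    # integer draws force ties
    x <- sample(1:4, n1, replace = TRUE)
    y <- sample(1:4, n2, replace = TRUE)
    r <- rank_sum_compare(x, y)
    expect_true(r$exact)
    expect_equal(r$p_value, oracle_ranksum_perm(x, y), tolerance = 1e-12)
  }
})

test_that("large-sample branch approximates the exact p-value", {
  set.seed(42)
  x <- rpois(25, 6)
  y <- rpois(30, 8)
  r <- rank_sum_compare(x, y)
  expect_false(r$exact)
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-8)
  expect_lt(r$median_difference, 0)
})

test_that("enrichment test equals the hypergeometric upper tail", {
  universe <- as.character(1:10)
  e <- enrichment_test(c("5", "6"), c("5", "6"), universe)
  expect_equal(e$p_value, 1 / 45)
  expect_equal(e$overlap_count, 2L)

  e0 <- enrichment_test(c("1", "2"), c("9"), universe)
  expect_equal(e0$overlap_count, 0L)
  expect_equal(e0$p_value, 1)

  expect_error(enrichment_test("zz", "1", universe), "subset")
  # annotations outside the universe are discarded before testing
  e <- enrichment_test(c("1", "2"), c("1", "notInUniverse"), universe)
  expect_equal(e$annotated_in_universe, 1L)
})

test_that("enrichment p-values match brute-force summation across tables", {
  for (bigN in c(5L, 9L, 17L, 33L, 60L)) {
    universe <- as.character(seq_len(bigN))
    set.seed(bigN)
    for (rep in 1:40) {
      bigK <- sample(1:bigN, 1)
      na <- sample(0:bigN, 1)
      kmin <- max(0L, na - (bigN - bigK))
      kmax <- min(bigK, na)
      k <- if (kmax > kmin) sample(kmin:kmax, 1) else kmin
      driver <- universe[seq_len(bigK)]
      annotated <- c(universe[seq_len(k)],
                     if (na > k) universe[bigK + seq_len(na - k)])
      e <- enrichment_test(driver, annotated, universe)
      expect_equal(e$p_value, oracle_hyper_tail(k, na, bigN, bigK),
                   tolerance = 1e-10)
    }
  }
})

test_that("odds ratios use the 0.5 correction only for zero cells", {
  u <- as.character(1:20)
  e <- enrichment_test(u[1:5], u[c(1:3, 10:12)], u)
  # 2x2: 3,2,3,12 -> OR = 6
  expect_equal(e$odds_ratio, (3 * 12) / (2 * 3))
  ez <- enrichment_test(u[1:5], u[1:5], u)
  expect_equal(ez$odds_ratio, (5.5 * 15.5) / (0.5 * 0.5))
})

test_that("annotation maps stay mutually consistent and parse both formats", {
  m <- annotation_map(list(c1 = c("A", "B"), c2 = c("B", "C"), c3 = "B"))
  expect_setequal(m$protein2terms$B, c("c1", "c2", "c3"))
  expect_equal(membership_counts(c("B", "A", "ZZ"), m),
               c(B = 3L, A = 1L, ZZ = 0L))

  f <- withr::local_tempfile()
  writeLines(c("A\tc1", "B\tc1", "B\tc2"), f)
  m2 <- read_annotations(f)
  expect_setequal(m2$term2proteins$c1, c("A", "B"))

  f2 <- withr::local_tempfile()
  writeLines(c("A", "B", "C"), f2)
  m3 <- read_annotations(f2, flat = TRUE, term = "essential")
  expect_equal(m3$term2proteins$essential, c("A", "B", "C"))
  expect_error(read_annotations(tempfile("nope")), "not found")
})

test_that("term enrichment applies Bonferroni over tested terms only", {
  set.seed(99)
  universe <- as.character(1:40)
  terms <- c(list(planted = universe[1:8]),
             lapply(1:4, function(i) universe[sample(1:40, 6)]))
  names(terms)[-1] <- paste0("bg", 1:4)
  terms$empty <- c("X1", "X2") # outside universe, must be skipped
  m <- annotation_map(terms)
  res <- term_enrichment(universe[1:8], m, universe, alpha = 0.01)
  expect_equal(nrow(res), 5L) # 'empty' skipped
  expect_equal(res$corrected_p, pmin(1, 5 * res$p_value))
  expect_equal(res$significant, res$corrected_p < 0.01)
  expect_equal(res$term[1], "planted")

  single <- annotation_map(list(only = universe[1:8]))
  r1 <- term_enrichment(universe[1:8], single, universe)
  expect_equal(r1$corrected_p, r1$p_value)
})
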