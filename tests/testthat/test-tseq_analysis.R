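test_that("chain, diamond and tapped-cycle sequences match their ground truth", {
  fx <- make_fixture("chain", delays = c(2L, 3L))
  log <- run_simulation(fx$network, fx$delays, fx$params, fx$stimuli)
  X <- extract_tseqs(log, "N1", "N3")
  expect_length(X, 1L)
  expect_equal(X[[1L]]$nodes, c("N1", "N2", "N3"))
  expect_equal(X[[1L]]$steps, c(0L, 2L, 5L))

  fd <- make_fixture("diamond")
  ld <- run_simulation(fd$network, fd$delays, fd$params, fd$stimuli)
  Xd <- extract_tseqs(ld, "A", "D")
  expect_same_tseq_set(Xd, tseq_set(fd$truth$expected_tseqs))
  # D's single event has two parents, hence two sequences
  expect_length(Xd, 2L)

  fc <- make_fixture("cycle_with_tap", n_steps = 20L)
  lc <- run_simulation(fc$network, fc$delays, fc$params, fc$stimuli)
  Xc <- extract_tseqs(lc, "A", "E")
  expect_length(Xc, 3L)
  expect_same_tseq_set(Xc, tseq_set(fc$truth$expected_tseqs))
})

test_that("sequences validate edgewise and delaywise against the network", {
  for (seed in 1:6) {
    toy <- random_toy_log(seed)
    ends <- toy$nodes[c(4L, 5L)]
    X <- extract_tseqs(toy$log, toy$start, ends)
    dkey <- setNames(toy$delays$steps,
                     paste(toy$delays$source, toy$delays$target))
    for (x in X) {
      expect_equal(x$nodes[1L], toy$start)
      expect_true(x$nodes[length(x$nodes)] %in% ends)
      if (length(x$nodes) > 1L) {
        k <- paste(head(x$nodes, -1L), tail(x$nodes, -1L))
        expect_true(all(k %in% names(dkey)))
        expect_equal(diff(x$steps), unname(dkey[k]))
      }
    }
  }
})

test_that("path explosion fails loudly instead of truncating", {
  fc <- make_fixture("cycle_with_tap", n_steps = 20L)
  lc <- run_simulation(fc$network, fc$delays, fc$params, fc$stimuli)
  expect_error(extract_tseqs(lc, "A", "E", max_paths = 2),
               "path explosion")
  expect_error(extract_tseqs(lc, "E", "A"), "no root event")
})

test_that("label-only deduplication collapses timing-distinct walks", {
  # a stimulus repeated after the refractory window retraces the same labels
  fx <- make_fixture("chain", delays = c(2L, 3L), n_steps = 40L)
  log <- run_simulation(fx$network, fx$delays, fx$params,
                        list(stimulus("N1", 0L), stimulus("N1", 20L)))
  X_timed <- extract_tseqs(log, "N1", "N3")
  X_labels <- extract_tseqs(log, "N1", "N3", dedupe_labels = TRUE)
  expect_length(X_timed, 2L)
  expect_length(X_labels, 1L)
})

test_that("greedy match fraction reproduces hand-traced values", {
  expect_equal(pairwise_match_fraction(c("A", "B", "C"),
                                       c("A", "B", "C")), 1)
  # 4 of 5 labels found in order -> 0.8
  expect_equal(pairwise_match_fraction(c("A", "B", "C", "D", "E"),
                                       c("A", "B", "C", "D", "X")), 0.8)
  # greedy cursor: A matches at position 2, B has no later occurrence
  expect_equal(pairwise_match_fraction(c("A", "B"), c("B", "A")), 0.5)
  expect_equal(pairwise_match_fraction(c("A", "B"), c("C", "D")), 0)
  # works on tseq objects too
  x <- tseq(c("A", "B"), c(0L, 2L))
  expect_equal(pairwise_match_fraction(x, x), 1)
  expect_error(pairwise_match_fraction(character(0), "A"), "non-empty")
})

test_that("match fraction is bounded, reflexive and complete on subsequences", {
  set.seed(5)
  for (rep in 1:50) {
    x <- sample(LETTERS[1:4], sample(2:6, 1L), replace = TRUE)
    y <- sample(LETTERS[1:4], sample(2:6, 1L), replace = TRUE)
    f1 <- pairwise_match_fraction(x, y)
    expect_gte(f1, 0); expect_lte(f1, 1)
    expect_equal(pairwise_match_fraction(x, x), 1)
    # greedy earliest-occurrence matching always certifies a supersequence:
    # interleaving noise into x leaves the full match intact
    noisy <- unlist(lapply(x, function(u)
      c(sample(LETTERS[1:4], sample(0:2, 1L), replace = TRUE), u)))
    expect_equal(pairwise_match_fraction(x, noisy), 1)
    # the count is an integer multiple of 1 / |x|
    expect_equal(f1 * length(x), round(f1 * length(x)))
  }
})

test_that("similarity counts behave like the percent-match table", {
  fd <- make_fixture("cycle_with_tap", n_steps = 20L)
  ld <- run_simulation(fd$network, fd$delays, fd$params, fd$stimuli)
  X <- extract_tseqs(ld, "A", "E")
  # every x matches itself at full threshold
  expect_equal(similarity_count(X, X, 1), length(X))
  # zero threshold is always met against any non-empty set
  Y1 <- X[1L]
  expect_equal(similarity_count(X, Y1, 0), length(X))
  # exhaustive pairwise check on a tiny hand case
  Xh <- tseq_set(list(tseq(c("A", "B"), c(0L, 1L)),
                      tseq(c("C", "D"), c(0L, 1L))))
  Yh <- tseq_set(list(tseq(c("A", "E", "B"), c(0L, 1L, 2L))))
  expect_equal(similarity_count(Xh, Yh, 1), 1L)
  expect_error(similarity_count(tseq_set(list()), X, 0.5), "non-empty")

  tab <- similarity_table(X, Y1)
  expect_equal(tab$alpha, c(0, 0.25, 0.5, 0.75, 1))
  expect_true(all(diff(tab$count) <= 0))
  expect_equal(tab$count[1L], length(X))
  expect_equal(tab$ref_size[1L], length(X))
  expect_equal(tab$cmp_size[1L], 1L)
  # X against itself: all rows equal |X|
  expect_true(all(similarity_table(X, X)$count == length(X)))
})

test_that("canonicalize collapses tandem repeats to a unique primitive form", {
  cc <- canonicalize(c("A", "B", "A", "B", "C"))
  expect_length(cc$units, 2L)
  expect_equal(cc$units[[1L]]$block, c("A", "B"))
  expect_equal(cc$units[[1L]]$count, 2L)
  expect_equal(cc$canonical, c("A", "B", "C"))

  # repeat-free sequences are their own canonical form
  s <- c("A", "B", "C", "A", "D")
  expect_equal(canonicalize(s)$canonical, s)

  # unit block
  cc3 <- canonicalize(c("A", "A", "A"))
  expect_length(cc3$units, 1L)
  expect_equal(cc3$units[[1L]],
               list(block = "A", count = 3L))

  # smallest period preferred: AAAB is (A)^3 B, not (AA) A B
  cc4 <- canonicalize(c("A", "A", "A", "B"))
  expect_equal(cc4$units[[1L]]$block, "A")
  expect_equal(cc4$units[[1L]]$count, 3L)

  # nested repetition reaches a fixed point
  cc5 <- canonicalize(c("A", "B", "A", "B", "C", "A", "B", "A", "B", "C"))
  expect_equal(cc5$canonical, c("A", "B", "C"))
})

test_that("recompose inverts canonicalize and honours supplied counts", {
  cc <- canonicalize(c("A", "B", "A", "B", "C"))
  expect_equal(recompose(cc), c("A", "B", "A", "B", "C"))
  expect_equal(recompose(cc, 3L),
               c("A", "B", "A", "B", "A", "B", "C"))
  expect_error(recompose(cc, c(2L, 2L)), "one repetition count")

  # fuzzed identity: compression round-trips arbitrary sequences
  set.seed(17)
  for (rep in 1:300) {
    n <- sample(1:12, 1L)
    s <- sample(LETTERS[1:3], n, replace = TRUE)
    cc <- canonicalize(s)
    expect_identical(recompose(cc), s)
  }
})

test_that("basis decomposition partitions sequences by canonical form", {
  X <- tseq_set(list(
    tseq(c("A", "B", "A", "B", "C"), c(0L, 1L, 2L, 3L, 4L)),
    tseq(c("A", "B", "A", "B", "A", "B", "C"), 0:6)))
  b <- decompose_basis(X)
  expect_equal(b$n_one_time, 0L)
  expect_equal(b$n_repeating, 1L)
  expect_length(b$repeating_groups[[1L]]$members, 2L)
  # representative is the shortest member, compressed
  expect_equal(recompose(b$repeating_groups[[1L]]$representative),
               c("A", "B", "A", "B", "C"))

  # pairwise label-distinct, repeat-free sequences are all one-time
  X2 <- tseq_set(list(tseq(c("A", "B"), 0:1), tseq(c("C", "D"), 0:1),
                      tseq(c("B", "C"), 0:1)))
  b2 <- decompose_basis(X2)
  expect_equal(b2$n_one_time, 3L)
  expect_equal(b2$n_repeating, 0L)

  # partition: |one_time| + sum of group sizes = |X|
  X3 <- tseq_set(c(unclass(X), unclass(X2)))
  b3 <- decompose_basis(X3)
  expect_equal(b3$n_one_time +
                 sum(lengths(lapply(b3$repeating_groups, `[[`, "members"))),
               length(X3))
})

test_that("basis decomposition on the tapped cycle groups all laps together", {
  fc <- make_fixture("cycle_with_tap", n_steps = 26L)
  lc <- run_simulation(fc$network, fc$delays, fc$params, fc$stimuli)
  X <- extract_tseqs(lc, "A", "E")
  expect_gte(length(X), 3L)
  b <- decompose_basis(X)
  # every lap count shares the canonical form (A,B,E)
  expect_equal(b$n_repeating, 1L)
  expect_equal(b$n_one_time, 0L)
  expect_equal(b$repeating_groups[[1L]]$canonical, c("A", "B", "E"))
  # every member re-expands from its compressed units
  for (cc in b$repeating_groups[[1L]]$compressed)
    expect_identical(recompose(cc), cc$labels)
})

test_that("class interaction counts match an exhaustive membership scan", {
  cls <- c(S = NA, M1 = "VA", M2 = "VB", M3 = "DB", M4 = "VA")
  X <- tseq_set(list(
    tseq(c("S", "M1", "M2"), 0:2),          # {VA, VB}
    tseq(c("S", "M3"), 0:1),                # {DB}
    tseq(c("S", "M4", "M3", "M2"), 0:3)))   # {VA, DB, VB}
  classes <- c("VA", "VB", "DB")
  k1 <- class_interaction_counts(X, cls, classes, 1L)
  expect_equal(k1$count[k1$subset == "VA"], 2L)
  expect_equal(k1$count[k1$subset == "DB"], 2L)
  k2 <- class_interaction_counts(X, cls, classes, 2L)
  expect_equal(k2$count[k2$subset == "VA+VB"], 2L)
  expect_equal(k2$count[k2$subset == "DB+VA"], 1L)
  k3 <- class_interaction_counts(X, cls, classes, 3L)
  expect_equal(k3$count, 1L)
  expect_error(class_interaction_counts(X, cls, c("VA", "XX"), 1L),
               "unknown class")

  # single sequence traversing one VB and one VA node, k = 2
  X1 <- tseq_set(list(tseq(c("M1", "M2"), 0:1)))
  k2a <- class_interaction_counts(X1, cls, classes, 2L)
  expect_equal(k2a$count[k2a$subset == "VA+VB"], 1L)
  expect_equal(sum(k2a$count), 1L)

  # k beyond the classes present in any sequence -> all zero
  expect_equal(sum(class_interaction_counts(X1, cls, classes, 3L)$count), 0L)

  # randomized cross-check against a brute-force subset scan
  set.seed(23)
  nodes <- paste0("m", 1:8)
  cmap <- setNames(sample(c("VA", "VB", "DA", "DB"), 8, replace = TRUE),
                   nodes)
  present <- sort(unique(cmap))
  Xr <- tseq_set(lapply(1:10, function(i) {
    n <- sample(2:6, 1L)
    tseq(sample(nodes, n, replace = TRUE), seq_len(n))
  }), dedupe_labels = FALSE)
  for (k in seq_len(min(3L, length(present)))) {
    got <- class_interaction_counts(Xr, cmap, present, k)
    subsets <- utils::combn(present, k, simplify = FALSE)
    for (S in subsets) {
      manual <- sum(vapply(Xr, function(x)
        all(S %in% cmap[x$nodes]), logical(1)))
      expect_equal(got$count[got$subset == paste(S, collapse = "+")],
                   manual)
    }
  }
})
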