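test_that("classification deduplication keeps one entry and drops conflicts", {
  recs <- fixture_records(c("CCO", "OCC", "CCN", "c1ccccc1", "C1=CC=CC=C1"),
                          ids = paste0("m", 1:5))
  labs <- c(1, 1, 0, 1, 0)
  out <- deduplicate_classification(recs, labs)
  # CCO/OCC agree -> kept once; benzene spellings conflict -> dropped
  smis <- vapply(out$records, `[[`, character(1), "smiles")
  expect_true(canonicalize("CCO") %in% smis)
  expect_false(canonicalize("c1ccccc1") %in% smis)
  expect_equal(out$report$dropped$reason, "CONFLICTING_LABELS")
  expect_length(out$records, 2)
  expect_error(deduplicate_classification(recs, c(1, 2, 0, 1, 0)),
               "binary")
})

test_that("regression aggregation merges within-spread groups and drops the rest", {
  recs <- fixture_records(c("CCO", "OCC", "CCN", "CCC", "C(C)C"),
                          ids = paste0("m", 1:5))
  out <- aggregate_regression(recs, c(4, 6, 3.2, 1, 9),
                              rel_spread_limit = 0.5)
  # {4,6}: spread 0.4 <= 0.5 -> mean 5; {1,9}: spread 1.6 -> dropped
  smis <- vapply(out$records, `[[`, character(1), "smiles")
  expect_equal(out$values[smis == canonicalize("CCO")], 5)
  expect_equal(out$values[smis == canonicalize("CCN")], 3.2)
  expect_false(canonicalize("CCC") %in% smis)
  expect_equal(out$report$dropped$reason, "EXCESS_SPREAD")
  # conservation: merged + dropped + singletons = distinct structures
  expect_equal(nrow(out$report$merged) + nrow(out$report$dropped) + 1,
               3)
})

test_that("diverse split partitions at the requested fraction", {
  for (case in list(c(100, 0.75, 75), c(4, 0.75, 3), c(37, 0.8, 30))) {
    m <- random_bit_matrix(case[1], 128, seed = case[1])
    fm <- feature_matrix(m, "fingerprint",
                         setNames(rep("ecfp4", ncol(m)), colnames(m)))
    sp <- diverse_split(fm, case[2], seed = 1)
    expect_length(sp$train_ids, case[3])
    expect_length(intersect(sp$train_ids, sp$test_ids), 0)
    expect_setequal(c(sp$train_ids, sp$test_ids), rownames(m))
  }
  expect_error(diverse_split(feature_matrix(
    random_bit_matrix(3, 16, 1), "fingerprint",
    setNames(rep("x", 16), paste0("b", 1:16)))), "too few")
})

test_that("diverse split is deterministic and diversity beats random picking", {
  m <- random_bit_matrix(40, 64, seed = 2)
  fm <- feature_matrix(m, "fingerprint",
                       setNames(rep("ecfp4", 64), colnames(m)))
  s1 <- diverse_split(fm, 0.75, seed = 5)
  s2 <- diverse_split(fm, 0.75, seed = 5)
  expect_identical(s1$train_ids, s2$train_ids)

  nn_dist <- function(X) {
    inter <- X %*% t(X); ones <- rowSums(X)
    u <- outer(ones, ones, "+") - inter
    D <- 1 - ifelse(u > 0, inter / u, 1)
    diag(D) <- Inf
    mean(apply(D, 1, min))
  }
  diffs <- vapply(1:20, function(s) {
    X <- random_bit_matrix(30, 64, seed = 100 + s)
    fmx <- feature_matrix(X, "fingerprint",
                          setNames(rep("ecfp4", 64), colnames(X)))
    sp <- diverse_split(fmx, 0.6, seed = s)
    picked <- nn_dist(X[sp$train_ids, ])
    set.seed(s)
    rand <- nn_dist(X[sample(rownames(X), length(sp$train_ids)), ])
    picked - rand
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
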