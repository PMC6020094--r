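store_path <- function() {
  system.file("extdata", "admet_store_synthetic.csv", package = "admetkit")
}

test_that("the demo store loads with canonical SMILES and computed properties", {
  store <- load_admet_store(store_path())
  expect_equal(nrow(store), 20)
  expect_identical(store$smiles,
                   vapply(store$smiles, canonicalize, character(1),
                          USE.NAMES = FALSE))
  expect_true(all(is.finite(store$MW)))
  expect_true(all(is.finite(store$AlogP)))
})

test_that("accurate search matches by canonical form and case-insensitive names", {
  store <- load_admet_store(store_path())
  hit <- accurate_search(store, "smiles", "OCC")   # spelled differently
  expect_equal(hit$entry_id, "S0001")
  expect_equal(accurate_search(store, "cas", "58-08-2")$entry_id, "S0004")
  expect_equal(accurate_search(store, "iupac", "ETHANOL")$entry_id, "S0001")
  expect_equal(nrow(accurate_search(store, "cas", "0000-00-0")), 0)
})

test_that("range search conjoins inclusive bounds", {
  store <- data.frame(entry_id = paste0("e", 1:5),
                      smiles = rep("CCO", 5),
                      MW = c(100, 200, 300, 400, 500),
                      AlogP = c(1, 2, 3, 4, 5), HBA = 1:5, HBD = 0:4)
  class(store) <- c("admet_store", "data.frame")
  expect_equal(range_search(store, list(MW = c(150, 350)))$entry_id,
               c("e2", "e3"))
  expect_equal(range_search(store, list(MW = c(200, 300)))$entry_id,
               c("e2", "e3"))  # inclusive at both ends
  expect_equal(range_search(store, list(MW = c(150, 450),
                                        HBD = c(2, 3)))$entry_id,
               c("e3", "e4"))
  expect_error(range_search(store, list()), "at least one")
  expect_error(range_search(store, list(MW = c(5, 1))), "lo <= hi")
  expect_error(range_search(store, list(XX = c(1, 2))), "unknown")
})

test_that("self-similarity is exactly 1 for every fingerprint and metric", {
  store <- load_admet_store(store_path())
  q <- molecule_record("CC(=O)Oc1ccccc1C(=O)O", id = "query")
  for (fp in c("fp2", "maccs", "ecfp2", "ecfp4", "ecfp6")) {
    for (met in c("tanimoto", "dice")) {
      hits <- similarity_search(store, q, fp, met, top_k = 3)
      expect_equal(hits$entry_id[1], "S0002")
      expect_equal(hits$score[1], 1.0)
    }
  }
})

test_that("tanimoto and dice match brute-force set arithmetic", {
  brute <- function(a, b, metric) {
    A <- which(a == 1); B <- which(b == 1)
    i <- length(intersect(A, B))
    if (metric == "tanimoto") {
      u <- length(union(A, B)); if (u == 0) 0 else i / u
    } else {
      d <- length(A) + length(B); if (d == 0) 0 else 2 * i / d
    }
  }
  set.seed(17)
  for (trial in 1:500) {
    a <- sample(0:1, 64, replace = TRUE, prob = c(0.7, 0.3))
    b <- sample(0:1, 64, replace = TRUE, prob = c(0.7, 0.3))
    m <- matrix(b, nrow = 1)
    tan <- admetkit:::.bit_similarity(a, m, "tanimoto")
    dic <- admetkit:::.bit_similarity(a, m, "dice")
    expect_equal(tan, brute(a, b, "tanimoto"), tolerance = 1e-12)
    expect_equal(dic, brute(a, b, "dice"), tolerance = 1e-12)
    if (tan > 0) expect_lte(tan, dic + 1e-12)
  }
})

test_that("hits are sorted by score with id tie-breaks and filters apply", {
  store <- load_admet_store(store_path())
  q <- molecule_record("c1ccccc1", id = "benzene")
  hits <- similarity_search(store, q, "maccs", "tanimoto")
  expect_true(all(diff(hits$score) <= 0))
  ties <- split(hits$entry_id, hits$score)
  for (grp in ties) expect_identical(grp, sort(grp))
  top <- similarity_search(store, q, "maccs", "tanimoto", top_k = 5)
  expect_equal(nrow(top), 5)
  thr <- similarity_search(store, q, "maccs", "tanimoto", min_score = 0.5)
  expect_true(all(thr$score >= 0.5))
})

test_that("probability symbols follow the band table", {
  cases <- list(c(0.05, "---"), c(0.1, "---"), c(0.25, "--"), c(0.45, "-"),
                c(0.55, "+"), c(0.7, "+"), c(0.85, "++"), c(0.95, "+++"))
  for (cs in cases)
    expect_identical(probability_symbol(as.numeric(cs[1])), cs[2])
})

test_that("the systematic profile renders one row per endpoint with symbols", {
  gen <- fixture_dataset("classification", n = 80, p = 8, informative = 3,
                         seed = 21)
  clf <- train(gen$dataset, model_config("rf", "classification", seed = 1))
  genr <- fixture_dataset("regression", n = 80, p = 8, informative = 3,
                          seed = 22)
  reg <- train(genr$dataset, model_config("rf", "regression", seed = 1))
  # features for real molecules: wire the models to a synthetic featurizer
  fake_featurizer <- function(records) {
    X <- matrix(0.1, length(records), 8)
    colnames(X) <- sprintf("feat_%03d", 1:8)
    rownames(X) <- vapply(records, `[[`, character(1), "id")
    feature_matrix(X, "descriptor",
                   setNames(rep("synthetic", 8), colnames(X)))
  }
  registry <- list(
    hERG = list(model = clf, features = fake_featurizer),
    LogS = list(model = reg, features = fake_featurizer),
    broken = list(model = clf, features = function(records)
      stop("no features")))
  prof <- systematic_profile(molecule_record("CCO", id = "q"), registry)
  expect_equal(nrow(prof), 3)
  herg <- prof[prof$endpoint == "hERG", ]
  expect_identical(herg$symbol, probability_symbol(herg$probability))
  expect_true(is.na(prof[prof$endpoint == "LogS", "symbol"]))
  expect_true(is.finite(prof[prof$endpoint == "LogS", "value"]))
  expect_identical(prof[prof$endpoint == "broken", "status"], "FAILED")
  expect_identical(herg$status, "OK")
})
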