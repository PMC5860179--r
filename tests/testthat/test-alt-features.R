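# a small labelled dataset: 4 reference, 6 classA, 6 classB samples
alt_fixture <- function(seed = 17, n_genes = 6) {
  set.seed(seed)
  ids <- c(sprintf("r%d", 1:4), sprintf("a%d", 1:6), sprintf("b%d", 1:6))
  m <- matrix(rnorm(n_genes * length(ids), mean = 8), nrow = n_genes,
              dimnames = list(sprintf("g%d", seq_len(n_genes)), ids))
  labels <- sample_annotation(ids, c(rep("reference", 4),
                                     rep("classA", 6), rep("classB", 6)))
  list(m = m, labels = labels)
}

test_that("gene features: all mode transposes; top-k finds the separating gene", {
  fx <- alt_fixture()
  fm <- gene_features(fx$m, "all")
  expect_equal(unclass(fm), t(fx$m), ignore_attr = TRUE)
  expect_identical(dimnames(fm), dimnames(t(fx$m)))

  m <- fx$m
  m["g1", samples_of(fx$labels, "classA")] <- rnorm(6, mean = 0, sd = 1)
  m["g1", samples_of(fx$labels, "classB")] <- rnorm(6, mean = 3, sd = 1)
  top1 <- gene_features(m, "top_k", labels = fx$labels, k = 1)
  expect_identical(colnames(top1), "g1")

  all_k <- gene_features(m, "top_k", labels = fx$labels, k = nrow(m))
  expect_setequal(colnames(all_k), rownames(m))
  expect_error(gene_features(m, "top_k", labels = fx$labels, k = 99), "exceeds")
})

test_that("gene features: panel errors on absent genes; pathway_genes filters", {
  fx <- alt_fixture()
  pan <- gene_features(fx$m, "panel", panel = c("g2", "g5"))
  expect_identical(colnames(pan), c("g2", "g5"))
  expect_error(gene_features(fx$m, "panel", panel = c("g2", "gX")), "gX")
  pw <- gene_features(fx$m, "pathway_genes", pathway_genes = c("g1", "g3", "gZ"))
  expect_setequal(colnames(pw), c("g1", "g3"))
})

test_that("LLR matches the closed form for unit-variance class fits", {
  # classA values (-1, 1): MLE fit N(0, 1); classB values (0, 2): N(1, 1)
  ids <- c("a1", "a2", "b1", "b2", "t1", "t2", "t3")
  m <- matrix(c(-1, 1, 0, 2, 0, 0.5, 2), nrow = 1,
              dimnames = list("g1", ids))
  labels <- sample_annotation(ids[1:4], c("classA", "classA", "classB", "classB"))
  # raw LLR(x) = 0.5 - x; check via the internals by normalizing by hand
  raw <- function(x) 0.5 - x
  train_raw <- raw(m[1, c("a1", "a2", "b1", "b2")])
  z <- (raw(m[1, ]) - mean(train_raw)) / sd(train_raw)
  fm <- llr_features(list(pw = "g1"), m, labels)
  expect_equal(unname(fm[, "pw"]), unname(z), tolerance = 1e-12)
})

test_that("LLR: identical class fits contribute exactly zero", {
  ids <- c("a1", "a2", "b1", "b2")
  m <- matrix(c(1, 3, 1, 3,            # identical classA/classB values
                1, 3, 5, 9), nrow = 2, byrow = TRUE,
              dimnames = list(c("flat", "inf"), ids))
  labels <- sample_annotation(ids, c("classA", "classA", "classB", "classB"))
  fm <- llr_features(list(p_flat = "flat", p_both = c("flat", "inf"),
                          p_inf = "inf"), m, labels)
  expect_true(all(fm[, "p_flat"] == 0))
  # additivity over disjoint sets
  expect_equal(fm[, "p_both"], fm[, "p_flat"] + fm[, "p_inf"], tolerance = 1e-12)
})

test_that("LLR requires both case classes and uses only training samples", {
  fx <- alt_fixture()
  fm1 <- llr_features(list(pw = rownames(fx$m)), fx$m, fx$labels)
  # perturbing REFERENCE samples (unused by LLR) leaves features unchanged
  m2 <- fx$m
  m2[, samples_of(fx$labels, "reference")] <- m2[, samples_of(fx$labels, "reference")] + 5
  fm2 <- llr_features(list(pw = rownames(fx$m)), m2, fx$labels)
  expect_equal(fm1[samples_of(fx$labels, "classA"), ],
               fm2[samples_of(fx$labels, "classA"), ], tolerance = 1e-12)
  one_a <- sample_annotation(c("a1", "b1", "b2"), c("classA", "classB", "classB"))
  expect_error(llr_features(list(pw = "g1"), fx$m, one_a), "classA")
})

test_that("CORG: single-gene pathway is its z-score; noise gene is rejected", {
  fx <- alt_fixture(seed = 23)
  m <- fx$m
  a <- samples_of(fx$labels, "classA"); b <- samples_of(fx$labels, "classB")
  m["g1", a] <- rnorm(6, 0, 0.5); m["g1", b] <- rnorm(6, 4, 0.5)
  fm <- corg_features(list(single = "g1", pair = c("g1", "g2")), m, fx$labels)
  z1 <- (m["g1", ] - mean(m["g1", ])) / sd(m["g1", ])
  expect_equal(unname(fm[, "single"]), unname(z1), tolerance = 1e-12)
  sel <- attr(fm, "selected")
  expect_identical(sel$single, "g1")
  # oracle: independently executed greedy on the same z-matrix
  sds <- apply(m, 1, sd); z <- (m - rowMeans(m)) / sds
  oracle <- corg_oracle(c("g1", "g2"), z, a, b)
  expect_identical(sel$pair, oracle$selected)
  expect_equal(unname(fm[, "pair"]), unname(oracle$activity), tolerance = 1e-12)
})

test_that("CORG keeps duplicated informative genes (t grows ~ sqrt(2))", {
  # two genes measuring the same class difference with independent noise:
  # averaging them roughly sqrt(2)-folds the t statistic, so both are kept
  ids <- c(sprintf("a%d", 1:8), sprintf("b%d", 1:8))
  set.seed(31)
  mu <- rep(c(0, 3), each = 8)
  m <- rbind(g1 = mu + rnorm(16, 0, 0.2), g2 = mu + rnorm(16, 0, 0.2))
  colnames(m) <- ids
  labels <- sample_annotation(ids, rep(c("classA", "classB"), each = 8))
  fm <- corg_features(list(pw = c("g1", "g2")), m, labels)
  expect_setequal(attr(fm, "selected")$pw, c("g1", "g2"))
})

test_that("CORG final |t| is never below the first gene's alone", {
  for (seed in 1:5) {
    fx <- alt_fixture(seed = seed, n_genes = 8)
    a <- samples_of(fx$labels, "classA"); b <- samples_of(fx$labels, "classB")
    fm <- corg_features(list(pw = rownames(fx$m)), fx$m, fx$labels)
    sds <- apply(fx$m, 1, sd); z <- (fx$m - rowMeans(fx$m)) / sds
    tstat <- function(v) abs(unname(stats::t.test(v[a], v[b])$statistic))
    first <- attr(fm, "selected")$pw[1]
    expect_gte(tstat(fm[, "pw"]) + 1e-12, tstat(z[first, ]))
  }
})

test_that("NTC distances: zero at the centroid, 3-4-5 fixture, order invariance", {
  ids <- c("r1", "r2", "x")
  m <- matrix(c(0, 2, 4,
                1, 1, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), ids))
  labels <- sample_annotation(c("r1", "r2"), c("reference", "reference"))
  fm <- ntc_features(list(pw = c("g1", "g2")), m, labels)
  # centroid (1, 1); sample x = (4, 5) -> distance 5
  expect_equal(unname(fm["x", "pw"]), 5)
  centroid_sample <- matrix(c(1, 1), ncol = 1, dimnames = list(c("g1", "g2"), "c"))
  fm2 <- ntc_features(list(pw = c("g1", "g2")), cbind(m, centroid_sample), labels)
  expect_equal(unname(fm2["c", "pw"]), 0)
  fm3 <- ntc_features(list(pw = c("g2", "g1")), m, labels)
  expect_equal(unname(fm3[, "pw"]), unname(fm[, "pw"]))
  expect_error(ntc_features(list(pw = "g1"), m,
                            sample_annotation("x", "classA")), "reference")
})

test_that("GED: null data gives all-zero features; a shifted gene loads P_over only", {
  set.seed(41)
  n <- 50
  ids <- c(sprintf("r%02d", 1:n), sprintf("a%02d", 1:n), sprintf("b%02d", 1:n))
  m <- matrix(rnorm(2 * 3 * n, mean = 8), nrow = 2,
              dimnames = list(c("g1", "g2"), ids))
  labels <- sample_annotation(ids, rep(c("reference", "classA", "classB"), each = n))
  null_fm <- ged_features(list(pw = c("g1", "g2")), m, labels)
  expect_true(all(null_fm == 0))

  m2 <- m
  ref_sd <- sd(m["g1", 1:n])
  m2["g1", samples_of(labels, "classA")] <-
    m2["g1", samples_of(labels, "classA")] + 3 * ref_sd
  fm <- ged_features(list(pw = c("g1", "g2")), m2, labels)
  # oracle: inclusion by direct KS test, direction by training mean deviation
  ks <- stats::ks.test(m2["g1", samples_of(labels, "classA")], m2["g1", 1:n])
  expect_lt(ks$p.value, 0.05)
  expect_true(all(fm[, "pw_over"] > 0))
  expect_true(all(fm[, "pw_under"] == 0))
})

test_that("GED inclusion is decided on training samples only", {
  set.seed(43)
  n <- 30
  ids <- c(sprintf("r%02d", 1:n), sprintf("a%02d", 1:n), sprintf("b%02d", 1:n), "test1")
  m <- matrix(rnorm(length(ids), mean = 8), nrow = 1,
              dimnames = list("g1", ids))
  m["g1", "test1"] <- 50   # an extreme lone test sample
  labels <- sample_annotation(ids[seq_len(3 * n)],
                              rep(c("reference", "classA", "classB"), each = n))
  fm <- ged_features(list(pw = "g1"), m, labels)
  expect_true(all(fm[, "pw_over"] == 0))   # test sample cannot flip inclusion
  expect_error(ged_features(list(pw = "g1"), m, labels, alpha = 1.5), "alpha")
})

test_that("all five methods emit finite, deterministic features", {
  sc <- make_scenario(n_pathways = 3, nodes_per_pathway = 6, n_reference = 20,
                      n_class_a = 10, n_class_b = 10, seed = 50)
  m <- cbind(sc$reference, sc$cases)
  sets <- graphs_to_gene_sets(sc$pathways)
  fms <- list(
    gene_features(m, "all"),
    llr_features(sets, m, sc$labels),
    corg_features(sets, m, sc$labels),
    ntc_features(sets, m, sc$labels),
    ged_features(sets, m, sc$labels))
  for (fm in fms) {
    expect_true(all(is.finite(fm)))
    expect_identical(rownames(fm), colnames(m))
  }
  expect_identical(unclass(llr_features(sets, m, sc$labels)),
                   unclass(fms[[2]]))
})
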