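test_that("parentless node fit is the sample mean and MLE variance", {
  m <- expr_mat(c(1, 2, 3, 4), "A", paste0("s", 1:4))
  np <- fit_node("A", character(0), m)
  expect_equal(np$beta0, 2.5)
  expect_equal(np$sigma2, 1.25)   # sum((x - mean)^2) / n, not / (n - 1)
})

test_that("single-parent fit reproduces the closed-form OLS solution", {
  np <- fit_node("B", "A", ols_fixture())
  expect_equal(np$beta0, -0.5, tolerance = 1e-12)
  expect_equal(np$betas, 2.3, tolerance = 1e-12)
  expect_equal(np$sigma2, 0.075, tolerance = 1e-12)
})

test_that("a perfect linear relation engages the variance floor", {
  m <- expr_mat(c(1, 2, 3, 4, 2, 4, 6, 8), c("A", "B"), paste0("s", 1:4))
  expect_warning(np <- fit_node("B", "A", m), "floor")
  expect_equal(np$betas, 2, tolerance = 1e-9)
  expect_equal(np$beta0, 0, tolerance = 1e-9)
  expect_equal(np$sigma2, 1e-8)
})

test_that("underdetermined fits fall back to ridge instead of crashing", {
  set.seed(3)
  m <- matrix(rnorm(12), nrow = 4,
              dimnames = list(c("Y", "P1", "P2", "P3"), paste0("s", 1:3)))
  # 3 samples < 4 coefficients; the interpolating ridge fit also floors sigma2
  np <- suppressWarnings(fit_node("Y", c("P1", "P2", "P3"), m))
  expect_true(np$ridged)
  expect_true(all(is.finite(c(np$beta0, np$betas, np$sigma2))))
  expect_length(np$betas, 3L)
})

test_that("node log-density matches hand-computed Gaussian values", {
  std <- structure(list(node = "X", parents = character(0), beta0 = 0,
                        betas = numeric(0), sigma2 = 1, ridged = FALSE),
                   class = "node_params")
  expect_equal(node_loglik(std, 0), -0.918939, tolerance = 1e-6)
  np <- fit_node("B", "A", ols_fixture())
  expect_equal(node_loglik(np, 4, 2), 0.30952, tolerance = 1e-4)
  # maximized at the conditional mean
  mu <- np$beta0 + np$betas * 2
  expect_gt(node_loglik(np, mu, 2), node_loglik(np, mu + 0.1, 2))
  expect_gt(node_loglik(np, mu, 2), node_loglik(np, mu - 0.1, 2))
  expect_error(node_loglik(np, Inf, 2), "non-finite")
  expect_error(node_loglik(np, 1, c(1, 2)), "align")
})

test_that("closed-form fit agrees with a numerical likelihood maximizer", {
  set.seed(91)
  for (rep in 1:25) {
    p <- sample(0:5, 1)
    n <- 50
    X <- matrix(rnorm(n * max(p, 1)), nrow = n)
    beta <- runif(p + 1, -2, 2)
    y <- beta[1] + (if (p > 0) X[, seq_len(p), drop = FALSE] %*% beta[-1] else 0) +
      rnorm(n, sd = runif(1, 0.3, 1.5))
    y <- drop(y)
    genes <- c("Y", if (p > 0) paste0("P", seq_len(p)))
    m <- rbind(y, if (p > 0) t(X[, seq_len(p), drop = FALSE]))
    dimnames(m) <- list(genes, paste0("s", seq_len(n)))
    np <- fit_node("Y", genes[-1], m)
    opt <- numeric_node_mle(y, if (p > 0) X[, seq_len(p), drop = FALSE] else
      matrix(nrow = n, ncol = 0))
    expect_equal(c(np$beta0, np$betas), unname(opt$beta), tolerance = 1e-6)
    expect_equal(np$sigma2, opt$sigma2, tolerance = 1e-6)
  }
})

test_that("pathway log-likelihood is the sum of per-node terms", {
  set.seed(5)
  ref <- matrix(rnorm(40, mean = 8), nrow = 2,
                dimnames = list(c("A", "B"), paste0("r", 1:20)))
  g <- pathway_graph("p", c("A", "B"), rbind(c("A", "B")))
  gbn <- fit_pathway_gbn(dagify(g, 0), ref)
  x <- c(A = 8.1, B = 7.7)
  manual <- node_loglik(gbn$node_params$A, x[["A"]]) +
    node_loglik(gbn$node_params$B, x[["B"]], x[["A"]])
  expect_equal(pathway_loglik(gbn, x), manual, tolerance = 1e-12)
  # order invariance of the sample vector
  expect_equal(pathway_loglik(gbn, x[c("B", "A")]), manual, tolerance = 1e-12)
  expect_error(pathway_loglik(gbn, c(A = 8)), "missing gene")
})

test_that("reference mean profile of a parentless pathway scores the closed form", {
  set.seed(6)
  ref <- matrix(rnorm(60, mean = 8), nrow = 3,
                dimnames = list(c("A", "B", "C"), paste0("r", 1:20)))
  g <- pathway_graph("p", c("A", "B", "C"), rbind(c("A", "B")))
  # strip the edge so every node is parentless
  g_iso <- pathway_graph("iso", c("A", "B", "C"))
  dag <- dagify(g_iso, 0)
  gbn <- fit_pathway_gbn(dag, ref)
  mu <- rowMeans(ref)
  expected <- sum(vapply(gbn$node_params, function(np)
    -0.5 * log(2 * pi * np$sigma2), numeric(1)))
  expect_equal(pathway_loglik(gbn, mu), expected, tolerance = 1e-10)
})

test_that("fitting recovers known chain parameters from simulated data", {
  # chain A -> B -> C with explicit parameters; the root's variance dominates
  # the downstream signal, so coefficient standard errors at n = 1000 are well
  # inside the +-0.05 band
  nodes <- c("A", "B", "C")
  g <- pathway_graph("chain", nodes, rbind(c("A", "B"), c("B", "C")))
  dag <- dagify(g, 0)
  mk <- function(node, parents, beta0, betas, sigma2)
    structure(list(node = node, parents = parents, beta0 = beta0,
                   betas = betas, sigma2 = sigma2, ridged = FALSE),
              class = "node_params")
  gbn <- structure(list(dag = dag, node_params = list(
    A = mk("A", character(0), 8, numeric(0), 1),
    B = mk("B", "A", 2, 0.8, 0.25),
    C = mk("C", "B", -1, 0.8, 0.25)), n_reference = NA_integer_),
    class = "pathway_gbn")
  sim <- sample_from_gbn(gbn, n = 1000, seed = 7)
  refit <- fit_pathway_gbn(dag, sim)
  for (v in nodes) {
    truth <- gbn$node_params[[v]]; est <- refit$node_params[[v]]
    expect_true(all(abs(est$betas - truth$betas) <= 0.05))
    expect_lt(abs(est$sigma2 - truth$sigma2) / truth$sigma2, 0.10)
  }
})

test_that("props features are deterministic and respond to perturbation", {
  sc <- make_scenario(n_pathways = 4, nodes_per_pathway = 8, n_reference = 50,
                      n_class_a = 10, n_class_b = 10,
                      perturbations = perturbation_spec("PW02", "mean_shift",
                                                        5, "classA"),
                      seed = 21)
  f1 <- props_features(sc$pathways, sc$reference, sc$cases, seed = 3)
  f2 <- props_features(sc$pathways, sc$reference, sc$cases, seed = 3)
  expect_identical(unclass(f1), unclass(f2))
  expect_identical(attr(f1, "method"), "props")
  expect_identical(colnames(f1), sprintf("PW%02d", 1:4))
  # shifted pathway: classA mean log-likelihood collapses
  a <- samples_of(sc$labels, "classA"); b <- samples_of(sc$labels, "classB")
  expect_lt(mean(f1[a, "PW02"]), mean(f1[b, "PW02"]) - 10)
  # unperturbed pathways look alike across classes
  expect_lt(abs(mean(f1[a, "PW01"]) - mean(f1[b, "PW01"])), 10)
})

test_that("a +5-SD shift on one pathway costs >= 10 nats of log-likelihood", {
  sc <- make_scenario(n_pathways = 2, nodes_per_pathway = 6, n_reference = 60,
                      n_class_a = 20, n_class_b = 20, seed = 9)
  model <- props(sc$pathways, sc$reference, seed = 1)
  base <- predict(model, sc$cases)
  shifted <- sc$cases
  genes <- grep("^PW01", rownames(shifted), value = TRUE)
  sds <- apply(sc$reference[genes, ], 1, sd)
  shifted[genes, ] <- shifted[genes, ] + 5 * sds
  after <- predict(model, shifted)
  expect_lt(mean(after[, "PW01"]), mean(base[, "PW01"]) - 10)
  expect_equal(mean(after[, "PW02"]), mean(base[, "PW02"]), tolerance = 1e-9)
})

test_that("cases simulated from the fitted model match reference feature distribution", {
  sc <- make_scenario(n_pathways = 3, nodes_per_pathway = 8, n_reference = 200,
                      n_class_a = 5, n_class_b = 5, seed = 33)
  model <- props(sc$pathways, sc$reference, seed = 2)
  sim <- simulate(model, nsim = 200, seed = 77)
  ref_scores <- predict(model, sc$reference)
  sim_scores <- predict(model, sim)
  for (pw in colnames(ref_scores)) {
    ks <- suppressWarnings(stats::ks.test(ref_scores[, pw], sim_scores[, pw]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("training samples score at least as high as under perturbed parameters", {
  sc <- make_scenario(n_pathways = 1, nodes_per_pathway = 6, n_reference = 40,
                      n_class_a = 5, n_class_b = 5, seed = 14)
  model <- props(sc$pathways, sc$reference, seed = 0)
  fit <- model$fits[[1]]
  train_mean <- mean(predict(model, sc$reference)[, 1])
  worse <- fit
  for (v in names(worse$node_params))
    worse$node_params[[v]]$beta0 <- worse$node_params[[v]]$beta0 + 0.5
  worse_mean <- mean(vapply(colnames(sc$reference), function(s)
    pathway_loglik(worse, sc$reference[, s]), numeric(1)))
  expect_gte(train_mean, worse_mean)
})

test_that("props model surface: print, summary, coef, serialization round trip", {
  sc <- make_scenario(n_pathways = 2, nodes_per_pathway = 5, n_reference = 30,
                      n_class_a = 5, n_class_b = 5, seed = 2)
  model <- props(sc$pathways, sc$reference, seed = 4)
  expect_output(print(model), "2 pathway")
  s <- summary(model)
  expect_identical(nrow(s$table), 2L)
  expect_true(all(s$table$prop_edges_kept == 1))  # generated DAGs are acyclic
  cf <- coef(model)
  expect_true(all(c("pathway", "node", "term", "estimate", "sigma2") %in% colnames(cf)))
  expect_true(all(is.finite(cf$estimate)))

  path <- tempfile(fileext = ".json")
  write_gbn_json(model, path)
  back <- read_gbn_json(path)
  expect_equal(predict(back, sc$cases), predict(model, sc$cases),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("props validates its inputs", {
  sc <- make_scenario(n_pathways = 1, nodes_per_pathway = 4, n_reference = 10,
                      n_class_a = 3, n_class_b = 3, seed = 8)
  expect_error(props(sc$pathways, sc$reference[, 1, drop = FALSE]),
               "at least 2")
  unmeasured <- sc$reference
  rownames(unmeasured) <- paste0("other_", rownames(unmeasured))
  expect_error(props(sc$pathways, unmeasured), "no scorable")
})
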