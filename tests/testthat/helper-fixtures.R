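# shared fixtures and independent oracles

# genes x samples matrix with names
expr_mat <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

# the 4-point OLS worked example: node B regressed on parent A
ols_fixture <- function() {
  expr_mat(c(1, 2, 3, 4,
             2, 4, 6, 9), c("A", "B"), paste0("s", 1:4))
}

# all permutations of 1..n (n <= 7)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# directed k-cycle graph
cycle_graph <- function(k) {
  nodes <- LETTERS[seq_len(k)]
  pathway_graph("cycle", nodes,
                cbind(nodes, nodes[c(2:k, 1)]))
}

# brute-force AUC: mean pair score with ties at 1/2
auc_brute <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# brute-force AUPRC by explicit threshold enumeration
pr_auc_brute <- function(scores, is_pos) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prec <- numeric(0); rec <- numeric(0)
  for (t in thr) {
    called <- scores >= t
    prec <- c(prec, sum(called & is_pos) / sum(called))
    rec <- c(rec, sum(called & is_pos) / sum(is_pos))
  }
  sum(diff(c(0, rec)) * prec)
}

# random annotated scenario labels for a feature matrix with rownames
labels_for <- function(ids, classes) {
  sample_annotation(ids, classes)
}

# numerical Gaussian-regression MLE via BFGS with analytic gradient;
# independent of the closed-form path under test
numeric_node_mle <- function(y, X) {
  n <- length(y)
  Z <- cbind(1, X)
  p <- ncol(Z)
  nll <- function(par) {
    mu <- drop(Z %*% par[seq_len(p)])
    s2 <- exp(par[p + 1L])
    0.5 * n * log(2 * pi * s2) + sum((y - mu)^2) / (2 * s2)
  }
  grad <- function(par) {
    mu <- drop(Z %*% par[seq_len(p)])
    s2 <- exp(par[p + 1L])
    r <- y - mu
    c(-drop(crossprod(Z, r)) / s2,
      0.5 * n - sum(r^2) / (2 * s2))
  }
  start <- c(mean(y), rep(0, p - 1L), log(stats::var(y)))
  opt <- stats::optim(start, nll, grad, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  # Newton polish on the smooth objective
  for (i in 1:50) {
    g <- grad(opt$par)
    h <- numDeriv_hess(nll, opt$par)
    step <- tryCatch(solve(h, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    opt$par <- opt$par - step
    if (max(abs(step)) < 1e-12) break
  }
  list(beta = opt$par[seq_len(p)], sigma2 = exp(opt$par[p + 1L]))
}

# small central-difference Hessian (avoids a numDeriv dependency)
numDeriv_hess <- function(f, x, eps = 1e-5) {
  k <- length(x)
  h <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ei <- ej <- rep(0, k); ei[i] <- eps; ej[j] <- eps
    h[i, j] <- (f(x + ei + ej) - f(x + ei - ej) -
                f(x - ei + ej) + f(x - ei - ej)) / (4 * eps^2)
  }
  (h + t(h)) / 2
}

# independent greedy CORG implementation using stats::t.test directly
corg_oracle <- function(genes, z, a_cols, b_cols) {
  tstat <- function(v) {
    t <- tryCatch(abs(unname(stats::t.test(v[a_cols], v[b_cols])$statistic)),
                  error = function(e) 0)
    if (is.finite(t)) t else 0
  }
  ranked <- genes[order(-vapply(genes, function(g) tstat(z[g, ]), numeric(1)))]
  S <- ranked[1L]
  best <- tstat(z[S, ])
  for (g in ranked[-1L]) {
    cand <- c(S, g)
    act <- colSums(z[cand, , drop = FALSE]) / sqrt(length(cand))
    t2 <- tstat(act)
    if (t2 > best) { S <- cand; best <- t2 } else break
  }
  list(selected = S,
       activity = if (length(S) == 1L) z[S, ] else
         colSums(z[S, , drop = FALSE]) / sqrt(length(S)))
}

# write a tiny KGML document to a temp file
write_kgml_fixture <- function(body, path = tempfile(fileext = ".xml")) {
  writeLines(c('<?xml version="1.0"?>',
               '<pathway name="path:test01" title="Test pathway">',
               body,
               '</pathway>'), path)
  path
}
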