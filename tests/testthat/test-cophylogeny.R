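test_that("patristic distances are path sums with metric structure", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  D <- patristic_matrix(tr)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 4)
  # triangle inequality on random trees
  set.seed(3)
  tr2 <- ape::rtree(8)
  D2 <- patristic_matrix(tr2)
  for (i in 1:6) {
    abc <- sample(rownames(D2), 3)
    expect_lte(D2[abc[1], abc[2]],
               D2[abc[1], abc[3]] + D2[abc[3], abc[2]] + 1e-12)
  }
  tr2$edge.length <- NULL
  expect_error(patristic_matrix(tr2), "branch lengths")
})

test_that("root-to-tip distances respect ultrametry, scaling and partitions", {
  tr <- ape::rcoal(10)
  rtt <- root_to_tip(tr)
  expect_lt(diff(range(rtt$distances)), 1e-10)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 3
  expect_equal(root_to_tip(tr2)$distances, rtt$distances * 3)
  # planted 2:1 rate ratio: plasmid clade deeper than chromosomal
  set.seed(9)
  a <- ape::rcoal(8, tip.label = sprintf("chr%d", 1:8))
  b <- ape::rcoal(8, tip.label = sprintf("pla%d", 1:8))
  b$edge.length <- b$edge.length * 2
  tr3 <- ape::read.tree(text = paste0(
    "(", sub(";$", "", ape::write.tree(a)), ":0.1,",
    sub(";$", "", ape::write.tree(b)), ":0.1);"))
  part <- setNames(c(rep("chromosome", 8), rep("plasmid", 8)), c(a$tip.label, b$tip.label))
  rt <- root_to_tip(tr3, partition = part)
  s <- rt$summary
  expect_gt(s$median[s$partition == "plasmid"],
            s$median[s$partition == "chromosome"])
  unr <- ape::unroot(ape::rtree(5))
  expect_error(root_to_tip(unr), "unrooted")
})

test_that("cophenetic correlation is scale-invariant and label-matched", {
  tr <- ape::rtree(10)
  D <- patristic_matrix(tr)
  expect_equal(cophenetic_correlation(D, D), 1)
  expect_equal(cophenetic_correlation(D, 2 * D), 1)
  # label matching: permuting one matrix must not change r
  perm <- sample(rownames(D))
  expect_equal(cophenetic_correlation(D, D[perm, perm]), 1)
  D2 <- D; rownames(D2) <- colnames(D2) <- paste0("z", seq_len(10))
  expect_error(cophenetic_correlation(D, D2), "label sets differ")
  # independent random distance matrices decorrelate
  set.seed(101)
  rs <- replicate(40, {
    rnd <- function() {
      m <- matrix(runif(50 * 50), 50); m <- m + t(m); diag(m) <- 0
      rownames(m) <- colnames(m) <- sprintf("t%02d", 1:50)
      m
    }
    cophenetic_correlation(rnd(), rnd())
  })
  expect_gte(mean(abs(rs) < 0.3), 0.95)
})

test_that("Robinson-Foulds matches phangorn and handles the extremes", {
  set.seed(7)
  t1 <- ape::rtree(8)
  expect_equal(robinson_foulds(t1, t1)$rf, 0)
  expect_equal(robinson_foulds(t1, t1)$nrf, 0)
  for (i in 1:20) {
    a <- ape::rtree(sample(4:10, 1))
    b <- ape::rtree(length(a$tip.label))
    b$tip.label <- sample(a$tip.label)
    expect_equal(robinson_foulds(a, b)$rf,
                 as.numeric(phangorn::RF.dist(a, b)))
  }
  # one NNI move (swap c and d across the central edge) costs exactly 2
  t <- ape::read.tree(text = "(((a,b),c),d,(e,f));")
  t2 <- ape::read.tree(text = "(((a,b),d),c,(e,f));")
  expect_equal(robinson_foulds(t, t2)$rf, 2)
  t3 <- ape::rtree(5)
  expect_error(robinson_foulds(t1, t3), "tip sets differ")
})

test_that("nRF equals the brute-force bipartition oracle", {
  set.seed(19)
  for (i in 1:80) {
    n <- sample(4:8, 1)
    a <- ape::rtree(n); b <- ape::rtree(n)
    b$tip.label <- sample(a$tip.label)
    got <- robinson_foulds(a, b)
    o <- oracle_rf(a, b)
    expect_equal(got$rf, o$rf)
    expect_equal(got$nrf, if (o$max == 0) 0 else o$rf / o$max)
  }
})

test_that("principal coordinates reproduce Euclidean distances exactly", {
  x <- c(0, 1, 3)
  D <- as.matrix(dist(x))
  rownames(D) <- colnames(D) <- letters[1:3]
  e <- pcoa_cailliez(D)
  expect_equal(e$correction, 0)
  expect_equal(as.matrix(dist(e$vectors)), unname(D) + 0 * D,
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("Cailliez correction is applied, minimal, and matches ape", {
  D <- matrix(c(0, 1, 1, 2.5,
                1, 0, 1, 1,
                1, 1, 0, 1,
                2.5, 1, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  e <- pcoa_cailliez(D)
  expect_gt(e$correction, 0)
  # corrected Gower matrix is PSD
  Dc <- e$D_used
  G <- -0.5 * (diag(4) - 1 / 4) %*% Dc^2 %*% (diag(4) - 1 / 4)
  expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  # coordinates reproduce the corrected distances
  expect_equal(as.matrix(dist(e$vectors)), Dc, ignore_attr = TRUE,
               tolerance = 1e-8)
  # minimality: half the constant still leaves a negative eigenvalue
  Dh <- D + e$correction / 2; diag(Dh) <- 0
  Gh <- -0.5 * (diag(4) - 1 / 4) %*% Dh^2 %*% (diag(4) - 1 / 4)
  expect_lt(min(eigen(Gh, symmetric = TRUE, only.values = TRUE)$values), -1e-6)
  # ape computes the same constant
  ap <- ape::pcoa(as.dist(D), correction = "cailliez")
  c_ape <- as.numeric(sub(".*D \\+ ([0-9.]+) .*", "\\1",
                          gsub("[()]", "", ap$note)))
  expect_equal(e$correction, c_ape, tolerance = 1e-6)
})

test_that("Procrustes superimposition matches vegan and its invariances", {
  set.seed(5)
  X <- matrix(rnorm(24), 8)
  # rotated + translated + scaled copy fits perfectly
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1), 3)
  Y <- 2 * X %*% R + matrix(5, 8, 3)
  fit <- procrustes_fit(X, Y)
  expect_lt(fit$m2, 1e-20)
  expect_true(all(fit$residuals < 1e-10))
  # residuals decompose m2
  Y2 <- X; Y2[3, ] <- Y2[3, ] + 2
  fit2 <- procrustes_fit(X, Y2)
  expect_equal(sum(fit2$residuals^2), fit2$m2)
  expect_equal(which.max(fit2$residuals), 3L)
  # vegan agreement on general input
  Z <- matrix(rnorm(24), 8)
  expect_equal(procrustes_fit(X, Z)$m2,
               vegan::procrustes(X, Z, symmetric = FALSE)$ss,
               tolerance = 1e-10)
  # consistent relabeling leaves m2 unchanged
  p <- sample(8)
  expect_equal(procrustes_fit(X[p, ], Z[p, ])$m2, procrustes_fit(X, Z)$m2,
               tolerance = 1e-10)
  expect_error(procrustes_fit(X[1:2, ], Z[1:2, ]), "at least 3")
})

test_that("PACo is deterministic under seed and its residuals decompose m2", {
  tr <- simulate_cophylogeny(16, 2, seed = 8)
  DH <- patristic_matrix(tr$tree_H); DP <- patristic_matrix(tr$tree_P)
  f1 <- paco(DH, DP, n_perm = 99, seed = 42)
  f2 <- paco(DH, DP, n_perm = 99, seed = 42)
  expect_identical(f1$p_value, f2$p_value)
  expect_identical(f1$perm_stats, f2$perm_stats)
  expect_equal(sum(f1$residuals^2), f1$m2, tolerance = 1e-8)
  expect_error(paco(DH, DP, n_perm = 0), "n_perm")
})

test_that("identical trees give a near-zero PACo statistic and tiny p", {
  tr <- simulate_cophylogeny(16, 0, branch_noise_sd = 0, seed = 2)
  D <- patristic_matrix(tr$tree_H)
  fit <- paco(D, D, n_perm = 199, seed = 42)
  expect_lt(fit$m2, 1e-8)
  expect_lte(fit$p_value, 0.01)
})

test_that("switched tips carry larger residuals than unswitched tips", {
  tr <- simulate_cophylogeny(64, 8, seed = 21)
  fit <- paco(patristic_matrix(tr$tree_H), patristic_matrix(tr$tree_P),
              n_perm = 9, seed = 1)
  sw <- names(fit$residuals) %in% tr$switched_tips
  expect_gt(mean(fit$residuals[sw]), mean(fit$residuals[!sw]))
})

test_that("residual bands follow type-7 quantile arithmetic", {
  r <- seq(0.1, 1.0, by = 0.1)
  b <- classify_residuals(r)
  q <- quantile(r, c(0.25, 0.75, 0.90), type = 7)
  expect_equal(b$q1, unname(q[1]))
  expect_equal(b$q3, unname(q[2]))
  expect_equal(b$p90, unname(q[3]))
  expect_equal(b$extreme_cut, unname(q[2] + 3 * (q[2] - q[1])))
  want <- ifelse(r > b$extreme_cut, "Extreme",
                 ifelse(r >= b$p90, "High",
                        ifelse(r >= b$q1, "Medium", "Low")))
  expect_equal(as.character(b$labels), want)
  expect_error(classify_residuals(c(1, 2, 3)), "at least 4")
})

test_that("published quartiles reproduce the extreme-outlier cutoff", {
  b <- classify_residuals(c(0.2, 0.6, 1.0, 2.0),
                          q1 = 0.38, q3 = 1.14, p90 = 1.35)
  expect_equal(b$extreme_cut, 3.42)
})

test_that("equal residuals all land in High with a degeneracy warning", {
  expect_warning(b <- classify_residuals(rep(0.5, 6)), "degenerate")
  expect_true(all(b$labels == "High"))
})

test_that("the cophylogeny report bundles all statistics coherently", {
  tr <- simulate_cophylogeny(16, 2, seed = 4)
  rep_ <- cophylogeny_report(tr$tree_H, tr$tree_P, n_perm = 49, seed = 42)
  expect_s3_class(rep_, "cophylogeny_report")
  expect_true(rep_$nrf >= 0 && rep_$nrf <= 1)
  expect_equal(length(rep_$paco$residuals), 16)
  expect_equal(length(rep_$bands$labels), 16)
  d <- withr::local_tempdir()
  write_cophylogeny_outputs(rep_, d)
  expect_true(file.exists(file.path(d, "cophylogeny_report.json")))
  js <- jsonlite::read_json(file.path(d, "cophylogeny_report.json"))
  expect_equal(js$n_perm, 49)
})
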