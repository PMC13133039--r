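#' LuxI-LuxR cophylogeny: PACo, residual bands, tree comparisons
#'
#' Codivergence between synthase and regulator trees is quantified with
#' the Procrustean approach to cophylogeny (PACo): each patristic
#' distance matrix is embedded by principal coordinates (with Cailliez's
#' additive correction when the matrix is not Euclidean), the regulator
#' configuration is superimposed on the synthase configuration by
#' least-squares Procrustes rotation, and the residual sum of squares
#' m2 measures global incongruence. Significance comes from permuting
#' the one-to-one tip association; per-link interaction residuals locate
#' the non-codiverging pairs and are banded by empirical quantiles.
#'
#' @name cophylogeny
NULL

#' Patristic (cophenetic) distance matrix of a tree
#'
#' @param tree `phylo` object with branch lengths.
#' @return symmetric matrix of path-length distances between tips.
#' @export
patristic_matrix <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stopf("patristic_matrix: tree has missing branch lengths")
  ape::cophenetic.phylo(tree)
}

#' Root-to-tip distances
#'
#' @param tree rooted `phylo` object with branch lengths.
#' @param partition optional named vector tip -> group label (e.g.
#'   chromosome/plasmid); summaries are reported per group and overall.
#' @return list with `distances` (named per tip) and `summary` (data
#'   frame of median and quartiles per partition level plus `all`).
#' @export
root_to_tip <- function(tree, partition = NULL) {
  if (!ape::is.rooted(tree))
    stopf("root_to_tip: tree is unrooted; reroot it (e.g. ape::root) first")
  if (is.null(tree$edge.length))
    stopf("root_to_tip: tree has no branch lengths")
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  grp <- if (is.null(partition)) rep("all", length(d))
         else unname(partition[names(d)])
  levs <- unique(c(grp, "all"))
  summ <- do.call(rbind, lapply(levs, function(g) {
    x <- if (g == "all") d else d[grp == g]
    data.frame(partition = g, n = length(x),
               q1 = unname(stats::quantile(x, 0.25)),
               median = stats::median(x),
               q3 = unname(stats::quantile(x, 0.75)),
               stringsAsFactors = FALSE)
  }))
  list(distances = d, summary = summ)
}

#' Cophenetic correlation between two distance matrices
#'
#' Pearson correlation over strictly-upper-triangle entries after
#' matching the two matrices on their shared label order.
#'
#' @param D1,D2 symmetric matrices with identical label sets.
#' @return correlation in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(D1, D2) {
  if (!setequal(rownames(D1), rownames(D2)))
    stopf("cophenetic_correlation: label sets differ")
  lab <- rownames(D1)
  D2 <- D2[lab, lab]
  ut <- upper.tri(D1)
  stats::cor(D1[ut], D2[ut])
}

# non-trivial bipartitions of an (implicitly unrooted) tree as canonical
# strings: for each internal edge, the tip set on one side, canonicalised
# to the side containing the alphabetically first tip
bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  anchor <- min(tree$tip.label)
  splits <- character(0)
  desc <- ape::prop.part(tree)  # tip index sets per internal node (clades)
  for (s in desc) {
    tips <- tree$tip.label[s]
    if (length(tips) <= 1L || length(tips) >= n - 1L) next
    side <- if (anchor %in% tips) tips else setdiff(tree$tip.label, tips)
    splits <- c(splits, paste(sort(side), collapse = "\r"))
  }
  unique(splits)
}

#' Robinson-Foulds distance and its normalised form
#'
#' `rf` is the size of the symmetric difference of the two trees'
#' non-trivial bipartitions; `nrf` divides by the maximum attainable
#' value, the sum of the two trees' internal-edge (bipartition) counts.
#'
#' @param t1,t2 `phylo` objects on the same tip set.
#' @return list with `rf` (count) and `nrf` in `[0, 1]`.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stopf("robinson_foulds: tip sets differ")
  b1 <- bipartitions(t1); b2 <- bipartitions(t2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  maxrf <- length(b1) + length(b2)
  list(rf = rf, nrf = if (maxrf == 0) 0 else rf / maxrf)
}

# double-centred Gower matrix of a distance matrix
gower_center <- function(A) {
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

# smallest additive constant making D + c (off-diagonal) Euclidean:
# largest real eigenvalue of the 2n x 2n Cailliez matrix
cailliez_constant <- function(D) {
  n <- nrow(D)
  d1 <- gower_center(-0.5 * D^2)
  d2 <- gower_center(-0.5 * D)
  M <- rbind(cbind(matrix(0, n, n), 2 * d1),
             cbind(-diag(n), -4 * d2))
  ev <- eigen(M, only.values = TRUE)$values
  max(Re(ev[abs(Im(ev)) < 1e-8]))
}

#' Principal coordinates with Cailliez correction
#'
#' Classical metric scaling of a distance matrix. If the Gower-centred
#' matrix is positive semi-definite (within tolerance) the embedding is
#' plain principal coordinates; otherwise the smallest Cailliez constant
#' is added to all off-diagonal distances first, guaranteeing Euclidean
#' embeddability. All axes with positive eigenvalue are kept, so the
#' coordinates reproduce the (corrected) distances to numerical
#' precision.
#'
#' @param D symmetric distance matrix, zero diagonal.
#' @param tol eigenvalue tolerance for calling `D` Euclidean (relative
#'   to the largest eigenvalue; default 1e-8).
#' @return list: `vectors` (n x k coordinates, rownames preserved),
#'   `values` (positive eigenvalues), `correction` (the constant c
#'   added; 0 when none), `D_used` (the embedded distance matrix).
#' @export
pcoa_cailliez <- function(D, tol = 1e-8) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stopf("pcoa_cailliez: distance matrix is not symmetric")
  embed <- function(Dm) {
    G <- gower_center(-0.5 * Dm^2)
    e <- eigen((G + t(G)) / 2, symmetric = TRUE)
    list(G = G, values = e$values, vectors = e$vectors)
  }
  e <- embed(D)
  cc <- 0
  scale_ <- max(abs(e$values))
  if (min(e$values) < -tol * max(scale_, 1)) {
    cc <- cailliez_constant(D)
    Dc <- D + cc
    diag(Dc) <- 0
    D <- Dc
    e <- embed(D)
  }
  keep <- e$values > tol * max(abs(e$values), 1)
  X <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                                nrow = sum(keep))
  rownames(X) <- rownames(D)
  list(vectors = X, values = e$values[keep], correction = cc, D_used = D)
}

#' Least-squares Procrustes superimposition
#'
#' Translates, scales and rotates `Y` onto `X` (reflection allowed)
#' minimising the sum of squared distances between matched rows. Column
#' counts are equalised by zero-padding.
#'
#' @param X,Y numeric matrices with matched rows (same order).
#' @return list: `m2` (minimised residual sum of squares), `residuals`
#'   (per-row Euclidean distances after superimposition; their squares
#'   sum to `m2`), `Yrot` (the transformed `Y`), `scale`, `rotation`.
#' @export
procrustes_fit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stopf("procrustes_fit: row counts differ")
  if (nrow(X) < 3L) stopf("procrustes_fit: need at least 3 matched rows")
  k <- max(ncol(X), ncol(Y))
  pad <- function(M) cbind(M, matrix(0, nrow(M), k - ncol(M)))
  X <- pad(X); Y <- pad(Y)
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  sv <- svd(crossprod(Xc, Yc))
  rot <- sv$v %*% t(sv$u)
  ssY <- sum(Yc^2)
  s <- sum(sv$d) / ssY
  Yrot <- s * Yc %*% rot
  resid <- sqrt(rowSums((Xc - Yrot)^2))
  names(resid) <- rownames(X)
  list(m2 = sum((Xc - Yrot)^2), residuals = resid, Yrot = Yrot,
       scale = s, rotation = rot)
}

#' Procrustean approach to cophylogeny (PACo)
#'
#' Embeds the two patristic matrices (Cailliez-corrected principal
#' coordinates), matches rows through the one-to-one association,
#' superimposes the `D_P` configuration on the `D_H` configuration and
#' reports the Procrustes statistic m2 plus per-link interaction
#' residuals. Significance: the association is randomly re-paired
#' `n_perm` times; with the default `better = "le"` the p-value is the
#' proportion of permuted fits at least as good (m2 no larger) than the
#' observed one, so small p indicates cophylogenetic congruence. The
#' verbatim alternative ("fit >= observed" read as m2 >= observed) is
#' available with `better = "ge"`. An optional add-one correction
#' `(s + 1) / (n_perm + 1)` is off by default to keep the plain
#' proportion definition.
#'
#' @param D_H,D_P patristic matrices (synthase and regulator trees).
#' @param assoc optional two-column matrix/data frame of (host tip,
#'   partner tip) links; default: identity association over shared
#'   labels.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutations (default 42).
#' @param better `"le"` (default) or `"ge"`, see above.
#' @param plus_one apply the add-one p-value correction (default FALSE).
#' @return object of class `paco`: `m2`, `p_value`, `n_perm`, `seed`,
#'   `residuals` (named per link), `perm_stats`, `correction_H`,
#'   `correction_P`.
#' @export
paco <- function(D_H, D_P, assoc = NULL, n_perm = 1000, seed = 42,
                 better = c("le", "ge"), plus_one = FALSE) {
  better <- match.arg(better)
  if (n_perm < 1) stopf("paco: n_perm must be at least 1")
  D_H <- as.matrix(D_H); D_P <- as.matrix(D_P)
  if (is.null(assoc)) {
    shared <- intersect(rownames(D_H), rownames(D_P))
    if (length(shared) < 3L) stopf("paco: fewer than 3 shared labels")
    assoc <- cbind(shared, shared)
  }
  assoc <- as.matrix(assoc)
  eh <- pcoa_cailliez(D_H)
  ep <- pcoa_cailliez(D_P)
  X <- eh$vectors[assoc[, 1], , drop = FALSE]
  Y <- ep$vectors[assoc[, 2], , drop = FALSE]
  obs <- procrustes_fit(X, Y)
  n <- nrow(assoc)

  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      procrustes_fit(X[sample.int(n), , drop = FALSE], Y)$m2
    }, numeric(1))
  })
  s <- if (better == "le") sum(perm_stats <= obs$m2) else sum(perm_stats >= obs$m2)
  p <- if (plus_one) (s + 1) / (n_perm + 1) else s / n_perm

  res <- obs$residuals
  names(res) <- paste(assoc[, 1], assoc[, 2], sep = "<->")
  # with an identity association keep the plain tip label
  if (all(assoc[, 1] == assoc[, 2])) names(res) <- assoc[, 1]
  structure(list(m2 = obs$m2, p_value = p, n_perm = n_perm, seed = seed,
                 better = better, plus_one = plus_one, residuals = res,
                 perm_stats = perm_stats,
                 correction_H = eh$correction, correction_P = ep$correction,
                 assoc = assoc),
            class = "paco")
}

#' @export
print.paco <- function(x, ...) {
  cat(sprintf("<PACo> m2 = %.6g, p = %.4g (%d permutations, seed %s)\n",
              x$m2, x$p_value, x$n_perm, format(x$seed)))
  cat(sprintf("  links: %d; Cailliez constants: H %.4g, P %.4g\n",
              length(x$residuals), x$correction_H, x$correction_P))
  invisible(x)
}

#' @export
summary.paco <- function(object, ...) {
  print(object)
  cat("residual quartiles:\n")
  print(stats::quantile(object$residuals))
  invisible(object)
}

#' @export
residuals.paco <- function(object, ...) object$residuals

#' Band PACo link residuals by empirical quantiles
#'
#' Quantiles (linear-interpolation type 7) of the residual distribution
#' define the bands: Low below Q1, High at or above the 90th percentile,
#' Extreme above `Q3 + 3 * IQR` (a subset of High), Medium otherwise.
#' Band precedence when the definitions overlap: Extreme > High >
#' Medium > Low. Quantiles can be supplied explicitly (e.g. to reproduce
#' a published banding) instead of being estimated from `residuals`.
#'
#' @param residuals numeric vector (named per link); at least 4 values
#'   unless all quantiles are supplied.
#' @param q1,q3,p90 optional quantile overrides.
#' @return object of class `residual_bands`: `q1`, `q3`, `p90`, `iqr`,
#'   `extreme_cut`, `labels` (factor per link), `counts`.
#' @export
classify_residuals <- function(residuals, q1 = NULL, q3 = NULL, p90 = NULL) {
  have_all <- !is.null(q1) && !is.null(q3) && !is.null(p90)
  if (!have_all && length(residuals) < 4L)
    stopf("classify_residuals: need at least 4 residuals")
  q1 <- q1 %||% unname(stats::quantile(residuals, 0.25, type = 7))
  q3 <- q3 %||% unname(stats::quantile(residuals, 0.75, type = 7))
  p90 <- p90 %||% unname(stats::quantile(residuals, 0.90, type = 7))
  iqr <- q3 - q1
  extreme_cut <- q3 + 3 * iqr
  if (length(residuals) > 1L && isTRUE(stats::sd(residuals) == 0))
    warning("degenerate residual distribution: all values equal")
  lab <- vapply(residuals, function(r) {
    if (r > extreme_cut) "Extreme"
    else if (r >= p90) "High"
    else if (r >= q1) "Medium"
    else "Low"
  }, character(1))
  lab <- factor(lab, levels = c("Low", "Medium", "High", "Extreme"))
  structure(list(q1 = q1, q3 = q3, p90 = p90, iqr = iqr,
                 extreme_cut = extreme_cut, labels = lab,
                 counts = table(lab)),
            class = "residual_bands")
}

#' @export
print.residual_bands <- function(x, ...) {
  cat(sprintf("<residual bands> Q1 %.3g | Q3 %.3g | p90 %.3g | extreme cut %.3g\n",
              x$q1, x$q3, x$p90, x$extreme_cut))
  print(x$counts)
  invisible(x)
}

#' Full cophylogeny stage on two Newick trees
#'
#' Reads/accepts the two trees, matches tips, runs nRF, cophenetic
#' correlation, PACo and residual banding, and returns everything in one
#' report object.
#'
#' @param tree_H,tree_P `phylo` objects or Newick file paths (support
#'   values tolerated and ignored).
#' @param n_perm,seed passed to [paco()].
#' @return list of class `cophylogeny_report`.
#' @export
cophylogeny_report <- function(tree_H, tree_P, n_perm = 1000, seed = 42) {
  if (is.character(tree_H)) tree_H <- ape::read.tree(tree_H)
  if (is.character(tree_P)) tree_P <- ape::read.tree(tree_P)
  DH <- patristic_matrix(tree_H)
  DP <- patristic_matrix(tree_P)
  rfres <- robinson_foulds(tree_H, tree_P)
  r <- cophenetic_correlation(DH, DP)
  fit <- paco(DH, DP, n_perm = n_perm, seed = seed)
  bands <- classify_residuals(fit$residuals)
  structure(list(nrf = rfres$nrf, rf = rfres$rf, cophenetic_r = r,
                 paco = fit, bands = bands,
                 tree_H = tree_H, tree_P = tree_P),
            class = "cophylogeny_report")
}

#' @export
print.cophylogeny_report <- function(x, ...) {
  cat(sprintf("<cophylogeny> nRF = %.3f, cophenetic r = %.3f\n", x$nrf,
              x$cophenetic_r))
  print(x$paco)
  print(x$bands)
  invisible(x)
}

#' Write cophylogeny outputs
#'
#' JSON report (m2, p, n_perm, seed, nRF, r), residual TSV with band
#' labels, and a tanglegram-ready paired-tree export (two Newick files
#' plus a link table).
#'
#' @param report `cophylogeny_report` object.
#' @param dir output directory.
#' @export
write_cophylogeny_outputs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(m2 = report$paco$m2, p_value = report$paco$p_value,
                            n_perm = report$paco$n_perm, seed = report$paco$seed,
                            nrf = report$nrf, cophenetic_r = report$cophenetic_r),
                       file.path(dir, "cophylogeny_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_tsv(data.frame(link = names(report$paco$residuals),
                       residual = unname(report$paco$residuals),
                       band = as.character(report$bands$labels)),
            file.path(dir, "paco_residuals.tsv"))
  ape::write.tree(report$tree_H, file.path(dir, "tree_luxI.nwk"))
  ape::write.tree(report$tree_P, file.path(dir, "tree_luxR.nwk"))
  write_tsv(data.frame(luxI_tip = report$paco$assoc[, 1],
                       luxR_tip = report$paco$assoc[, 2]),
            file.path(dir, "tanglegram_links.tsv"))
  invisible(dir)
}
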