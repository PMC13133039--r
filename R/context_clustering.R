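#' Genomic-context fingerprinting and clustering
#'
#' Each detected QSS's neighbourhood (a fixed gene-rank window around the
#' luxI-like gene) is summarised as a binary presence/absence vector over
#' the domain-architecture signatures observed in any window. Contexts
#' are compared with the Jaccard distance, clustered by UPGMA, and the
#' dendrogram is cut at the threshold that maximises the mean silhouette
#' width.
#'
#' @name context_clustering
NULL

#' Build binary context profiles
#'
#' @param qss_inventory data frame from [detect_qss()].
#' @param genes gene table covering the inventory's replicons.
#' @param architectures architecture table from [resolve_architectures()].
#' @param window gene-rank radius around the luxI gene (default 15).
#' @return binary matrix, one row per QSS (rownames = `qss_id`), one
#'   column per architecture signature seen in any window. Columns that
#'   are constant across rows are retained so the vocabulary stays
#'   auditable. Genes with an empty architecture contribute nothing.
#' @export
build_profiles <- function(qss_inventory, genes, architectures, window = 15) {
  sig <- arch_lookup(architectures)
  sets <- list()
  for (i in seq_len(nrow(qss_inventory))) {
    q <- qss_inventory[i, ]
    rep <- genes[genes$replicon_id == q$replicon_id, , drop = FALSE]
    lo <- q$luxI_index - window; hi <- q$luxI_index + window
    win <- rep[rep$index >= lo & rep$index <= hi, , drop = FALSE]
    s <- unique(gene_signature(sig, win$protein_id))
    sets[[q$qss_id]] <- s[nzchar(s)]
  }
  vocab <- sort(unique(unlist(sets)))
  m <- matrix(0L, nrow = length(sets), ncol = length(vocab),
              dimnames = list(names(sets), vocab))
  for (id in names(sets)) m[id, sets[[id]]] <- 1L
  m
}

#' Jaccard distance between two binary rows
#'
#' `1 - |intersection| / |union|` over positions set in either row; two
#' all-zero rows are at distance 0 by convention.
#'
#' @param row_a,row_b binary vectors of equal length.
#' @return distance in `[0, 1]`.
#' @export
jaccard_distance <- function(row_a, row_b) {
  if (length(row_a) != length(row_b))
    stopf("jaccard_distance: length mismatch (%d vs %d)",
          length(row_a), length(row_b))
  a <- row_a != 0; b <- row_b != 0
  u <- sum(a | b)
  if (u == 0) return(0)
  1 - sum(a & b) / u
}

#' Jaccard distance matrix for a binary profile matrix
#'
#' @param m binary matrix (rows = items).
#' @return symmetric distance matrix with zero diagonal.
#' @export
jaccard_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    d[i, j] <- d[j, i] <- jaccard_distance(m[i, ], m[j, ])
  }
  d
}

#' UPGMA hierarchical clustering
#'
#' Average-linkage agglomeration with deterministic tie-breaking: among
#' equally close pairs the one with the lowest (row, column) index merges
#' first. Merge heights are on the ultrametric scale (half the average
#' distance between the merged clusters), so two leaves at distance `d`
#' merge at height `d/2` and every leaf-to-root path has equal length.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @return an object of class `c("upgma", "hclust")` (merge matrix,
#'   heights on the d/2 scale, labels), compatible with
#'   [stats::cutree()], [stats::as.dendrogram()] and
#'   [ape::as.phylo()].
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stopf("upgma: distance matrix is not symmetric")
  n <- nrow(d)
  labels <- rownames(d) %||% as.character(seq_len(n))
  size <- rep(1L, n)
  id <- -seq_len(n)            # hclust convention: negative = leaf
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  work <- d
  for (step in seq_len(n - 1L)) {
    best <- c(Inf, NA, NA)
    idx <- which(active)
    for (ii in seq_along(idx)) for (jj in seq_along(idx)) if (jj > ii) {
      i <- idx[ii]; j <- idx[jj]
      if (work[i, j] < best[1]) best <- c(work[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- best[1] / 2
    # average linkage update into slot i
    for (k in idx) if (k != i && k != j) {
      work[i, k] <- work[k, i] <-
        (size[i] * work[i, k] + size[j] * work[j, k]) / (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    id[i] <- step
  }
  structure(list(merge = merge, height = height,
                 order = hclust_order(merge),
                 labels = labels, method = "upgma (average, d/2 heights)",
                 call = match.call(), dist.method = "user"),
            class = c("upgma", "hclust"))
}

# leaf ordering for plotting, standard recursive untangling
hclust_order <- function(merge) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  rec(nrow(merge))
}

#' Cut a dendrogram at the silhouette-optimal threshold
#'
#' Evaluates every distinct merge height that yields between 2 and
#' `n - 1` clusters as a candidate cut and returns the one maximising
#' the mean silhouette width computed on the supplied distance matrix
#' ([cluster::silhouette()], distance-matrix form). Ties are broken
#' towards the smaller threshold (the finer clustering).
#'
#' @param dendrogram `upgma`/`hclust` object.
#' @param d the distance matrix the dendrogram was built from.
#' @return list of class `context_clustering`: `threshold`, `labels`
#'   (named integer cluster vector), `silhouette` (mean width), `k`.
#' @export
silhouette_cut <- function(dendrogram, d) {
  d <- as.matrix(d)
  n <- length(dendrogram$labels)
  if (n < 3L) stopf("silhouette_cut: need at least 3 leaves")
  hs <- sort(unique(dendrogram$height))
  if (all(d[upper.tri(d)] == 0)) {
    warning("all points identical; returning a single cluster (silhouette 0)")
    labs <- stats::setNames(rep(1L, n), dendrogram$labels)
    return(structure(list(threshold = 0, labels = labs, silhouette = 0, k = 1L,
                          dendrogram = dendrogram),
                     class = "context_clustering"))
  }
  best <- NULL
  # one candidate threshold just below each distinct merge height: the cut
  # keeps exactly the merges formed strictly under that height. The
  # threshold reported is the midpoint below the merge so that
  # cutree(h = threshold) reproduces the labels exactly.
  thresholds <- (c(0, hs[-length(hs)]) + hs) / 2
  for (t in thresholds) {
    labs <- stats::cutree(dendrogram, h = t)
    k <- max(labs)
    if (k < 2L || k > n - 1L) next
    sil <- cluster::silhouette(labs, dmatrix = d)
    s <- mean(sil[, "sil_width"])
    if (is.null(best) || s > best$silhouette + 1e-12) {
      best <- list(threshold = t, labels = stats::setNames(labs, dendrogram$labels),
                   silhouette = s, k = k)
    }
  }
  if (is.null(best)) {
    # fully tied merge heights (e.g. equidistant leaves): no height cut
    # yields 2..n-1 clusters, so fall back to the coarsest 2-group cut
    labs <- stats::cutree(dendrogram, k = 2L)
    sil <- cluster::silhouette(labs, dmatrix = d)
    best <- list(threshold = max(hs),
                 labels = stats::setNames(labs, dendrogram$labels),
                 silhouette = mean(sil[, "sil_width"]), k = 2L)
  }
  best$dendrogram <- dendrogram
  structure(best, class = "context_clustering")
}

#' @export
print.context_clustering <- function(x, ...) {
  cat(sprintf("<context clustering> %d clusters at threshold %.4g (mean silhouette %.3f)\n",
              x$k, x$threshold, x$silhouette))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Convert a UPGMA dendrogram to an ape phylo tree
#'
#' @param dendrogram `upgma`/`hclust` object.
#' @return `phylo` object with branch lengths from merge heights.
#' @export
as_phylo_upgma <- function(dendrogram) {
  ph <- ape::as.phylo(stats::as.hclust(dendrogram))
  ph
}

#' Reroot a context dendrogram on an outgroup leaf
#'
#' Places the root on the edge subtending `outgroup_id` (the convention
#' used to orient the context dendrogram on the outgroup's QSS context).
#' Leaf set and path lengths along the tree are preserved.
#'
#' @param dendrogram `upgma`/`hclust` object or `phylo` tree.
#' @param outgroup_id leaf label.
#' @return rooted `phylo` object.
#' @export
reroot_with_outgroup <- function(dendrogram, outgroup_id) {
  ph <- if (inherits(dendrogram, "phylo")) dendrogram else as_phylo_upgma(dendrogram)
  if (!(outgroup_id %in% ph$tip.label))
    stopf("reroot_with_outgroup: unknown leaf '%s'", outgroup_id)
  ape::root(ph, outgroup = outgroup_id, resolve.root = TRUE)
}

#' Run the full context-clustering stage
#'
#' Profiles, Jaccard distances, UPGMA, silhouette cut and (optionally)
#' outgroup rerooting in one call, with an optional manual reassignment
#' map applied after automatic labelling (never silently: reassigned ids
#' are recorded in the result).
#'
#' @param qss_inventory,genes,architectures,window as [build_profiles()].
#' @param outgroup_id optional leaf (qss id) to reroot on.
#' @param reassign optional named vector `qss_id -> cluster id` applied
#'   after the automatic cut (manual curation hook).
#' @return `context_clustering` object with extra elements `profiles`,
#'   `dist`, `tree` (phylo), `reassigned`.
#' @export
cluster_contexts <- function(qss_inventory, genes, architectures, window = 15,
                             outgroup_id = NULL, reassign = NULL) {
  m <- build_profiles(qss_inventory, genes, architectures, window)
  d <- jaccard_matrix(m)
  den <- upgma(d)
  cut <- silhouette_cut(den, d)
  cut$profiles <- m
  cut$dist <- d
  tree <- as_phylo_upgma(den)
  if (!is.null(outgroup_id)) tree <- reroot_with_outgroup(tree, outgroup_id)
  cut$tree <- tree
  cut$reassigned <- character(0)
  if (!is.null(reassign)) {
    keep <- names(reassign)[names(reassign) %in% names(cut$labels)]
    cut$labels[keep] <- as.integer(reassign[keep])
    cut$reassigned <- keep
  }
  cut
}

#' Write context-clustering outputs
#'
#' Emits the profile matrix (TSV), labels (TSV), dendrogram (Newick) and
#' a silhouette report (JSON) into `dir`.
#'
#' @param clustering `context_clustering` from [cluster_contexts()].
#' @param dir output directory (created if absent).
#' @export
write_context_outputs <- function(clustering, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prof <- data.frame(qss_id = rownames(clustering$profiles),
                     clustering$profiles, check.names = FALSE)
  write_tsv(prof, file.path(dir, "context_matrix.tsv"))
  write_tsv(data.frame(qss_id = names(clustering$labels),
                       cluster = unname(clustering$labels)),
            file.path(dir, "context_labels.tsv"))
  if (!is.null(clustering$tree))
    ape::write.tree(clustering$tree, file.path(dir, "context_dendrogram.nwk"))
  jsonlite::write_json(list(threshold = clustering$threshold,
                            k = clustering$k,
                            silhouette = clustering$silhouette,
                            reassigned = clustering$reassigned),
                       file.path(dir, "silhouette_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
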