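# Independent oracles used to validate the implementations. These are
# deliberately naive (enumeration / recomputation from first principles)
# and share no code with the package internals they check.

# exhaustive maximum-coverage search over non-overlapping hit subsets;
# returns the optimal covered_aa (and the minimal summed log10 E among
# optima). Recursion with include/exclude branching.
oracle_max_coverage <- function(hits) {
  n <- nrow(hits)
  if (n == 0) return(list(coverage = 0L, sumlog = 0))
  overlap <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    hits$env_from[i] <= hits$env_to[j] && hits$env_from[j] <= hits$env_to[i]
  }))
  len <- hits$env_to - hits$env_from + 1L
  loge <- log10(hits$e_value)
  best_cov <- 0L; best_sl <- Inf
  rec <- function(i, chosen, cov, sl) {
    if (i > n) {
      if (cov > best_cov || (cov == best_cov && sl < best_sl)) {
        best_cov <<- cov; best_sl <<- sl
      }
      return(invisible())
    }
    if (!any(overlap[i, chosen])) rec(i + 1L, c(chosen, i), cov + len[i], sl + loge[i])
    rec(i + 1L, chosen, cov, sl)
  }
  rec(1L, integer(0), 0L, 0)
  list(coverage = best_cov, sumlog = best_sl)
}

random_hit_instance <- function(n_max = 12, L = 300) {
  n <- sample.int(n_max, 1)
  from <- sample.int(L - 20L, n, replace = TRUE)
  to <- pmin(L, from + sample.int(80L, n, replace = TRUE))
  domain_hits(protein_id = rep("p1", n),
              pfam_acc = sprintf("PF%05d", sample.int(99999, n)),
              pfam_name = sprintf("D%02d", seq_len(n)),
              env_from = from, env_to = to,
              e_value = 10^runif(n, -30, -4))
}

# naive O(n^3) average-linkage agglomeration; returns merge heights (d/2
# scale) and the full ultrametric cophenetic matrix
oracle_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  U <- matrix(0, n, n)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (avg < best[1]) best <- c(avg, i, j)
    }
    h <- best[1] / 2
    heights <- c(heights, h)
    a <- clusters[[best[2]]]; b <- clusters[[best[3]]]
    U[a, b] <- U[b, a] <- h
    clusters[[best[2]]] <- c(a, b)
    clusters[[best[3]]] <- NULL
  }
  list(heights = heights, cophenetic = U)
}

# independent split enumeration: collects, for every internal edge of the
# unrooted tree, the tip set below it via a hand-written DFS on the edge
# matrix (no ape::prop.part)
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  edge <- tree$edge
  kids <- split(edge[, 2], edge[, 1])
  below <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], below))
  }
  anchor <- min(tree$tip.label)
  out <- character(0)
  for (e in seq_len(nrow(edge))) {
    child <- edge[e, 2]
    if (child <= n) next            # trivial split
    tips <- below(child)
    if (length(tips) >= n - 1L) next
    side <- if (anchor %in% tips) tips else setdiff(tree$tip.label, tips)
    out <- c(out, paste(sort(side), collapse = "\r"))
  }
  unique(out)
}

oracle_rf <- function(t1, t2) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  list(rf = length(setdiff(s1, s2)) + length(setdiff(s2, s1)),
       max = length(s1) + length(s2))
}

# adjusted Rand index between two labelings (mclust is the oracle)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
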