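#' Domain-hit tables and architecture resolution
#'
#' A protein's *domain architecture* is the ordered set of non-overlapping
#' Pfam-A domains that together cover as much of the sequence as possible.
#' hmmscan typically reports several overlapping candidate placements per
#' protein; these functions reduce them to one representative architecture
#' per protein, the vocabulary unit used by all neighbourhood
#' fingerprinting downstream.
#'
#' @name domain_architecture
NULL

#' Construct a domain-hit table
#'
#' @param protein_id,pfam_acc,pfam_name character vectors.
#' @param env_from,env_to 1-based inclusive amino-acid envelope coordinates.
#' @param e_value independent E-values (non-negative).
#' @return data frame of class `domain_hits`.
#' @export
domain_hits <- function(protein_id, pfam_acc, pfam_name, env_from, env_to,
                        e_value) {
  h <- data.frame(protein_id = as.character(protein_id),
                  pfam_acc = as.character(pfam_acc),
                  pfam_name = as.character(pfam_name),
                  env_from = as.integer(env_from),
                  env_to = as.integer(env_to),
                  e_value = as.numeric(e_value),
                  stringsAsFactors = FALSE)
  if (any(h$env_from > h$env_to)) stopf("env_from > env_to in domain hits")
  if (any(h$e_value < 0)) stopf("negative E-value in domain hits")
  class(h) <- c("domain_hits", "data.frame")
  h
}

#' Filter domain hits by E-value
#'
#' Retains hits with `e_value` strictly below `e_cut` (the hmmscan
#' convention used throughout: a hit at exactly the cutoff is dropped).
#' Input order is preserved.
#'
#' @param hits domain-hit data frame (see [domain_hits()]).
#' @param e_cut E-value cutoff; default 0.001.
#' @return the filtered data frame.
#' @export
filter_hits <- function(hits, e_cut = 0.001) {
  stopifnot(is.data.frame(hits))
  hits[hits$e_value < e_cut, , drop = FALSE]
}

#' Resolve one protein's hits into a non-overlapping architecture
#'
#' Selects the subset of pairwise non-overlapping hits that maximises the
#' number of amino acids covered (weighted interval scheduling, exact via
#' dynamic programming on end-sorted intervals). Among subsets of equal
#' coverage the one with the smallest summed log10 E-value wins; any
#' remaining tie is broken lexicographically on the concatenated Pfam
#' accessions. Intervals sharing at least one residue overlap; there is no
#' tolerance window.
#'
#' @param hits domain-hit data frame for a single protein, already
#'   E-value filtered.
#' @param protein_length protein length in amino acids.
#' @return a list of class `protein_architecture` with elements
#'   `protein_id`, `domains` (pfam names ordered by `env_from`),
#'   `signature` (names joined with `"|"`), `covered_aa`,
#'   `protein_length`, and `selected` (the chosen rows of `hits`).
#' @export
resolve_architecture <- function(hits, protein_length) {
  protein_length <- as.integer(protein_length)
  pid <- if (nrow(hits) > 0L) hits$protein_id[1L] else NA_character_
  if (nrow(hits) > 0L) {
    if (length(unique(hits$protein_id)) > 1L)
      stopf("resolve_architecture: hits span multiple proteins")
    if (any(hits$env_to > protein_length))
      stopf("domain hit extends past protein length (%d aa) for %s",
            protein_length, pid)
  }
  if (nrow(hits) == 0L) {
    return(new_architecture(pid, hits, protein_length))
  }

  o <- order(hits$env_to, hits$env_from)
  h <- hits[o, , drop = FALSE]
  n <- nrow(h)
  len <- h$env_to - h$env_from + 1L
  loge <- log10(pmax(h$e_value, .Machine$double.xmin))

  # p[i]: rightmost interval ending before h[i] starts (0 if none)
  p <- integer(n)
  for (i in seq_len(n)) {
    j <- which(h$env_to < h$env_from[i])
    p[i] <- if (length(j)) max(j) else 0L
  }

  # DP over prefix i: best (coverage, -sum log10 E, acc string) using
  # intervals 1..i. Objectives compared lexicographically; coverage and
  # log-E are additive so the optimal-substructure argument is standard.
  cov <- numeric(n + 1L); sle <- numeric(n + 1L); acc <- character(n + 1L)
  take <- logical(n)
  for (i in seq_len(n)) {
    skip <- c(cov[i], sle[i])
    with_i <- c(cov[p[i] + 1L] + len[i], sle[p[i] + 1L] + loge[i])
    acc_with <- paste0(acc[p[i] + 1L], h$pfam_acc[i])
    better <- (with_i[1] > skip[1]) ||
      (with_i[1] == skip[1] && with_i[2] < skip[2]) ||
      (with_i[1] == skip[1] && with_i[2] == skip[2] && acc_with < acc[i])
    if (better) {
      cov[i + 1L] <- with_i[1]; sle[i + 1L] <- with_i[2]
      acc[i + 1L] <- acc_with; take[i] <- TRUE
    } else {
      cov[i + 1L] <- skip[1]; sle[i + 1L] <- skip[2]; acc[i + 1L] <- acc[i]
    }
  }

  sel <- integer(0)
  i <- n
  while (i >= 1L) {
    if (take[i]) { sel <- c(i, sel); i <- p[i] } else i <- i - 1L
  }
  new_architecture(pid, h[sel, , drop = FALSE], protein_length)
}

new_architecture <- function(protein_id, selected, protein_length) {
  selected <- selected[order(selected$env_from), , drop = FALSE]
  covered <- if (nrow(selected)) sum(selected$env_to - selected$env_from + 1L) else 0L
  structure(list(protein_id = protein_id,
                 domains = selected$pfam_name %||% character(0),
                 signature = make_signature(selected$pfam_name),
                 covered_aa = as.integer(covered),
                 protein_length = protein_length,
                 selected = selected),
            class = "protein_architecture")
}

#' @export
print.protein_architecture <- function(x, ...) {
  cat(sprintf("<protein architecture> %s: %s (%d/%s aa covered)\n",
              x$protein_id %||% "?",
              if (nzchar(x$signature)) x$signature else "(none)",
              x$covered_aa,
              if (is.na(x$protein_length)) "?" else x$protein_length))
  invisible(x)
}

#' Resolve architectures for a whole hit table
#'
#' Applies [filter_hits()] then [resolve_architecture()] per protein.
#'
#' @param hits domain-hit data frame covering many proteins.
#' @param protein_lengths named integer vector (names = protein ids). Ids
#'   absent from `hits` yield empty architectures.
#' @param e_cut E-value cutoff passed to [filter_hits()].
#' @return data frame with columns `protein_id`, `signature`,
#'   `covered_aa`, `protein_length`.
#' @export
resolve_architectures <- function(hits, protein_lengths, e_cut = 0.001) {
  hits <- filter_hits(hits, e_cut)
  ids <- names(protein_lengths)
  split_idx <- split(seq_len(nrow(hits)), hits$protein_id)
  sig <- character(length(ids)); cov <- integer(length(ids))
  for (k in seq_along(ids)) {
    rows <- split_idx[[ids[k]]]
    a <- resolve_architecture(hits[rows %||% integer(0), , drop = FALSE],
                              protein_lengths[[k]])
    sig[k] <- a$signature; cov[k] <- a$covered_aa
  }
  data.frame(protein_id = ids, signature = sig, covered_aa = cov,
             protein_length = as.integer(protein_lengths),
             stringsAsFactors = FALSE)
}

#' Read a domain-hit TSV
#'
#' Expects the columns emitted by [simulate_replicons()]:
#' `protein_id`, `pfam_acc`, `pfam_name`, `env_from`, `env_to`, `i_evalue`.
#'
#' @param path TSV path.
#' @return `domain_hits` data frame.
#' @export
read_domain_hits <- function(path) {
  d <- read_tsv(path)
  domain_hits(d$protein_id, d$pfam_acc, d$pfam_name, d$env_from, d$env_to,
              d$i_evalue)
}

#' Read an hmmscan --domtblout file
#'
#' Adapter for hmmer's space-delimited per-domain table: takes the target
#' (domain) name/accession, query (protein) name, independent E-value and
#' envelope coordinates. Lines starting with `#` are skipped.
#'
#' @param path domtblout path.
#' @return `domain_hits` data frame.
#' @export
read_domtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(domain_hits(character(0), character(0), character(0),
                       integer(0), integer(0), numeric(0)))
  }
  f <- strsplit(trimws(lines), "[[:space:]]+")
  get <- function(i) vapply(f, `[[`, "", i)
  # domtblout columns: 1 target name, 2 target acc, 4 query name,
  # 13 i-Evalue, 20 env from, 21 env to
  domain_hits(protein_id = get(4), pfam_acc = sub("\\.\\d+$", "", get(2)),
              pfam_name = get(1), env_from = as.integer(get(20)),
              env_to = as.integer(get(21)), e_value = as.numeric(get(13)))
}

#' Write an architecture table to TSV
#'
#' @param arch data frame from [resolve_architectures()].
#' @param path output path.
#' @export
write_architectures <- function(arch, path) write_tsv(arch, path)
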