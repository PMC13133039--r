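#' Canonical quorum-sensing system detection
#'
#' A canonical QS system (QSS) is a LuxI-like AHL-synthase gene
#' (architecture containing the Pfam domain `Autoind_synth`, PF00765)
#' paired with a LuxR-like regulator (an N-terminal autoinducer-binding
#' domain `Autoind_bind`, PF03472, followed by a C-terminal helix-turn-helix
#' `GerE` domain, PF00196) within a fixed window of neighbouring genes.
#' Detection operates on gene-rank coordinates: the window unit is the
#' position of a gene in the replicon's gene order, not base pairs.
#'
#' @name qss_detection
NULL

# transposase families flagged in QSS neighbourhoods; an architecture
# matches when it contains every domain of a family's signature
TRANSPOSASE_FAMILIES <- list(
  PF01527 = "HTH_Tnp_1",
  PF13610 = "DDE_Tnp_IS240",
  "PF01548|PF02371" = c("DEDD_Tnp_IS110", "Transposase_20")
)

LUXI_DOMAIN <- "Autoind_synth"
LUXR_DOMAINS <- c("Autoind_bind", "GerE")

arch_lookup <- function(architectures) {
  if (is.data.frame(architectures)) {
    stats::setNames(architectures$signature, architectures$protein_id)
  } else {
    unlist(architectures)
  }
}

gene_signature <- function(sig_by_protein, protein_id) {
  s <- sig_by_protein[protein_id]
  ifelse(is.na(s), "", s)
}

has_luxR_architecture <- function(sig) {
  d <- split_signature(sig)
  i <- which(d == "Autoind_bind"); j <- which(d == "GerE")
  length(i) > 0L && length(j) > 0L && min(i) < max(j)
}

#' Find LuxI-like candidate genes on a replicon
#'
#' Returns the genes whose resolved architecture contains `Autoind_synth`
#' (fusions such as `"Autoind_synth|WGR"` qualify). Pseudogenes are
#' returned, carrying their `pseudo` flag, so degraded systems remain
#' visible downstream.
#'
#' @param replicon gene table for one replicon: columns `replicon_id`,
#'   `index` (0-based gene rank), `locus_tag`, `strand`, `start`, `end`,
#'   `protein_id`, `length_aa`, `pseudo`.
#' @param architectures architecture table from [resolve_architectures()]
#'   (or a named signature vector).
#' @return the candidate rows of `replicon`.
#' @export
find_luxI_candidates <- function(replicon, architectures) {
  sig <- arch_lookup(architectures)
  s <- gene_signature(sig, replicon$protein_id)
  hit <- vapply(s, function(x) LUXI_DOMAIN %in% split_signature(x), logical(1))
  replicon[hit, , drop = FALSE]
}

#' Find the cognate LuxR-like partner of a LuxI candidate
#'
#' Scans gene ranks within `window` of the LuxI gene (clipped at replicon
#' ends, no circular wrap-around) for genes whose architecture contains
#' `Autoind_bind` followed by `GerE` in coordinate order. The nearest gene
#' by rank distance wins; an exact distance tie is broken towards the
#' lower index. Additional LuxR-like genes in the window are returned in
#' the `secondary` attribute (luxR duplications).
#'
#' @param replicon gene table (see [find_luxI_candidates()]).
#' @param luxI one row of `replicon` (the LuxI candidate).
#' @param architectures architecture table or named signature vector.
#' @param window gene-rank search radius (default 15).
#' @return the partner gene row, or `NULL` if none; attribute
#'   `secondary` holds further partners ordered by distance.
#' @export
find_luxR_partner <- function(replicon, luxI, architectures, window = 15) {
  sig <- arch_lookup(architectures)
  lo <- max(min(replicon$index), luxI$index - window)
  hi <- min(max(replicon$index), luxI$index + window)
  win <- replicon[replicon$index >= lo & replicon$index <= hi &
                    replicon$index != luxI$index, , drop = FALSE]
  if (!nrow(win)) return(NULL)
  s <- gene_signature(sig, win$protein_id)
  isR <- vapply(s, has_luxR_architecture, logical(1))
  cand <- win[isR, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  dist <- abs(cand$index - luxI$index)
  ord <- order(dist, cand$index)
  cand <- cand[ord, , drop = FALSE]
  best <- cand[1L, , drop = FALSE]
  attr(best, "secondary") <- if (nrow(cand) > 1L) cand[-1L, , drop = FALSE] else NULL
  best
}

#' Classify the luxI/luxR pair configuration
#'
#' Same strand: `tandem`. Opposite strands: `head_to_head` when the 5'
#' ends face each other (divergent transcription), `tail_to_tail` when
#' the 3' ends face (convergent). Pairs more than one rank apart are
#' additionally annotated `separated_by_k` with `k` = rank gap minus one.
#'
#' @param luxI,luxR gene rows on the same replicon.
#' @return list with `configuration` (string), `k` (integer gap).
#' @export
classify_configuration <- function(luxI, luxR) {
  if (luxI$replicon_id != luxR$replicon_id)
    stopf("classify_configuration: genes on different replicons")
  k <- abs(luxI$index - luxR$index) - 1L
  if (luxI$strand == luxR$strand) {
    conf <- "tandem"
  } else {
    first <- if (luxI$start <= luxR$start) luxI else luxR
    second <- if (luxI$start <= luxR$start) luxR else luxI
    # + strand: 5' at start; - strand: 5' at end
    conf <- if (first$strand == "-" && second$strand == "+") "head_to_head"
            else "tail_to_tail"
  }
  list(configuration = if (k > 0L) sprintf("%s_separated_by_%d", conf, k) else conf,
       base_configuration = conf, k = as.integer(k))
}

#' Flag degraded features of a QSS
#'
#' @param qss list as built by [detect_qss()] (elements `luxI`, `luxR`).
#' @param short_luxI_max_aa LuxI proteins at or below this length are
#'   flagged `luxI_short`; default 170 aa, covering the 42-162 aa range
#'   of observed non-functional synthases with margin.
#' @return character vector of flags among `luxI_pseudo`, `luxR_pseudo`,
#'   `luxI_short`, `luxR_missing`.
#' @export
flag_degraded <- function(qss, short_luxI_max_aa = 170) {
  flags <- character(0)
  if (isTRUE(as.logical(qss$luxI$pseudo))) flags <- c(flags, "luxI_pseudo")
  if (qss$luxI$length_aa <= short_luxI_max_aa) flags <- c(flags, "luxI_short")
  if (is.null(qss$luxR)) {
    flags <- c(flags, "luxR_missing")
  } else if (isTRUE(as.logical(qss$luxR$pseudo))) {
    flags <- c(flags, "luxR_pseudo")
  }
  flags
}

#' Flag transposase genes in a QSS neighbourhood
#'
#' Searches the gene-rank window around the luxI--luxR span for
#' architectures matching the transposase families `HTH_Tnp_1` (PF01527),
#' `DDE_Tnp_IS240` (PF13610) and `DEDD_Tnp_IS110|Transposase_20`
#' (PF01548|PF02371). A family found at both lower and higher ranks than
#' the span is `flanked_both_sides`; on exactly one side,
#' `single_adjacent`.
#'
#' @param replicon gene table.
#' @param qss list with `luxI` (and optionally `luxR`) gene rows.
#' @param architectures architecture table or named signature vector.
#' @param window gene-rank radius searched beyond the span (default 15).
#' @return data frame with columns `family` (Pfam accession signature)
#'   and `placement`; zero rows when no transposase is in the window.
#' @export
flag_transposase_context <- function(replicon, qss, architectures, window = 15) {
  sig <- arch_lookup(architectures)
  span <- range(c(qss$luxI$index, if (!is.null(qss$luxR)) qss$luxR$index))
  lo <- max(min(replicon$index), span[1] - window)
  hi <- min(max(replicon$index), span[2] + window)
  win <- replicon[replicon$index >= lo & replicon$index <= hi &
                    (replicon$index < span[1] | replicon$index > span[2]), ,
                  drop = FALSE]
  out <- list()
  for (fam in names(TRANSPOSASE_FAMILIES)) {
    need <- TRANSPOSASE_FAMILIES[[fam]]
    isT <- vapply(gene_signature(sig, win$protein_id),
                  function(x) all(need %in% split_signature(x)), logical(1))
    if (!any(isT)) next
    idx <- win$index[isT]
    placement <- if (any(idx < span[1]) && any(idx > span[2]))
      "flanked_both_sides" else "single_adjacent"
    out[[fam]] <- data.frame(family = fam, placement = placement,
                             stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(family = character(0), placement = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Detect canonical QS systems across a replicon set
#'
#' End-to-end detection: LuxI candidates, cognate LuxR partners within the
#' window, pair configuration, degraded-system flags and transposase
#' context. Each LuxI--LuxR combination is one row (a LuxI with two LuxR
#' partners in the window yields a primary pair plus rows for secondary
#' partners, mirroring the unique-identifier-per-combination convention);
#' LuxI genes without a partner are reported as non-canonical
#' (`luxR_missing`). LuxR-like genes with no LuxI in the window (LuxR
#' solos) are inventoried separately in the `solos` attribute and take no
#' further part in the pipeline.
#'
#' @param genes gene table for one or many replicons (column
#'   `replicon_id` partitions it); needs `rep_type` and `strain_id`
#'   columns for the inventory.
#' @param architectures architecture table from [resolve_architectures()].
#' @param window gene-rank search radius (default 15).
#' @param short_luxI_max_aa threshold for [flag_degraded()].
#' @return data frame (class `qss_inventory`), one row per LuxI--LuxR
#'   combination: `qss_id`, `strain_id`, `replicon_id`, `rep_type`,
#'   `luxI_protein`, `luxR_protein`, `luxI_index`, `luxR_index`,
#'   `configuration`, `canonical`, `degraded_flags`, `transposase_flags`
#'   (flags as comma-joined strings).
#' @export
detect_qss <- function(genes, architectures, window = 15,
                       short_luxI_max_aa = 170) {
  rows <- list(); solos <- list()
  for (rid in unique(genes$replicon_id)) {
    rep <- genes[genes$replicon_id == rid, , drop = FALSE]
    rep <- rep[order(rep$index), , drop = FALSE]
    cand <- find_luxI_candidates(rep, architectures)
    sig <- arch_lookup(architectures)
    isR <- vapply(gene_signature(sig, rep$protein_id), has_luxR_architecture,
                  logical(1))
    paired_R <- character(0)
    n_sys <- 0L
    for (i in seq_len(nrow(cand))) {
      luxI <- cand[i, , drop = FALSE]
      partner <- find_luxR_partner(rep, luxI, architectures, window)
      partners <- list()
      if (!is.null(partner)) {
        partners <- c(list(partner),
                      if (!is.null(attr(partner, "secondary")))
                        split(attr(partner, "secondary"),
                              seq_len(nrow(attr(partner, "secondary")))))
      }
      if (!length(partners)) partners <- list(NULL)
      for (luxR in partners) {
        n_sys <- n_sys + 1L
        qss <- list(luxI = luxI, luxR = luxR)
        conf <- if (!is.null(luxR)) classify_configuration(luxI, luxR) else
          list(configuration = NA_character_)
        dflags <- flag_degraded(qss, short_luxI_max_aa)
        tflags <- flag_transposase_context(rep, qss, architectures, window)
        if (!is.null(luxR)) paired_R <- c(paired_R, luxR$protein_id)
        rows[[length(rows) + 1L]] <- data.frame(
          qss_id = sprintf("%s_qss%02d", rid, n_sys),
          strain_id = rep$strain_id[1] %||% NA_character_,
          replicon_id = rid,
          rep_type = rep$rep_type[1] %||% NA_character_,
          luxI_protein = luxI$protein_id,
          luxR_protein = if (!is.null(luxR)) luxR$protein_id else NA_character_,
          luxI_index = luxI$index,
          luxR_index = if (!is.null(luxR)) luxR$index else NA_integer_,
          configuration = conf$configuration,
          canonical = !is.null(luxR),
          degraded_flags = paste(dflags, collapse = ","),
          transposase_flags = paste(
            sprintf("%s:%s", tflags$family, tflags$placement), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    solo_ids <- rep$protein_id[isR & !(rep$protein_id %in% paired_R)]
    # a LuxR is a solo only if no LuxI candidate lies within the window
    for (pid in solo_ids) {
      ridx <- rep$index[match(pid, rep$protein_id)]
      near_I <- any(abs(cand$index - ridx) <= window)
      if (!near_I) solos[[length(solos) + 1L]] <-
        data.frame(replicon_id = rid, protein_id = pid, index = ridx,
                   stringsAsFactors = FALSE)
    }
  }
  inv <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
         else data.frame(qss_id = character(0), strain_id = character(0),
                         replicon_id = character(0), rep_type = character(0),
                         luxI_protein = character(0), luxR_protein = character(0),
                         luxI_index = integer(0), luxR_index = integer(0),
                         configuration = character(0), canonical = logical(0),
                         degraded_flags = character(0),
                         transposase_flags = character(0),
                         stringsAsFactors = FALSE)
  attr(inv, "solos") <- if (length(solos))
    do.call(rbind, c(solos, list(make.row.names = FALSE))) else NULL
  class(inv) <- c("qss_inventory", "data.frame")
  inv
}

#' Write a QSS inventory to TSV
#'
#' @param inventory data frame from [detect_qss()].
#' @param path output path.
#' @export
write_qss_inventory <- function(inventory, path) {
  write_tsv(as.data.frame(inventory), path)
}
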