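#' ANI-based replicon grouping and trait-based plasmid categories
#'
#' Genomes are grouped at 95% average nucleotide identity with at least
#' 70% query coverage bidirectionally; plasmids at 95% identity and 75%
#' coverage. Grouping is single-linkage: the described two-pass procedure
#' (group mutually matching replicons, then attach anything matching at
#' least one member) is exactly connected components of the
#' threshold-passing pair graph. Plasmids are then typed by trait
#' booleans (repABC, symbiosis, conjugation, RctA, QSS, QS-linked
#' conjugation) and assigned one of eight categories A-H.
#'
#' @name replicon_classification
NULL

# default Pfam-domain fixture for the tra/trb (Dtr + Mpf) conjugation
# machinery; editable because the canonical list lives in supplementary
# material of the underlying survey and completeness rules differ by
# plasmid family
DEFAULT_CONJ_DOMAINS <- c("TraG_N", "TrwB_AAD_bind", "Relaxase",
                          "T4SS-DNA_transf", "CagE_TrbE_VirB4",
                          "TrbC_Ftype", "CagX", "TrbL", "VirB8", "VirB3")

DEFAULT_MARKERS <- list(
  repABC = c("RepA", "RepB", "RepC"),   # any one marks the family
  rctA = "RctA",
  nif = "Fer4_NifH",
  nod = "NodA"
)

#' Cluster replicons by ANI rules
#'
#' Builds the graph whose edges are replicon pairs meeting both the
#' identity and coverage thresholds (both directions of coverage when
#' `bidirectional`) and returns its connected components
#' (single-linkage). Non-singleton groups are numbered by decreasing
#' size; singletons are either reported individually or pooled into one
#' miscellaneous group (the convention for orphan plasmids).
#'
#' @param records ANI table: columns `query_id`, `subject_id`,
#'   `identity_pct` (0-100), `qcov`, `scov` (proportions). One row per
#'   ordered or unordered pair; identity must agree between directions.
#' @param ids optional full replicon id set (replicons absent from
#'   `records` become singletons).
#' @param id_min identity threshold in percent (default 95).
#' @param cov_min coverage threshold as a proportion (default 0.70).
#' @param bidirectional require both qcov and scov above `cov_min`
#'   (default TRUE); otherwise either direction suffices.
#' @param pool_singletons pool all singletons into one group (default
#'   FALSE).
#' @param misc_label label of the pooled singleton group (default
#'   `"77"`, the orphan-plasmid convention).
#' @return list with `groups` (named character vector id -> group
#'   label), `sizes`, and `orphans` (singleton ids).
#' @export
cluster_by_ani <- function(records, ids = NULL, id_min = 95, cov_min = 0.70,
                           bidirectional = TRUE, pool_singletons = FALSE,
                           misc_label = "77") {
  ids <- unique(c(ids, records$query_id, records$subject_id))
  pass_cov <- if (bidirectional) pmin(records$qcov, records$scov)
              else pmax(records$qcov, records$scov)
  edge <- records$identity_pct >= id_min & pass_cov >= cov_min &
    records$query_id != records$subject_id
  g <- igraph::graph_from_data_frame(
    records[edge, c("query_id", "subject_id"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  member <- split(ids, comp$membership)
  sizes <- lengths(member)
  real <- member[sizes > 1L]
  real <- real[order(-sizes[sizes > 1L], vapply(real, min, ""))]
  groups <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (k in seq_along(real)) groups[real[[k]]] <- as.character(k)
  orphans <- ids[is.na(groups)]
  if (pool_singletons) {
    groups[orphans] <- misc_label
  } else {
    groups[orphans] <- paste0("singleton_", orphans)
  }
  list(groups = groups,
       sizes = table(groups),
       orphans = orphans)
}

#' Name ANI clusters by reference-strain precedence
#'
#' Clusters containing exactly one reference strain take that species
#' name; clusters with several references take the earliest-described
#' species (publication year precedence); reference-free clusters of two
#' or more members become sequential `tax_group` letters; singletons
#' become `"sp."`.
#'
#' @param groups named vector id -> group label (from
#'   [cluster_by_ani()]).
#' @param reference_strains named character vector: reference replicon id
#'   -> species name.
#' @param precedence named numeric vector: species name -> year of first
#'   description. Required whenever a cluster holds two or more
#'   reference species; a contested cluster with a missing year is an
#'   error (names are never guessed).
#' @return named character vector id -> assigned name.
#' @export
name_clusters <- function(groups, reference_strains, precedence = NULL) {
  out <- stats::setNames(rep(NA_character_, length(groups)), names(groups))
  tax_letter <- 0L
  for (grp in unique(groups)) {
    members <- names(groups)[groups == grp]
    refs <- reference_strains[names(reference_strains) %in% members]
    species <- unique(unname(refs))
    if (length(species) == 1L) {
      out[members] <- species
    } else if (length(species) > 1L) {
      yrs <- precedence[species]
      if (is.null(precedence) || anyNA(yrs))
        stopf("name_clusters: publication year missing for contested cluster {%s}",
              paste(species, collapse = ", "))
      out[members] <- species[which.min(yrs)]
    } else if (length(members) >= 2L) {
      tax_letter <- tax_letter + 1L
      out[members] <- paste0("tax_group_", LETTERS[tax_letter])
    } else {
      out[members] <- "sp."
    }
  }
  out
}

#' Detect plasmid traits
#'
#' Trait booleans from a replicon's gene table and resolved
#' architectures: `has_nif` (Fer4_NifH domain), `has_nod` (NodA),
#' `has_repABC` / `has_rctA` (configurable annotation markers),
#' `has_conjugation` (fraction of the tra/trb domain fixture present at
#' or above `completeness_min`), `has_qss` (any QSS on the replicon in
#' the inventory) and `qs_linked_conjugation` (a luxI/luxR-like gene
#' within `conj_window` gene ranks of a tra/trb-domain gene).
#'
#' @param replicon gene table for one replicon.
#' @param architectures architecture table or named signature vector.
#' @param qss_inventory inventory from [detect_qss()] (may cover many
#'   replicons).
#' @param conj_domain_set required tra/trb Pfam names (default
#'   `DEFAULT_CONJ_DOMAINS`).
#' @param completeness_min fraction of `conj_domain_set` required
#'   (default 0.75).
#' @param conj_window gene-rank window linking QS genes to the
#'   conjugation machinery (default 25; conjugative neighbourhoods are
#'   larger and more variable than ordinary QSS contexts).
#' @param markers marker list overriding `DEFAULT_MARKERS`.
#' @return one-row data frame of trait booleans plus
#'   `conjugation_completeness`.
#' @export
detect_traits <- function(replicon, architectures, qss_inventory,
                          conj_domain_set = DEFAULT_CONJ_DOMAINS,
                          completeness_min = 0.75, conj_window = 25,
                          markers = DEFAULT_MARKERS) {
  sig <- arch_lookup(architectures)
  sigs <- gene_signature(sig, replicon$protein_id)
  doms <- lapply(sigs, split_signature)
  all_doms <- unique(unlist(doms))
  rid <- replicon$replicon_id[1]

  has_nif <- markers$nif %in% all_doms
  has_nod <- markers$nod %in% all_doms
  has_repABC <- any(markers$repABC %in% all_doms)
  has_rctA <- any(markers$rctA %in% all_doms)
  found <- sum(conj_domain_set %in% all_doms)
  completeness <- found / length(conj_domain_set)
  has_conj <- completeness >= completeness_min

  qss_here <- qss_inventory[qss_inventory$replicon_id == rid, , drop = FALSE]
  has_qss <- nrow(qss_here) > 0L

  qs_linked <- FALSE
  if (has_conj && has_qss) {
    conj_idx <- replicon$index[vapply(doms, function(x)
      any(conj_domain_set %in% x), logical(1))]
    qs_idx <- replicon$index[vapply(doms, function(x)
      LUXI_DOMAIN %in% x || all(LUXR_DOMAINS %in% x), logical(1))]
    qs_linked <- any(vapply(qs_idx, function(i)
      any(abs(conj_idx - i) <= conj_window), logical(1)))
  }

  data.frame(replicon_id = rid, has_repABC = has_repABC, has_nif = has_nif,
             has_nod = has_nod, has_conjugation = has_conj,
             qs_linked_conjugation = qs_linked, has_rctA = has_rctA,
             has_qss = has_qss, conjugation_completeness = completeness,
             stringsAsFactors = FALSE)
}

#' Assign a plasmid category (A-H)
#'
#' Decision table evaluated top-down over the trait space (symbiotic =
#' nif or nod):
#' QS & conjugative & symbiotic -> D; QS & conjugative & RctA -> G;
#' QS & conjugative -> B; QS & symbiotic -> C; QS -> A;
#' symbiotic without QS -> E; conjugative without QS -> F;
#' otherwise H (cryptic). Total and deterministic: every combination of
#' traits maps to exactly one label.
#'
#' @param traits one-row data frame from [detect_traits()] (or any list
#'   with the boolean fields).
#' @return single character, one of `"A"` to `"H"`.
#' @export
assign_category <- function(traits) {
  qs <- isTRUE(as.logical(traits$has_qss))
  conj <- isTRUE(as.logical(traits$has_conjugation))
  sym <- isTRUE(as.logical(traits$has_nif)) || isTRUE(as.logical(traits$has_nod))
  rct <- isTRUE(as.logical(traits$has_rctA))
  if (qs && conj && sym) return("D")
  if (qs && conj && rct) return("G")
  if (qs && conj) return("B")
  if (qs && sym) return("C")
  if (qs) return("A")
  if (sym) return("E")
  if (conj) return("F")
  "H"
}

#' Classify all plasmids of a gene table
#'
#' Convenience wrapper: traits plus category per plasmid replicon.
#'
#' @param genes gene table (replicons with `rep_type == "plasmid"` are
#'   classified).
#' @param architectures,qss_inventory,... passed to [detect_traits()].
#' @return data frame: traits columns plus `category`.
#' @export
classify_plasmids <- function(genes, architectures, qss_inventory, ...) {
  plasmids <- unique(genes$replicon_id[genes$rep_type == "plasmid"])
  rows <- lapply(plasmids, function(rid) {
    tr <- detect_traits(genes[genes$replicon_id == rid, , drop = FALSE],
                        architectures, qss_inventory, ...)
    tr$category <- assign_category(tr)
    tr
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read an ANI TSV
#'
#' Columns `query`/`query_id`, `subject`/`subject_id`, `identity_pct`,
#' `qcov`, `scov`.
#'
#' @param path TSV path.
#' @return normalised ANI data frame.
#' @export
read_ani_table <- function(path) {
  d <- read_tsv(path)
  names(d)[names(d) == "query"] <- "query_id"
  names(d)[names(d) == "subject"] <- "subject_id"
  d
}

#' Group-by-category incidence table
#'
#' Machine-readable twin of a groups-vs-categories ribbon figure: counts
#' of plasmids per (ANI group, category) cell.
#'
#' @param groups named vector plasmid id -> group label.
#' @param categories data frame from [classify_plasmids()] (columns
#'   `replicon_id`, `category`).
#' @return contingency table.
#' @export
group_category_incidence <- function(groups, categories) {
  table(group = groups[categories$replicon_id],
        category = categories$category)
}
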