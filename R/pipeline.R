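#' End-to-end pipeline orchestration
#'
#' [run_all()] drives the stages in order -- architecture resolution,
#' QSS detection, context clustering, replicon classification,
#' cophylogeny -- from a single configuration, either on files on disk
#' or on a freshly generated simulation, and writes a manifest plus a
#' summary so a run is reproducible from its configuration alone.
#'
#' @name pipeline
NULL

#' Default run configuration
#'
#' All thresholds the pipeline keys on, at their standard values:
#' 15-gene window (25 for conjugation linkage), E-value cutoff 0.001,
#' ANI 95%/70% bidirectional for genomes and 95%/75% for plasmids,
#' 170 aa short-LuxI threshold, 1000 PACo permutations with seed 42.
#'
#' @param ... overrides for any field.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(window = 15, conj_window = 25, e_cut = 0.001,
              ani_genome = list(id_min = 95, cov_min = 0.70, bidirectional = TRUE),
              ani_plasmid = list(id_min = 95, cov_min = 0.75, bidirectional = TRUE),
              short_luxI_max_aa = 170, n_perm = 1000, seed = 42,
              simulate = NULL, genes = NULL, domains = NULL, ani = NULL,
              tree_H = NULL, tree_P = NULL, out = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Run the full pipeline
#'
#' @param config `run_config`; either the `simulate` field holds a
#'   [sim_config()] or the input paths (`genes`, `domains`, optionally
#'   `ani`, `tree_H`, `tree_P`) are set.
#' @param out output directory (overrides `config$out`); when `NULL`
#'   nothing is written and the report is only returned.
#' @return list of class `qsce_run`: per-stage results plus a `summary`
#'   list (counts of QSS per replicon type, context clusters, ANI
#'   groups, categories, cophylogeny statistics) and a `manifest`.
#' @export
run_all <- function(config = run_config(), out = NULL) {
  out <- out %||% config$out
  trees <- NULL; ani <- NULL; truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- simulate_replicons(config$simulate)
    genes <- sim$genes
    hits <- sim$hits
    truth <- sim$ground_truth
    ani_sim <- simulate_ani_table(config$simulate)
    ani <- ani_sim$ani
    trees <- simulate_cophylogeny(config$simulate$tree_n_tips,
                                  config$simulate$n_switch_events,
                                  config$simulate$branch_rate,
                                  config$simulate$branch_noise_sd,
                                  seed = config$simulate$seed)
  } else {
    if (is.null(config$genes) || is.null(config$domains))
      stopf("run_all: need either a simulate block or genes+domains paths")
    genes <- read_tsv(config$genes)
    hits <- read_domain_hits(config$domains)
    if (!is.null(config$ani)) ani <- read_ani_table(config$ani)
    if (!is.null(config$tree_H) && !is.null(config$tree_P))
      trees <- list(tree_H = ape::read.tree(config$tree_H),
                    tree_P = ape::read.tree(config$tree_P))
  }

  plen <- stats::setNames(genes$length_aa, genes$protein_id)
  arch <- resolve_architectures(hits, plen, e_cut = config$e_cut)
  inventory <- detect_qss(genes, arch, window = config$window,
                          short_luxI_max_aa = config$short_luxI_max_aa)

  canonical <- inventory[inventory$canonical, , drop = FALSE]
  contexts <- NULL
  if (nrow(canonical) >= 3L) {
    contexts <- cluster_contexts(canonical, genes, arch,
                                 window = config$window)
  } else if (nrow(canonical) == 0L) {
    warning("no canonical QS systems detected; context and tree stages skipped")
  }

  plasmid_cats <- classify_plasmids(genes, arch, inventory,
                                    conj_window = config$conj_window)
  ani_groups <- NULL
  if (!is.null(ani)) {
    thr <- config$ani_plasmid
    ani_groups <- cluster_by_ani(ani, id_min = thr$id_min,
                                 cov_min = thr$cov_min,
                                 bidirectional = thr$bidirectional,
                                 pool_singletons = TRUE)
  }
  cophy <- NULL
  if (!is.null(trees) && nrow(canonical) > 0L) {
    cophy <- cophylogeny_report(trees$tree_H, trees$tree_P,
                                n_perm = config$n_perm, seed = config$seed)
  }

  summary <- list(
    n_replicons = length(unique(genes$replicon_id)),
    n_qss = nrow(inventory),
    n_canonical = nrow(canonical),
    qss_per_rep_type = as.list(table(inventory$rep_type[inventory$canonical])),
    n_context_clusters = if (!is.null(contexts)) contexts$k else 0L,
    context_silhouette = if (!is.null(contexts)) contexts$silhouette else NA,
    n_ani_groups = if (!is.null(ani_groups))
      sum(names(ani_groups$sizes) != "77" &
            !startsWith(names(ani_groups$sizes), "singleton")) else NA,
    categories = as.list(table(plasmid_cats$category)),
    cophylogeny = if (!is.null(cophy))
      list(m2 = cophy$paco$m2, p_value = cophy$paco$p_value,
           nrf = cophy$nrf, r = cophy$cophenetic_r) else NULL)
  manifest <- list(package_version = as.character(utils::packageVersion("qsce")),
                   r_version = R.version.string,
                   seed = config$seed,
                   sim_seed = if (!is.null(config$simulate)) config$simulate$seed,
                   window = config$window, e_cut = config$e_cut,
                   n_perm = config$n_perm)

  res <- structure(list(genes = genes, architectures = arch,
                        inventory = inventory, contexts = contexts,
                        plasmid_categories = plasmid_cats,
                        ani_groups = ani_groups, cophylogeny = cophy,
                        ground_truth = truth, summary = summary,
                        manifest = manifest),
                   class = "qsce_run")
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_tsv(genes, file.path(out, "genes.tsv"))
    write_architectures(arch, file.path(out, "architectures.tsv"))
    write_qss_inventory(inventory, file.path(out, "qss_inventory.tsv"))
    if (!is.null(contexts)) write_context_outputs(contexts, out)
    write_tsv(plasmid_cats, file.path(out, "plasmid_categories.tsv"))
    if (!is.null(ani_groups))
      write_tsv(data.frame(replicon_id = names(ani_groups$groups),
                           group = unname(ani_groups$groups)),
                file.path(out, "ani_groups.tsv"))
    if (!is.null(ani_groups))
      utils::write.csv(as.data.frame.matrix(
        group_category_incidence(ani_groups$groups, plasmid_cats)),
        file.path(out, "group_category_incidence.csv"))
    if (!is.null(cophy)) write_cophylogeny_outputs(cophy, out)
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.qsce_run <- function(x, ...) {
  s <- x$summary
  cat("<qsce run>\n")
  cat(sprintf("  replicons: %d | QSS: %d (%d canonical)\n",
              s$n_replicons, s$n_qss, s$n_canonical))
  cat(sprintf("  context clusters: %s | ANI groups: %s\n",
              format(s$n_context_clusters), format(s$n_ani_groups)))
  if (!is.null(s$cophylogeny))
    cat(sprintf("  PACo m2 = %.4g, p = %.4g; nRF = %.3f, r = %.3f\n",
                s$cophylogeny$m2, s$cophylogeny$p_value, s$cophylogeny$nrf,
                s$cophylogeny$r))
  invisible(x)
}
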