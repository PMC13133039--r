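#' Synthetic pipeline inputs with known ground truth
#'
#' The generator emulates the four input kinds the pipeline consumes --
#' per-replicon gene tables, per-protein domain-hit tables, pairwise ANI
#' tables and paired Newick trees -- with planted structure (context
#' templates, plasmid traits, ANI blocks, codivergence with host
#' switches) so every downstream stage has a parameter-recovery test.
#' Only annotations are simulated, never nucleotide or amino-acid
#' sequence.
#'
#' @name synthetic_data
NULL

# Pfam name -> accession for the domains the pipeline keys on; synthetic
# accessions are generated for everything else
PFAM_ACC <- c(Autoind_synth = "PF00765", Autoind_bind = "PF03472",
              GerE = "PF00196", HTH_Tnp_1 = "PF01527",
              DDE_Tnp_IS240 = "PF13610", DEDD_Tnp_IS110 = "PF01548",
              Transposase_20 = "PF02371", Fer4_NifH = "PF00142",
              NodA = "PF02474", WGR = "PF05406")

pfam_acc_of <- function(name) {
  acc <- PFAM_ACC[name]
  miss <- is.na(acc)
  acc[miss] <- sprintf("PFX%05d",
                       vapply(name[miss], function(s)
                         sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 100000L,
                         integer(1)))
  unname(acc)
}

#' Shipped genomic-context templates
#'
#' Four context templates mirroring well-characterised rhizobial QSS
#' neighbourhoods: `A` (the prevalent chromosomal context: a cinI/cinR
#' tandem pair with seven conserved flanking genes, among them DUF4174-
#' and DUF2934-carrying proteins), `E` (the symbiotic rhiI-rhiABCD-rhiR
#' arrangement flanked by nod/nif genes; rhiA and rhiC carry no Pfam
#' domain), `AA` (plasmid raiI/raiR with the Lrp-family dadR regulator
#' and alanine-metabolism genes) and `AI` (conjugative traI/traR
#' divergent pair embedded between the tra and trb operons). Each
#' template has exactly one Autoind_synth slot and at most one
#' Autoind_bind+GerE slot.
#'
#' @return named list of templates; each is a list with `template_id`,
#'   `replicon` (`"chromosome"` or `"plasmid"`), `configuration` and
#'   `slots` (data frame: `offset` relative to the luxI gene,
#'   `signature`, `strand`, `role`).
#' @export
context_templates <- function() {
  tpl <- function(id, replicon, configuration, offset, signature, strand, role) {
    list(template_id = id, replicon = replicon, configuration = configuration,
         slots = data.frame(offset = offset, signature = signature,
                            strand = strand, role = role,
                            stringsAsFactors = FALSE))
  }
  list(
    A = tpl("A", "chromosome", "tandem",
            offset = c(-4, -3, -2, -1, 0, 1, 2, 3, 4),
            signature = c("DUF4174", "DUF2934", "SBP_bac_8", "GntR|FCD",
                          "Autoind_synth", "Autoind_bind|GerE",
                          "Response_reg|Trans_reg_C", "HTH_1", "ABC_tran"),
            strand = c("+", "+", "+", "+", "+", "+", "-", "-", "+"),
            role = c(rep("flank", 4), "luxI", "luxR", rep("flank", 3))),
    E = tpl("E", "chromosome", "separated_by_4",
            offset = c(-2, -1, 0, 1, 2, 3, 4, 5, 6, 7),
            signature = c("NodA", "Fer4_NifH", "Autoind_synth", "",
                          "Phage_tail_collar", "", "Abhydrolase_3",
                          "Autoind_bind|GerE", "Oxidored_nitro", "Fer4"),
            strand = c("-", "-", "+", "+", "+", "+", "+", "+", "+", "+"),
            role = c("flank", "flank", "luxI", rep("flank", 4), "luxR",
                     "flank", "flank")),
    AA = tpl("AA", "plasmid", "tandem",
             offset = c(-3, -2, -1, 0, 1, 2),
             signature = c("Ala_racemase_N", "Aminotran_5",
                           "AsnC_trans_reg|AsnC_family", "Autoind_synth",
                           "Autoind_bind|GerE", "DAO"),
             strand = c("+", "+", "-", "+", "+", "+"),
             role = c(rep("flank", 3), "luxI", "luxR", "flank")),
    AI = tpl("AI", "plasmid", "head_to_head",
             offset = c(-5, -4, -3, -2, -1, 0, 1, 2, 3, 4, 5, 6),
             signature = c("TraG_N", "TrwB_AAD_bind", "Relaxase",
                           "T4SS-DNA_transf", "Autoind_bind|GerE",
                           "Autoind_synth", "CagE_TrbE_VirB4", "TrbC_Ftype",
                           "CagX", "TrbL", "VirB8", "VirB3"),
             strand = c("-", "-", "-", "-", "-", "+", "+", "+", "+", "+",
                        "+", "+"),
             role = c(rep("flank", 4), "luxR", "luxI", rep("flank", 6)))
  )
}

#' Simulation configuration
#'
#' @param n_strains number of strains (default 10).
#' @param plasmids_per_strain integer range `c(min, max)`; raised to the
#'   number of plasmid-borne templates when smaller.
#' @param templates character vector of template ids to plant (from
#'   [context_templates()]).
#' @param n_noise_genes accessory genes per replicon, each with a unique
#'   architecture signature disjoint from every template vocabulary
#'   (default 60).
#' @param degraded_fraction proportion of planted systems degraded
#'   (default 0).
#' @param degraded_mode `"short_luxI"` (LuxI length drawn uniformly from
#'   42-162 aa), `"luxR_missing"` (LuxR slot removed) or `"mixed"`.
#' @param transposase_fraction proportion of planted systems flanked by
#'   inserted PF01527-architecture transposase genes (default 0).
#' @param spurious_hit_fraction per-gene probability of an extra
#'   overlapping domain hit with an E-value at least 10x the true hit's
#'   (default 0.1), making overlap resolution decidable.
#' @param ani_group_spec data frame with columns `size`,
#'   `identity` (percent), `coverage` (proportion) describing planted
#'   ANI blocks.
#' @param n_ani_orphans designated orphans with no partner above
#'   thresholds (default 2).
#' @param tree_n_tips,n_switch_events,branch_rate,branch_noise_sd
#'   cophylogeny simulation parameters (see [simulate_cophylogeny()]).
#' @param seed integer RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 10, plasmids_per_strain = c(2, 3),
                       templates = c("A", "E", "AA", "AI"),
                       n_noise_genes = 60,
                       degraded_fraction = 0, degraded_mode = "mixed",
                       transposase_fraction = 0,
                       spurious_hit_fraction = 0.1,
                       ani_group_spec = data.frame(size = c(3, 2),
                                                   identity = c(97, 96),
                                                   coverage = c(0.9, 0.85)),
                       n_ani_orphans = 2,
                       tree_n_tips = 32, n_switch_events = 0,
                       branch_rate = 0.1, branch_noise_sd = 0.25,
                       seed = 1) {
  cfg <- list(n_strains = n_strains, plasmids_per_strain = plasmids_per_strain,
              templates = templates, n_noise_genes = n_noise_genes,
              degraded_fraction = degraded_fraction,
              degraded_mode = degraded_mode,
              transposase_fraction = transposase_fraction,
              spurious_hit_fraction = spurious_hit_fraction,
              ani_group_spec = ani_group_spec, n_ani_orphans = n_ani_orphans,
              tree_n_tips = tree_n_tips, n_switch_events = n_switch_events,
              branch_rate = branch_rate, branch_noise_sd = branch_noise_sd,
              seed = seed)
  props <- c(degraded_fraction, transposase_fraction, spurious_hit_fraction)
  if (any(props < 0 | props > 1)) stopf("sim_config: proportions must be in [0,1]")
  if (n_strains < 1 || n_noise_genes < 0) stopf("sim_config: counts must be positive")
  if (any(ani_group_spec$identity < 0 | ani_group_spec$identity > 100))
    stopf("sim_config: ANI identity must be in [0,100]")
  if (!all(templates %in% names(context_templates())))
    stopf("sim_config: unknown template id(s): %s",
          paste(setdiff(templates, names(context_templates())), collapse = ", "))
  if (branch_rate <= 0) stopf("sim_config: branch_rate must be positive")
  structure(cfg, class = "sim_config")
}

# gene "spec" rows used while assembling a replicon
gene_spec <- function(signature, strand, length_aa, pseudo = FALSE,
                      role = "noise", template = NA_character_) {
  data.frame(signature = signature, strand = strand,
             length_aa = as.integer(length_aa), pseudo = pseudo, role = role,
             template = template, degraded = "none", has_tnp = FALSE,
             stringsAsFactors = FALSE)
}

# sample that never falls into the 1:x scalar trap
resample <- function(x, n) x[sample.int(length(x), n)]

# insert `block` (data frame of gene specs) into `base` after position p
# (0 = before everything)
insert_block <- function(base, block, p) {
  rbind(base[seq_len(p), , drop = FALSE], block,
        base[seq_len(nrow(base)) > p, , drop = FALSE])
}

#' Simulate gene tables and domain hits with planted QS systems
#'
#' Each strain receives one chromosome and a number of plasmids; every
#' template in the configuration is planted once per strain on a
#' replicon of its kind, surrounded by noise genes with unique
#' signatures disjoint from all template vocabularies. Planted blocks
#' are kept more than a detection window apart; a configuration whose
#' templates cannot be placed that far apart on the replicon is
#' rejected. Plasmids additionally carry a repABC replication block.
#' Degraded systems lose their LuxR slot or get a LuxI drawn from the
#' 42-162 aa range; transposase-flagged systems gain PF01527 genes on
#' both sides of the pair. Output is bit-reproducible for a fixed
#' configuration (including the seed).
#'
#' @param config `sim_config` object.
#' @return list with `genes` (gene table), `hits` (domain-hit table) and
#'   `ground_truth` (list: `planted_qss` data frame mapping luxI protein
#'   ids to template ids and flags, `planted_traits` per plasmid with
#'   the intended category).
#' @export
simulate_replicons <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_replicons_impl(config))
}

simulate_replicons_impl <- function(config) {
  tpls <- context_templates()[config$templates]
  chrom_tpls <- tpls[vapply(tpls, function(t) t$replicon == "chromosome", TRUE)]
  plasm_tpls <- tpls[vapply(tpls, function(t) t$replicon == "plasmid", TRUE)]
  window_sep <- 32L   # planted blocks stay a detection window apart
  noise_counter <- 0L
  genes <- list(); hits <- list(); planted <- list(); traits <- list()

  noise_gene <- function() {
    noise_counter <<- noise_counter + 1L
    gene_spec(sprintf("NOI%05d", noise_counter),
              sample(c("+", "-"), 1), sample(120:500, 1))
  }
  template_block <- function(t) {
    slots <- t$slots[order(t$slots$offset), , drop = FALSE]
    n <- nrow(slots)
    lens <- integer(n)
    for (i in seq_len(n)) {
      k <- length(split_signature(slots$signature[i]))
      lens[i] <- if (slots$role[i] == "luxI") 200L
                 else if (k == 0) sample(80:200, 1)
                 else 120L * k + sample(30:80, 1)
    }
    gene_spec(slots$signature, slots$strand, lens, role = slots$role,
              template = t$template_id)
  }

  # decide degraded / transposase systems over all planted loci up front
  n_loci <- config$n_strains * length(tpls)
  pick <- function(frac) {
    n <- round(frac * n_loci)
    if (n <= 0) integer(0) else sort(sample.int(n_loci, n))
  }
  degraded_ids <- pick(config$degraded_fraction)
  transposase_ids <- pick(config$transposase_fraction)
  locus_no <- 0L

  build_replicon <- function(strain, rid, rep_type, blocks) {
    base <- do.call(rbind, replicate(config$n_noise_genes, noise_gene(),
                                     simplify = FALSE))
    if (is.null(base)) base <- gene_spec(character(0), character(0), integer(0))
    # insertion points at least window_sep noise genes apart, and at
    # least a window from the replicon start (where repABC sits)
    margin <- if (rep_type == "plasmid") 16L else 0L
    lo <- margin
    hi <- config$n_noise_genes
    need <- lo + (length(blocks) - 1L) * window_sep
    if (length(blocks) && hi < need)
      stopf("simulate_replicons: templates do not fit on %s; increase n_noise_genes",
            rid)
    pos <- if (length(blocks))
      sort(resample(seq(lo, hi - (length(blocks) - 1L) * window_sep),
                    length(blocks))) +
        (seq_along(blocks) - 1L) * window_sep
    else integer(0)
    spec <- base
    shift <- 0L
    for (b in seq_along(blocks)) {
      blk <- blocks[[b]]
      locus_no <<- locus_no + 1L
      this <- locus_no
      if (this %in% degraded_ids) {
        mode <- config$degraded_mode
        if (mode == "mixed")
          mode <- if (this %% 2L == 0L) "short_luxI" else "luxR_missing"
        if (mode == "short_luxI") {
          blk$length_aa[blk$role == "luxI"] <- resample(42:162, 1)
        } else {
          blk <- blk[blk$role != "luxR", , drop = FALSE]
        }
        blk$degraded <- mode
      }
      if (this %in% transposase_ids) {
        tn <- function() gene_spec("HTH_Tnp_1", resample(c("+", "-"), 1),
                                   resample(100:300, 1), role = "transposase")
        pair <- range(which(blk$role %in% c("luxI", "luxR")))
        blk <- rbind(blk[seq_len(pair[1] - 1L), , drop = FALSE], tn(),
                     blk[pair[1]:pair[2], , drop = FALSE], tn(),
                     blk[seq_len(nrow(blk)) > pair[2], , drop = FALSE])
        blk$has_tnp <- TRUE
      }
      spec <- insert_block(spec, blk, pos[b] + shift)
      shift <- shift + nrow(blk)
    }
    spec
  }

  emit_replicon <- function(strain, rid, rep_type, spec) {
    n <- nrow(spec)
    if (!n) return()
    gaps <- sample(20:200, n, replace = TRUE)
    width <- spec$length_aa * 3L + 3L
    start <- cumsum(c(1L, (width + gaps)[-n]))
    pid <- sprintf("%s_p%04d", rid, seq_len(n))
    genes[[rid]] <<- data.frame(
      replicon_id = rid, strain_id = strain, rep_type = rep_type,
      index = seq_len(n) - 1L, locus_tag = sprintf("%s_g%04d", rid, seq_len(n)),
      strand = spec$strand, start = start, end = start + width - 1L,
      protein_id = pid, length_aa = spec$length_aa, pseudo = spec$pseudo,
      stringsAsFactors = FALSE)
    # domain hits per gene
    for (i in seq_len(n)) {
      doms <- split_signature(spec$signature[i])
      if (!length(doms)) next
      L <- spec$length_aa[i]; k <- length(doms)
      seg <- floor(L / k)
      from <- pmax(1L, (seq_len(k) - 1L) * seg + 3L)
      to <- pmin(L, seq_len(k) * seg - 2L)
      to <- pmax(to, from)
      ev <- 10^stats::runif(k, -30, -4)
      h <- data.frame(protein_id = pid[i], pfam_acc = pfam_acc_of(doms),
                      pfam_name = doms, env_from = from, env_to = to,
                      e_value = ev, stringsAsFactors = FALSE)
      if (stats::runif(1) < config$spurious_hit_fraction) {
        # overlaps the first true hit but covers strictly less and has a
        # much worse E-value, so overlap resolution is decidable
        sp_from <- min(from[1] + 2L, to[1]); sp_to <- to[1]
        h <- rbind(h, data.frame(protein_id = pid[i],
                                 pfam_acc = pfam_acc_of("SPURIOUS"),
                                 pfam_name = sprintf("SPUR%05d", i),
                                 env_from = sp_from, env_to = sp_to,
                                 e_value = ev[1] * 10^stats::runif(1, 1, 4),
                                 stringsAsFactors = FALSE))
      }
      hits[[length(hits) + 1L]] <<- h
    }
    # ground truth rows for planted loci
    for (tid in unique(stats::na.omit(spec$template))) {
      rows <- which(spec$template == tid)
      luxI_row <- rows[spec$role[rows] == "luxI"]
      planted[[length(planted) + 1L]] <<- data.frame(
        strain_id = strain, replicon_id = rid, rep_type = rep_type,
        template_id = tid, luxI_protein = pid[luxI_row],
        luxI_index = luxI_row - 1L,
        degraded = spec$degraded[luxI_row],
        transposase = isTRUE(spec$has_tnp[luxI_row]),
        stringsAsFactors = FALSE)
    }
  }

  for (s in seq_len(config$n_strains)) {
    strain <- sprintf("S%02d", s)
    # chromosome
    rid <- paste0(strain, "C")
    blocks <- lapply(chrom_tpls, template_block)
    spec <- build_replicon(strain, rid, "chromosome", unname(blocks))
    emit_replicon(strain, rid, "chromosome", spec)
    # plasmids: one per plasmid-borne template, plus extra cryptic ones
    n_extra <- resample(seq(config$plasmids_per_strain[1],
                            config$plasmids_per_strain[2]), 1)
    n_plasmids <- max(length(plasm_tpls), n_extra)
    for (k in seq_len(n_plasmids)) {
      rid <- sprintf("%sP%d", strain, k)
      repabc <- gene_spec(c("RepA", "RepB", "RepC"), "+",
                          c(400L, 350L, 440L), role = "repABC")
      blocks <- if (k <= length(plasm_tpls))
        list(template_block(plasm_tpls[[k]])) else list()
      spec <- build_replicon(strain, rid, "plasmid", blocks)
      spec <- insert_block(spec, repabc, 0L)
      emit_replicon(strain, rid, "plasmid", spec)
    }
  }

  gene_tab <- do.call(rbind, c(unname(genes), list(make.row.names = FALSE)))
  hit_tab <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  hit_tab <- domain_hits(hit_tab$protein_id, hit_tab$pfam_acc,
                         hit_tab$pfam_name, hit_tab$env_from, hit_tab$env_to,
                         hit_tab$e_value)
  planted_tab <- if (length(planted))
    do.call(rbind, c(planted, list(make.row.names = FALSE)))
  else data.frame(strain_id = character(0), replicon_id = character(0),
                  rep_type = character(0), template_id = character(0),
                  luxI_protein = character(0), luxI_index = integer(0),
                  degraded = character(0), transposase = logical(0),
                  stringsAsFactors = FALSE)

  # intended plasmid traits and category (generator's own decision table)
  plasmids <- unique(gene_tab$replicon_id[gene_tab$rep_type == "plasmid"])
  traits <- do.call(rbind, lapply(plasmids, function(rid) {
    tid <- planted_tab$template_id[planted_tab$replicon_id == rid]
    qs <- length(tid) > 0L
    conj <- "AI" %in% tid
    sym <- "E" %in% tid
    cat <- if (qs && conj && sym) "D" else if (qs && conj) "B"
           else if (qs && sym) "C" else if (qs) "A" else if (sym) "E"
           else if (conj) "F" else "H"
    data.frame(replicon_id = rid, has_qss = qs, has_conjugation = conj,
               has_nif = sym, has_nod = sym, has_rctA = FALSE,
               has_repABC = TRUE, category = cat, stringsAsFactors = FALSE)
  }))

  list(genes = gene_tab, hits = hit_tab,
       ground_truth = list(planted_qss = planted_tab, planted_traits = traits))
}

#' Simulate a block-structured pairwise ANI table
#'
#' Within each planted group every pair is at the specified identity and
#' coverage; between groups (and for the designated orphans) identity is
#' drawn below 90 percent. Identity is symmetric; coverage is emitted
#' per direction.
#'
#' @param config `sim_config` (uses `ani_group_spec`, `n_ani_orphans`,
#'   `seed`).
#' @return list: `ani` (data frame `query_id`, `subject_id`,
#'   `identity_pct`, `qcov`, `scov`; both directions emitted),
#'   `groups` (named ground-truth group label per replicon; orphans
#'   labelled `"orphan"`).
#' @export
simulate_ani_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$ani_group_spec
  if (is.null(spec) || nrow(spec) == 0) stopf("simulate_ani_table: empty group spec")
  with_seed(config$seed, {
    n <- sum(spec$size) + config$n_ani_orphans
    ids <- sprintf("R%03d", seq_len(n))
    grp <- c(rep(seq_len(nrow(spec)), spec$size),
             rep(NA_integer_, config$n_ani_orphans))
    rows <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
      same <- !is.na(grp[i]) && !is.na(grp[j]) && grp[i] == grp[j]
      if (same) {
        idy <- spec$identity[grp[i]]
        qc <- spec$coverage[grp[i]]; sc <- spec$coverage[grp[i]]
      } else {
        idy <- stats::runif(1, 75, 89.5)
        qc <- stats::runif(1, 0.2, 1); sc <- stats::runif(1, 0.2, 1)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = c(ids[i], ids[j]), subject_id = c(ids[j], ids[i]),
        identity_pct = idy, qcov = c(qc, sc), scov = c(sc, qc),
        stringsAsFactors = FALSE)
    }
    ani <- if (length(rows))
      do.call(rbind, c(rows, list(make.row.names = FALSE)))
    else data.frame(query_id = character(0), subject_id = character(0),
                    identity_pct = numeric(0), qcov = numeric(0),
                    scov = numeric(0))
    truth <- stats::setNames(ifelse(is.na(grp), "orphan",
                                    as.character(grp)), ids)
    list(ani = ani, groups = truth)
  })
}

#' Simulate a codiverging tree pair with planted host switches
#'
#' The first tree is a random bifurcating topology (sequential random
#' coalescence) with exponential branch lengths (mean `branch_rate`).
#' The partner tree is a copy whose branch lengths receive multiplicative
#' log-normal noise and in which `n_switch_events` disjoint leaf pairs
#' have their labels swapped -- a cheap host-switch model with
#' unambiguous ground truth.
#'
#' @param n_tips number of tips (>= 4).
#' @param n_switch_events leaf-pair swaps (0 to `n_tips / 2`).
#' @param branch_rate mean branch length (default 0.1).
#' @param branch_noise_sd log-normal sdlog for partner-tree branch noise
#'   (0 disables noise; default 0.25).
#' @param seed RNG seed.
#' @return list: `tree_H`, `tree_P` (`phylo`), `switched_tips`
#'   (character).
#' @export
simulate_cophylogeny <- function(n_tips, n_switch_events = 0,
                                 branch_rate = 0.1, branch_noise_sd = 0.25,
                                 seed = 1) {
  if (n_tips < 4) stopf("simulate_cophylogeny: need at least 4 tips")
  if (n_switch_events < 0 || n_switch_events > n_tips / 2)
    stopf("simulate_cophylogeny: n_switch_events must be in [0, n_tips/2]")
  with_seed(seed, {
    labels <- sprintf("t%03d", seq_len(n_tips))
    tree_H <- ape::rcoal(n_tips, tip.label = labels)
    tree_H$edge.length <- stats::rexp(nrow(tree_H$edge), rate = 1 / branch_rate)
    tree_P <- tree_H
    if (branch_noise_sd > 0)
      tree_P$edge.length <- tree_P$edge.length *
        stats::rlnorm(length(tree_P$edge.length), 0, branch_noise_sd)
    switched <- character(0)
    if (n_switch_events > 0) {
      chosen <- sample(labels, 2L * n_switch_events)
      a <- chosen[seq_len(n_switch_events)]
      b <- chosen[n_switch_events + seq_len(n_switch_events)]
      lab <- tree_P$tip.label
      ia <- match(a, lab); ib <- match(b, lab)
      lab[ia] <- b; lab[ib] <- a
      tree_P$tip.label <- lab
      switched <- sort(chosen)
    }
    list(tree_H = tree_H, tree_P = tree_P, switched_tips = switched)
  })
}

#' Write a full simulation to disk
#'
#' Emits the gene table (TSV and, when rtracklayer is installed, GFF3
#' with CDS features carrying `protein_id` and `pseudo` attributes),
#' domain hits (TSV, hmmscan-like columns), ANI table (TSV), tree pair
#' (Newick) and ground truth (JSON) into `dir`.
#'
#' @param config `sim_config` object.
#' @param dir output directory.
#' @return invisibly, the list of generated objects.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_replicons(config)
  write_tsv(sim$genes, file.path(dir, "genes.tsv"))
  h <- as.data.frame(sim$hits)
  names(h)[names(h) == "e_value"] <- "i_evalue"
  write_tsv(h, file.path(dir, "domain_hits.tsv"))
  if (requireNamespace("rtracklayer", quietly = TRUE))
    write_gff3(sim$genes, file.path(dir, "genes.gff3"))
  ani <- simulate_ani_table(config)
  write_tsv(ani$ani, file.path(dir, "ani.tsv"))
  trees <- simulate_cophylogeny(config$tree_n_tips, config$n_switch_events,
                                config$branch_rate, config$branch_noise_sd,
                                seed = config$seed)
  ape::write.tree(trees$tree_H, file.path(dir, "tree_luxI.nwk"))
  ape::write.tree(trees$tree_P, file.path(dir, "tree_luxR.nwk"))
  jsonlite::write_json(
    list(planted_qss = sim$ground_truth$planted_qss,
         planted_traits = sim$ground_truth$planted_traits,
         ani_groups = as.list(ani$groups),
         switched_tips = trees$switched_tips),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(sim = sim, ani = ani, trees = trees))
}

#' Write a gene table as GFF3
#'
#' CDS features; attributes carry `protein_id` and `pseudo`. Requires
#' rtracklayer.
#'
#' @param genes gene table.
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("write_gff3 requires the rtracklayer package")
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon_id,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "qsce_sim", type = "CDS", phase = 0L,
    ID = genes$locus_tag, protein_id = genes$protein_id,
    pseudo = ifelse(genes$pseudo, "true", "false"),
    locus_tag = genes$locus_tag)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 gene table
#'
#' Imports CDS features and reconstructs the gene-rank coordinate system
#' (genes ordered by start within each replicon). Requires rtracklayer.
#'
#' @param path GFF3 path.
#' @param strain_id,rep_type optional vectors (named by replicon id)
#'   restoring metadata GFF3 does not carry.
#' @return gene table data frame.
#' @export
read_gff3_genes <- function(path, strain_id = NULL, rep_type = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("read_gff3_genes requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  d <- data.frame(replicon_id = as.character(GenomicRanges::seqnames(gr)),
                  locus_tag = gr$locus_tag,
                  strand = as.character(GenomicRanges::strand(gr)),
                  start = GenomicRanges::start(gr),
                  end = GenomicRanges::end(gr),
                  protein_id = gr$protein_id,
                  pseudo = !is.na(gr$pseudo) & gr$pseudo == "true",
                  stringsAsFactors = FALSE)
  d <- d[order(d$replicon_id, d$start), ]
  d$index <- stats::ave(seq_len(nrow(d)), d$replicon_id,
                        FUN = function(x) seq_along(x) - 1L)
  d$length_aa <- (d$end - d$start + 1L - 3L) %/% 3L
  if (!is.null(strain_id)) d$strain_id <- strain_id[d$replicon_id]
  if (!is.null(rep_type)) d$rep_type <- rep_type[d$replicon_id]
  rownames(d) <- NULL
  d
}
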