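test_that("sim_config validates its invariants", {
  expect_error(sim_config(degraded_fraction = 1.5), "proportions")
  expect_error(sim_config(n_strains = 0), "counts")
  expect_error(sim_config(templates = "ZZ"), "unknown template")
  expect_error(sim_config(branch_rate = 0), "branch_rate")
  expect_error(sim_config(ani_group_spec = data.frame(size = 2, identity = 101,
                                                      coverage = 0.9)),
               "identity")
})

test_that("shipped templates carry the promised structure", {
  tpls <- context_templates()
  expect_setequal(names(tpls), c("A", "E", "AA", "AI"))
  for (t in tpls) {
    has_synth <- grepl("Autoind_synth", t$slots$signature)
    expect_equal(sum(has_synth), 1)                 # exactly one synthase slot
    luxr <- grepl("Autoind_bind", t$slots$signature)
    expect_lte(sum(luxr), 1)                        # at most one receptor slot
  }
  expect_true(any(grepl("DUF4174", tpls$A$slots$signature)))
  expect_true(any(grepl("Phage_tail_collar", tpls$E$slots$signature)))
  expect_true(any(grepl("AsnC", tpls$AA$slots$signature)))
  expect_true(any(grepl("TraG_N", tpls$AI$slots$signature)))
})

test_that("simulation is deterministic under a fixed config", {
  cfg <- sim_config(n_strains = 3, seed = 77)
  a <- simulate_replicons(cfg)
  b <- simulate_replicons(cfg)
  expect_identical(a, b)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(cfg, d1); write_simulation(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("planted loci land within a detection window of their template", {
  cfg <- sim_config(n_strains = 3, seed = 12)
  sim <- simulate_replicons(cfg)
  gt <- sim$ground_truth$planted_qss
  tpls <- context_templates()
  for (i in seq_len(nrow(gt))) {
    rep <- sim$genes[sim$genes$replicon_id == gt$replicon_id[i], ]
    tpl <- tpls[[gt$template_id[i]]]
    win <- rep[abs(rep$index - gt$luxI_index[i]) <= 15, ]
    # every template slot's architecture is present in the window
    hits <- sim$hits[sim$hits$protein_id %in% win$protein_id, ]
    for (s in setdiff(tpl$slots$signature, "")) {
      for (dom in strsplit(s, "|", fixed = TRUE)[[1]]) {
        expect_true(dom %in% hits$pfam_name,
                    label = sprintf("%s in window of %s", dom, gt$replicon_id[i]))
      }
    }
  }
})

test_that("noise architectures stay disjoint from template vocabularies", {
  cfg <- sim_config(n_strains = 2, seed = 14)
  sim <- simulate_replicons(cfg)
  tpl_doms <- unique(unlist(strsplit(
    unlist(lapply(context_templates(), function(t) t$slots$signature)),
    "|", fixed = TRUE)))
  noise_names <- grep("^NOI", sim$hits$pfam_name, value = TRUE)
  expect_gt(length(noise_names), 0)
  expect_length(intersect(noise_names, tpl_doms), 0)
})

test_that("degraded modes shorten LuxI into 42-162 aa or drop LuxR", {
  cfg <- sim_config(n_strains = 4, degraded_fraction = 1,
                    degraded_mode = "short_luxI", seed = 15)
  sim <- simulate_replicons(cfg)
  gt <- sim$ground_truth$planted_qss
  lens <- sim$genes$length_aa[match(gt$luxI_protein, sim$genes$protein_id)]
  expect_true(all(lens >= 42 & lens <= 162))

  cfg <- sim_config(n_strains = 4, degraded_fraction = 1,
                    degraded_mode = "luxR_missing", seed = 15)
  sim <- simulate_replicons(cfg)
  plen <- setNames(sim$genes$length_aa, sim$genes$protein_id)
  arch <- resolve_architectures(sim$hits, plen)
  inv <- detect_qss(sim$genes, arch)
  expect_true(all(!inv$canonical))
  expect_true(all(grepl("luxR_missing", inv$degraded_flags)))
})

test_that("transposase planting is recovered by the context flags", {
  cfg <- sim_config(n_strains = 3, transposase_fraction = 1, seed = 16)
  sim <- simulate_replicons(cfg)
  plen <- setNames(sim$genes$length_aa, sim$genes$protein_id)
  arch <- resolve_architectures(sim$hits, plen)
  inv <- detect_qss(sim$genes, arch)
  expect_true(all(grepl("PF01527:flanked_both_sides", inv$transposase_flags)))
})

test_that("ANI table is symmetric with block structure", {
  cfg <- sim_config(seed = 18)
  ani <- simulate_ani_table(cfg)$ani
  key <- paste(ani$query_id, ani$subject_id)
  rev <- paste(ani$subject_id, ani$query_id)
  m <- match(rev, key)
  expect_false(anyNA(m))
  expect_equal(ani$identity_pct, ani$identity_pct[m])
  expect_equal(ani$qcov, ani$scov[m])
  # single replicon: no pairs
  cfg1 <- sim_config(seed = 1, n_ani_orphans = 0,
                     ani_group_spec = data.frame(size = 1, identity = 97,
                                                 coverage = 0.9))
  expect_equal(nrow(simulate_ani_table(cfg1)$ani), 0)
})

test_that("designated ANI orphans have no partner above thresholds", {
  cfg <- sim_config(seed = 19, n_ani_orphans = 2,
                    ani_group_spec = data.frame(size = 3, identity = 97,
                                                coverage = 0.9))
  out <- simulate_ani_table(cfg)
  orphans <- names(out$groups)[out$groups == "orphan"]
  for (o in orphans) {
    rows <- out$ani[out$ani$query_id == o, ]
    expect_true(all(rows$identity_pct < 95))
  }
})

test_that("tree pair simulation honours its contracts", {
  expect_error(simulate_cophylogeny(3), "at least 4")
  expect_error(simulate_cophylogeny(16, 9), "n_switch_events")
  # no switches, no noise: identical trees
  tr <- simulate_cophylogeny(16, 0, branch_noise_sd = 0, seed = 1)
  expect_equal(phangorn::RF.dist(tr$tree_H, tr$tree_P), 0)
  expect_equal(patristic_matrix(tr$tree_H), patristic_matrix(tr$tree_P))
  # 3 swaps move exactly 6 tips
  tr2 <- simulate_cophylogeny(16, 3, seed = 42)
  expect_length(tr2$switched_tips, 6)
  expect_setequal(tr2$tree_H$tip.label, tr2$tree_P$tip.label)
  # determinism
  tr3 <- simulate_cophylogeny(16, 3, seed = 42)
  expect_identical(tr2, tr3)
})

test_that("gene tables round-trip through GFF3", {
  cfg <- sim_config(n_strains = 1, seed = 23)
  sim <- simulate_replicons(cfg)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$genes, f)
  back <- read_gff3_genes(f)
  ord <- match(paste(sim$genes$replicon_id, sim$genes$locus_tag),
               paste(back$replicon_id, back$locus_tag))
  expect_false(anyNA(ord))
  back <- back[ord, ]
  expect_equal(back$start, sim$genes$start)
  expect_equal(back$end, sim$genes$end)
  expect_equal(back$strand, sim$genes$strand)
  expect_equal(back$index, sim$genes$index)
  expect_equal(back$protein_id, sim$genes$protein_id)
})
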