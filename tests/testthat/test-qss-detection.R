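luxI_sig <- "Autoind_synth"
luxR_sig <- "Autoind_bind|GerE"

test_that("luxI candidates require Autoind_synth, fusions included", {
  r <- make_replicon(c("DUF1", luxI_sig, "Autoind_synth|WGR", "GerE", "DUF2"))
  cand <- find_luxI_candidates(r$genes, r$arch)
  expect_equal(cand$index, c(1L, 2L))
  r2 <- make_replicon(c("DUF1", "GerE", "DUF2"))
  expect_equal(nrow(find_luxI_candidates(r2$genes, r2$arch)), 0)
})

test_that("luxR partner needs both domains in N->C order", {
  r <- make_replicon(c(luxI_sig, "GerE", "DUF1"))       # solo-HTH: no partner
  luxI <- r$genes[1, ]
  expect_null(find_luxR_partner(r$genes, luxI, r$arch))
  r2 <- make_replicon(c(luxI_sig, "GerE|Autoind_bind")) # wrong domain order
  expect_null(find_luxR_partner(r2$genes, r2$genes[1, ], r2$arch))
  r3 <- make_replicon(c(luxI_sig, luxR_sig))
  p <- find_luxR_partner(r3$genes, r3$genes[1, ], r3$arch)
  expect_equal(p$index, 1L)
})

test_that("nearest partner wins; the farther one is recorded as secondary", {
  sig <- c(luxI_sig, "DUF1", luxR_sig, rep("DUF2", 6), luxR_sig)
  r <- make_replicon(sig)
  p <- find_luxR_partner(r$genes, r$genes[1, ], r$arch)
  expect_equal(p$index, 2L)
  sec <- attr(p, "secondary")
  expect_equal(sec$index, 9L)
})

test_that("the search window clips at replicon ends and bounds the scan", {
  sig <- c(luxI_sig, rep("DUF", 16), luxR_sig)   # partner at distance 17
  r <- make_replicon(sig)
  expect_null(find_luxR_partner(r$genes, r$genes[1, ], r$arch, window = 15))
  expect_false(is.null(find_luxR_partner(r$genes, r$genes[1, ], r$arch,
                                         window = 17)))
})

test_that("pair configurations follow strand geometry", {
  r <- make_replicon(c(luxI_sig, luxR_sig), strands = c("+", "+"))
  cf <- classify_configuration(r$genes[1, ], r$genes[2, ])
  expect_equal(cf$configuration, "tandem")
  expect_equal(cf$k, 0L)

  # divergent: 5' ends facing
  r <- make_replicon(c(luxR_sig, luxI_sig), strands = c("-", "+"))
  cf <- classify_configuration(r$genes[2, ], r$genes[1, ])
  expect_equal(cf$base_configuration, "head_to_head")

  # convergent: 3' ends facing
  r <- make_replicon(c(luxI_sig, luxR_sig), strands = c("+", "-"))
  cf <- classify_configuration(r$genes[1, ], r$genes[2, ])
  expect_equal(cf$base_configuration, "tail_to_tail")

  # separation annotated in gene ranks
  r <- make_replicon(c(luxI_sig, "A", "B", "C", luxR_sig))
  cf <- classify_configuration(r$genes[1, ], r$genes[5, ])
  expect_equal(cf$configuration, "tandem_separated_by_3")

  r2 <- make_replicon(luxI_sig, replicon_id = "other")
  expect_error(classify_configuration(r$genes[1, ], r2$genes[1, ]),
               "different replicons")
})

test_that("degraded flags cover the observed short-LuxI range", {
  r <- make_replicon(c(luxI_sig, luxR_sig), lengths_aa = c(162L, 250L))
  expect_true("luxI_short" %in%
                flag_degraded(list(luxI = r$genes[1, ], luxR = r$genes[2, ])))
  r <- make_replicon(c(luxI_sig, luxR_sig), lengths_aa = c(42L, 250L))
  expect_true("luxI_short" %in%
                flag_degraded(list(luxI = r$genes[1, ], luxR = r$genes[2, ])))
  r <- make_replicon(c(luxI_sig, luxR_sig), lengths_aa = c(200L, 250L))
  expect_length(flag_degraded(list(luxI = r$genes[1, ], luxR = r$genes[2, ])), 0)
  expect_true("luxR_missing" %in%
                flag_degraded(list(luxI = r$genes[1, ], luxR = NULL)))
  r <- make_replicon(c(luxI_sig, luxR_sig), lengths_aa = c(200L, 250L),
                     pseudo = c(TRUE, FALSE))
  expect_true("luxI_pseudo" %in%
                flag_degraded(list(luxI = r$genes[1, ], luxR = r$genes[2, ])))
})

test_that("transposase context distinguishes flanking from single-adjacent", {
  sig <- c("HTH_Tnp_1", luxI_sig, luxR_sig, "HTH_Tnp_1")
  r <- make_replicon(sig)
  qss <- list(luxI = r$genes[2, ], luxR = r$genes[3, ])
  fl <- flag_transposase_context(r$genes, qss, r$arch)
  expect_equal(fl$placement, "flanked_both_sides")
  expect_equal(fl$family, "PF01527")

  sig <- c(luxI_sig, luxR_sig, "DUF", "DDE_Tnp_IS240")
  r <- make_replicon(sig)
  fl <- flag_transposase_context(r$genes, list(luxI = r$genes[1, ],
                                               luxR = r$genes[2, ]), r$arch)
  expect_equal(fl$placement, "single_adjacent")
  expect_equal(fl$family, "PF13610")

  # the composite IS110 family needs both domains in one protein
  sig <- c("DEDD_Tnp_IS110|Transposase_20", luxI_sig, luxR_sig)
  r <- make_replicon(sig)
  fl <- flag_transposase_context(r$genes, list(luxI = r$genes[2, ],
                                               luxR = r$genes[3, ]), r$arch)
  expect_equal(fl$family, "PF01548|PF02371")

  sig <- c("DEDD_Tnp_IS110", luxI_sig, luxR_sig)
  r <- make_replicon(sig)
  fl <- flag_transposase_context(r$genes, list(luxI = r$genes[2, ],
                                               luxR = r$genes[3, ]), r$arch)
  expect_equal(nrow(fl), 0)
})

test_that("detection recovers every planted system on clean simulations", {
  cfg <- sim_config(seed = 11, degraded_fraction = 0)
  sim <- simulate_replicons(cfg)
  plen <- setNames(sim$genes$length_aa, sim$genes$protein_id)
  arch <- resolve_architectures(sim$hits, plen)
  inv <- detect_qss(sim$genes, arch)
  gt <- sim$ground_truth$planted_qss
  expect_setequal(inv$luxI_protein[inv$canonical], gt$luxI_protein)
  expect_true(all(inv$canonical))
  # per-strain counts match the plant
  got <- table(inv$strain_id[inv$canonical])
  want <- table(gt$strain_id)
  expect_equal(as.vector(got[names(want)]), as.vector(want))
})

test_that("window symmetry: partner search is reciprocal", {
  cfg <- sim_config(n_strains = 3, seed = 5)
  sim <- simulate_replicons(cfg)
  plen <- setNames(sim$genes$length_aa, sim$genes$protein_id)
  arch <- resolve_architectures(sim$hits, plen)
  inv <- detect_qss(sim$genes, arch)
  inv <- inv[inv$canonical, ]
  for (i in seq_len(nrow(inv))) {
    d <- abs(inv$luxI_index[i] - inv$luxR_index[i])
    expect_lte(d, 15)
  }
})

test_that("LuxR solos are inventoried but excluded from pairs", {
  sig <- c(luxR_sig, rep("DUF", 20), luxI_sig, luxR_sig)
  r <- make_replicon(sig)
  inv <- detect_qss(r$genes, r$arch)
  expect_equal(nrow(inv), 1)
  expect_equal(inv$luxR_index, 22L)
  solos <- attr(inv, "solos")
  expect_equal(solos$index, 0L)
})
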