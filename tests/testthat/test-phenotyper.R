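test_that("mutant specifications translate to the documented clamp sets", {
  nm <- minicdc_net()
  net <- nm$net
  # deletion clamps every state of the protein and of its gene and mRNA
  cl <- apply_mutant(net, mutant_spec(deletions = "Cln3"))
  expect_true(all(!cl))
  expect_setequal(names(cl), c("Cln3", "CLN3g", "CLN3m"))
  # alanine-style lock: phospho-state false, unmodified complement true
  cl2 <- apply_mutant(net, mutant_spec(locks = c("Sic1_[t2]-P" = FALSE)))
  expect_identical(cl2[["Sic1_[t2]-P"]], FALSE)
  expect_identical(cl2[["Sic1_[t2]-0"]], TRUE)
  # phosphomimetic: the reverse
  cl3 <- apply_mutant(net, mutant_spec(locks = c("SBF_[r1]-P" = TRUE)))
  expect_identical(cl3[["SBF_[r1]-P"]], TRUE)
  expect_identical(cl3[["SBF_[r1]-0"]], FALSE)
  # overexpression clamps the transcription reaction node on
  cl4 <- apply_mutant(net, mutant_spec(overexpress = "Cln2"))
  expect_identical(cl4, c("CLN2g_trsc" = TRUE))
  # empty spec -> empty clamp set
  expect_length(apply_mutant(net, mutant_spec()), 0L)
  # conflicting deletion + lock, unknown objects
  expect_error(apply_mutant(net, mutant_spec(deletions = "Sic1",
                                             locks = c("Sic1_[t2]-P" = FALSE))),
               "same component")
  expect_error(apply_mutant(net, mutant_spec(deletions = "Nope")), "unknown")
  expect_error(apply_mutant(net, mutant_spec(overexpress = "Cdc28")),
               "no transcription reaction")
})

test_that("the miniCDC behavioural contract holds", {
  nm <- minicdc_net()
  net <- nm$net
  cgm <- nm$fx$cgm
  # (i) no nutrients: point attractor at the quiescent profile
  g0att <- find_attractor(net, default_initial_vector(net),
                          clamps = c("[Nutrients]" = FALSE))
  expect_identical(g0att$kind, "point")
  s <- g0att$states[1, ]
  expect_true(all(s[c("[DNAlicensed]", "[SPBsatellite]", "[BUDnone]")]))
  expect_false(any(s[c("[DNAreplicating]", "[DNAreplicated]",
                       "[DNAsegregated]", "[SPBduplicated]", "[BUDsmall]",
                       "[BUDlarge]", "Cln3", "Cdc28_[cyclin]--Cln2_[cdc28]",
                       "Cdc28_[cyclin]--Clb5_[cdc28]",
                       "Cdc28_[cyclin]--Clb2_[cdc28]")]))
  g0 <- minicdc_g0_state()
  # (ii) nutrients: ordered traversal of all three macro cycles
  wt <- find_attractor(net, g0, clamps = c("[Nutrients]" = TRUE))
  expect_identical(wt$kind, "cycle")
  wt_call <- classify_attractor(wt, cgm)
  expect_identical(wt_call$viability, "viable")
  expect_identical(wt_call$mode, "full-cycle")
  # (iii) pheromone: G1 point arrest
  ph <- find_attractor(net, g0, clamps = c("[Nutrients]" = TRUE,
                                           "[Pheromone]" = TRUE))
  expect_identical(ph$kind, "point")
  ph_call <- classify_attractor(ph, cgm)
  expect_identical(ph_call$stage, "G1")
  expect_true(ph$states[1, "Cln3"])       # only the nutrient sensor remains
  # (iv) replication poison: arrest with replicating DNA (S profile)
  hu <- find_attractor(net, g0, clamps = c("[Nutrients]" = TRUE,
                                           "[HU]" = TRUE))
  expect_identical(hu$kind, "point")
  expect_true(hu$states[1, "[DNAreplicating]"])
  expect_true(hu$states[1, "[SPBduplicated]"])
  hu_call <- classify_attractor(hu, cgm)
  expect_identical(hu_call$stage, "S")
  # (v) deleting the G1 transcription driver arrests in G1
  sbf <- find_attractor(net, g0, clamps = c(
    c("[Nutrients]" = TRUE), apply_mutant(net, mutant_spec(deletions = "SBF"))))
  sbf_call <- classify_attractor(sbf, cgm)
  expect_identical(sbf_call$viability, "lethal")
  expect_identical(sbf_call$stage, "G1")
  # (vi) deleting the CDK-inhibitor analogue is viable
  sic <- find_attractor(net, g0, clamps = c(
    c("[Nutrients]" = TRUE), apply_mutant(net, mutant_spec(deletions = "Sic1"))))
  expect_identical(classify_attractor(sic, cgm)$viability, "viable")
})

test_that("an empty mutant reproduces the wild-type attractor exactly", {
  nm <- minicdc_net()
  g0 <- minicdc_g0_state()
  base <- c("[Nutrients]" = TRUE)
  wt <- find_attractor(nm$net, g0, clamps = base)
  mut <- find_attractor(nm$net, g0,
                        clamps = c(base, apply_mutant(nm$net, mutant_spec())))
  expect_identical(wt$period, mut$period)
  expect_identical(wt$transient, mut$transient)
  expect_identical(wt$states, mut$states)
})

test_that("deleting an uncoupled component leaves the cycle untouched", {
  nm <- minicdc_net()
  g0 <- minicdc_g0_state()
  base <- c("[Nutrients]" = TRUE)
  wt <- find_attractor(nm$net, g0, clamps = base)
  by <- find_attractor(nm$net, g0, clamps = c(
    base, apply_mutant(nm$net, mutant_spec(deletions = "Bys1"))))
  expect_identical(wt$period, by$period)
  keep <- !grepl("Bys", colnames(wt$states), fixed = TRUE)
  expect_identical(wt$states[, keep], by$states[, keep])
})

test_that("attractor classification covers all modes", {
  nm <- minicdc_net()
  g0 <- minicdc_g0_state()
  base <- c("[Nutrients]" = TRUE)
  cgm <- nm$fx$cgm
  # partial cycle: cytokinesis blocked, DNA and nuclear cycles keep running
  chs <- find_attractor(nm$net, g0, clamps = c(
    base, apply_mutant(nm$net, mutant_spec(deletions = "Chs2"))))
  expect_identical(chs$kind, "cycle")
  call <- classify_attractor(chs, cgm)
  expect_identical(call$mode, "partial-cycle-multinucleate")
  expect_identical(call$viability, "lethal")
  expect_identical(call$dna_count, "unbounded")
  # post-nuclear-division arrest carries two nuclei
  cdc14 <- find_attractor(nm$net, g0, clamps = c(
    base, apply_mutant(nm$net, mutant_spec(deletions = "Cdc14"))))
  call14 <- classify_attractor(cdc14, cgm)
  expect_identical(call14$mode, "point-arrest")
  expect_identical(call14$nuclei_count, 2L)
  # G2/M arrest: replicated DNA, single nucleus
  clb2 <- find_attractor(nm$net, g0, clamps = c(
    base, apply_mutant(nm$net, mutant_spec(deletions = "Clb2"))))
  call2 <- classify_attractor(clb2, cgm)
  expect_identical(call2$stage, "G2/M")
  expect_identical(call2$nuclei_count, 1L)
  # budget-exceeded propagates as its own mode
  tiny <- find_attractor(nm$net, g0, clamps = base, max_steps = 3L)
  expect_identical(classify_attractor(tiny, cgm)$mode, "budget-exceeded")
  # unmapped CGM nodes are an error
  bad <- cgm_map(dna = c("[NoSuch]", "[DNAreplicating]", "[DNAreplicated]",
                         "[DNAsegregated]"),
                 spb = cgm$cycles$spb, bud = cgm$cycles$bud,
                 replicated = cgm$replicated, segregated = cgm$segregated,
                 division = cgm$division)
  wt <- find_attractor(nm$net, g0, clamps = base)
  expect_error(classify_attractor(wt, bad), "unmapped CGM node")
})

test_that("the benchmark table runs end to end with correct calls", {
  nm <- minicdc_net()
  rows <- read_mutant_table(system.file("extdata", "minicdc_mutants.tsv",
                                        package = "rxncycle"))
  bm <- benchmark_mutants(nm$net, rows, minicdc_g0_state(), nm$fx$cgm)
  expect_identical(bm$summary$rows, nrow(rows))
  expect_identical(bm$summary$evaluated, nrow(rows))
  expect_identical(bm$summary$correct, nrow(rows))
  expect_identical(bm$summary$correct +
                     sum(!bm$calls$correct), nrow(rows))
  expect_identical(bm$summary$correct_lethal, bm$summary$expected_lethal)
  # predicted stages match the expectations where stated
  staged <- rows$expected_stage != "" & !is.na(rows$expected_stage)
  expect_identical(bm$calls$stage[staged], rows$expected_stage[staged])
  expect_true(length(bm$summary$arrest_profile_census) >= 3L)
})

test_that("benchmark failures are recorded per row, and empty tables give zero counts", {
  nm <- minicdc_net()
  rows <- data.frame(label = c("ok", "broken"),
                     deletions = c("Bys1", "NotAComponent"),
                     locks = "", overexpress = "",
                     expected_viability = c("viable", "viable"),
                     expected_stage = "", stringsAsFactors = FALSE)
  bm <- benchmark_mutants(nm$net, rows, minicdc_g0_state(), nm$fx$cgm)
  expect_identical(bm$summary$evaluated, 1L)
  expect_match(bm$calls$error[2], "unknown")
  empty <- benchmark_mutants(nm$net, rows[0, ], minicdc_g0_state(),
                             nm$fx$cgm)
  expect_identical(empty$summary$rows, 0L)
  expect_identical(empty$summary$correct, 0L)
})
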