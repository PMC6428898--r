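test_that("skeletons follow the reaction-type rules", {
  sys <- rxncon_system(data.frame(
    rtype = "ppi+", a_name = "Cdc28", a_locus = "cyclin",
    b_name = "Cln1", b_locus = "cdc28", stringsAsFactors = FALSE))
  sk <- skeleton_states(sys, "Cdc28_[cyclin]_ppi+_Cln1_[cdc28]")
  expect_identical(sk$produced, "Cdc28_[cyclin]--Cln1_[cdc28]")
  expect_setequal(sk$consumed, c("Cdc28_[cyclin]--0", "Cln1_[cdc28]--0"))
  expect_length(sk$synthesised, 0)
  expect_length(sk$degraded, 0)

  psys <- tiny_phospho_system()
  psk <- skeleton_states(psys, "K_P+_T_[r]")
  expect_identical(psk$produced, "T_[r]-P")
  expect_identical(psk$consumed, "T_[r]-0")
  rsk <- skeleton_states(psys, "PPT_P-_T_[r]")
  expect_identical(rsk$produced, "T_[r]-0")
  expect_identical(rsk$consumed, "T_[r]-P")

  dsys <- tiny_degradation_system()
  dsk <- skeleton_states(dsys, "X_deg")
  # X carries: unbound p, unmodified r, bond, phospho -> 4 states, all degraded
  expect_setequal(dsk$degraded,
                  c("X_[p]--0", "X_[r]-0", "X_[p]--P_[x]", "X_[r]-P"))
  expect_length(dsk$produced, 0)
  expect_length(dsk$consumed, 0)
})

test_that("skeletons are deterministic functions of (rtype, A, B)", {
  sys <- tiny_degradation_system()
  for (rid in sys$reactions$id) {
    expect_identical(skeleton_states(sys, rid), skeleton_states(sys, rid))
  }
  sys2 <- tiny_degradation_system()
  for (rid in sys$reactions$id) {
    expect_identical(skeleton_states(sys, rid), skeleton_states(sys2, rid))
  }
})

test_that("locus kinds are enforced: bonds on domains, modifications on residues", {
  expect_error(rxncon_system(rbind(
    data.frame(rtype = "ppi+", a_name = "A", a_locus = "s", b_name = "B",
               b_locus = "a", stringsAsFactors = FALSE),
    data.frame(rtype = "P+", a_name = "K", a_locus = NA, b_name = "A",
               b_locus = "s", stringsAsFactors = FALSE))),
    "domain and as residue")
  expect_error(rxncon_system(data.frame(
    rtype = "ppi+", a_name = "A", a_locus = NA, b_name = "B", b_locus = "a",
    stringsAsFactors = FALSE)), "domain loci")
  expect_error(rxncon_system(data.frame(
    rtype = "P+", a_name = "K", a_locus = NA, b_name = "T", b_locus = NA,
    stringsAsFactors = FALSE)), "residue")
})

test_that("unknown reaction types and malformed contingencies are rejected with row numbers", {
  expect_error(rxncon_system(data.frame(
    rtype = "frobnicate", a_name = "A", stringsAsFactors = FALSE)),
    "row.*1.*frobnicate")
  expect_error(rxncon_system(
    data.frame(rtype = "syn", a_name = "A", stringsAsFactors = FALSE),
    data.frame(target = "A_syn", modifier = "??", effector = "[X]",
               stringsAsFactors = FALSE)), "modifier")
  expect_error(rxncon_system(
    data.frame(rtype = "syn", a_name = "A", stringsAsFactors = FALSE),
    data.frame(target = "[X]", modifier = "!", effector = "[X]",
               stringsAsFactors = FALSE)), "own effector")
})

test_that("mutual-exclusion groups partition locus-bearing states", {
  sys <- rxncon_system(rbind(
    data.frame(rtype = "ppi+", a_name = "A", a_locus = "d", b_name = "B",
               b_locus = "a", stringsAsFactors = FALSE),
    data.frame(rtype = "ppi+", a_name = "A", a_locus = "d", b_name = "C",
               b_locus = "a", stringsAsFactors = FALSE),
    data.frame(rtype = "P+", a_name = "K", a_locus = NA, b_name = "A",
               b_locus = "r", stringsAsFactors = FALSE),
    data.frame(rtype = "P-", a_name = "PPT", a_locus = NA, b_name = "A",
               b_locus = "r", stringsAsFactors = FALSE)))
  groups <- mutual_exclusion_groups(sys)
  # A_[d]: unbound + two bonds; A_[r]: P + 0; B_[a], C_[a]: unbound + bond
  expect_setequal(groups[["A_[d]"]],
                  c("A_[d]--0", "A_[d]--B_[a]", "A_[d]--C_[a]"))
  expect_setequal(groups[["A_[r]"]], c("A_[r]-0", "A_[r]-P"))
  # groups partition the locus-bearing states
  locus_states <- sys$states$id[!(sys$states$variant %in%
                                    c("presence", "global"))]
  expect_true(all(locus_states %in% unlist(groups)))
  # bonds appear in exactly the two groups of their loci, others in one
  counts <- table(unlist(groups))
  bonds <- sys$states$id[sys$states$variant == "bond"]
  expect_true(all(counts[bonds] == 2))
  expect_true(all(counts[setdiff(locus_states, bonds)] == 1))
  # group count on the fixture equals its locus count
  fx <- minicdc_net()$fx
  expect_length(mutual_exclusion_groups(fx$system), nrow(fx$system$loci))
})

test_that("every non-global contingency effector lies in exactly one group per locus", {
  fx <- minicdc_net()$fx
  groups <- mutual_exclusion_groups(fx$system)
  counts <- table(unlist(groups))
  reg <- fx$system$contingencies
  effs <- reg$effector[reg$modifier %in% c("!", "x", "k+", "k-")]
  effs <- unique(effs[!grepl("^\\[", effs) & !grepl("^<", effs)])
  for (e in effs) {
    p <- parse_state_id(e)
    expected <- if (p$variant == "bond") 2L else 1L
    expect_identical(as.integer(counts[[e]]), expected)
  }
})

test_that("validation flags turnover violations, missing degradation and dangling effectors", {
  # kinase reaction only, no removal, target stable (not degraded)
  rep1 <- validate_system(tiny_phospho_system(with_removal = FALSE))
  expect_identical(rep1$rule, "turnover")
  expect_identical(rep1$level, "warning")
  # the no-turnover flag silences it
  expect_identical(nrow(validate_system(
    tiny_phospho_system(with_removal = FALSE, no_turnover = TRUE))), 0L)
  # with a phosphatase there is nothing to report
  expect_identical(nrow(validate_system(tiny_phospho_system())), 0L)
  # synthesised component without degradation
  rep2 <- validate_system(rxncon_system(data.frame(
    rtype = "syn", a_name = "A", stringsAsFactors = FALSE)))
  expect_identical(rep2$rule, "no-degradation")
  # contingency on a never-produced state
  sys <- rxncon_system(
    rbind(data.frame(rtype = "P+", a_name = "K", a_locus = NA, b_name = "T",
                     b_locus = "r", no_turnover = TRUE,
                     stringsAsFactors = FALSE),
          data.frame(rtype = "ppi-", a_name = "T", a_locus = "d",
                     b_name = "U", b_locus = "t", no_turnover = FALSE,
                     stringsAsFactors = FALSE)),
    data.frame(target = "K_P+_T_[r]", modifier = "!",
               effector = "T_[d]--U_[t]", stringsAsFactors = FALSE))
  rep3 <- validate_system(sys)
  expect_identical(rep3$rule, "dangling-effector")
  expect_identical(rep3$object, "T_[d]--U_[t]")
  # unknown effector ids are errors, not warnings
  sys2 <- rxncon_system(
    data.frame(rtype = "syn", a_name = "A", no_turnover = TRUE,
               stringsAsFactors = FALSE),
    data.frame(target = "A_syn", modifier = "x", effector = "Nope_[x]-P",
               stringsAsFactors = FALSE))
  rep4 <- validate_system(sys2)
  expect_identical(rep4$rule, "undefined-effector")
  expect_identical(rep4$level, "error")
  # the fixture passes with an empty report
  expect_identical(nrow(validate_system(minicdc_net()$fx$system)), 0L)
})

test_that("gate construction enforces arity and acyclicity", {
  rx <- data.frame(rtype = "syn", a_name = "A", stringsAsFactors = FALSE)
  expect_error(rxncon_system(rx, rbind(
    data.frame(target = "<N>", modifier = "NOT", effector = "[X]",
               stringsAsFactors = FALSE),
    data.frame(target = "<N>", modifier = "NOT", effector = "[Y]",
               stringsAsFactors = FALSE))), "exactly one child")
  expect_error(rxncon_system(rx, rbind(
    data.frame(target = "<A>", modifier = "AND", effector = "<B>",
               stringsAsFactors = FALSE),
    data.frame(target = "<B>", modifier = "AND", effector = "<A>",
               stringsAsFactors = FALSE))), "cycle")
})

test_that("component invariants hold: unique names, gene/mRNA links", {
  expect_error(rxncon_system(
    data.frame(rtype = "syn", a_name = "A", stringsAsFactors = FALSE),
    components = data.frame(name = c("A", "A"), kind = "protein",
                            stringsAsFactors = FALSE)),
    "duplicate component names")
  expect_error(rxncon_system(
    data.frame(rtype = "trsc", a_name = "Ag", stringsAsFactors = FALSE),
    components = data.frame(name = "Ag", kind = "gene", protein = NA,
                            stringsAsFactors = FALSE)),
    "protein link")
})

test_that("empty systems are representable", {
  sys <- rxncon_system(NULL)
  expect_identical(nrow(sys$reactions), 0L)
  expect_identical(nrow(sys$contingencies), 0L)
  st <- system_stats(sys)
  expect_identical(st$reactions, 0L)
  expect_identical(st$components, 0L)
})
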