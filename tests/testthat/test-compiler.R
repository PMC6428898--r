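test_that("a single unregulated bond formation compiles to four nodes", {
  net <- compile_network(tiny_bond_system(), delays = "none")
  census <- node_census(net)
  expect_identical(census[["state"]], 3L)     # two neutrals + the bond
  expect_identical(census[["reaction"]], 1L)
  expect_identical(census[["gate"]], 0L)
  expect_identical(census[["global"]], 0L)
  expect_identical(census[["total"]], 4L)
})

test_that("reaction rules conjoin presence, requirements and inhibitions", {
  sys <- rxncon_system(
    rbind(
      data.frame(rtype = "ppi+", a_name = "Cdc28", a_locus = "cyclin",
                 b_name = "Cln1", b_locus = "cdc28", stringsAsFactors = FALSE),
      data.frame(rtype = "P+", a_name = "Cak1", a_locus = NA, b_name = "Cdc28",
                 b_locus = "T169", stringsAsFactors = FALSE),
      data.frame(rtype = "P-", a_name = "PPT", a_locus = NA, b_name = "Cdc28",
                 b_locus = "T169", stringsAsFactors = FALSE)),
    rbind(
      data.frame(target = "Cdc28_[cyclin]_ppi+_Cln1_[cdc28]", modifier = "!",
                 effector = "Cdc28_[T169]-P", stringsAsFactors = FALSE),
      data.frame(target = "Cdc28_[cyclin]_ppi+_Cln1_[cdc28]", modifier = "x",
                 effector = "[Pheromone]", stringsAsFactors = FALSE),
      data.frame(target = "Cdc28_[cyclin]_ppi+_Cln1_[cdc28]", modifier = "k+",
                 effector = "[Nutrients]", stringsAsFactors = FALSE)))
  rule <- reaction_update_rule(sys, "Cdc28_[cyclin]_ppi+_Cln1_[cdc28]")
  expect_identical(rule$op, "and")
  flat <- rxncycle:::expr_to_text(rule)
  # requirement conjoined positively, inhibition negated
  expect_match(flat, "Cdc28_\\[T169\\]-P")
  expect_match(flat, "!\\[Pheromone\\]")
  # k+ carries no executable semantics
  expect_false(grepl("[Nutrients]", flat, fixed = TRUE))
  # presence factor of each component is an OR over its states
  refs <- rxncycle:::expr_refs(rule)
  expect_true(all(c("Cdc28_[cyclin]--0", "Cdc28_[T169]-P",
                    "Cln1_[cdc28]--0") %in% refs))
  # source states are NOT part of the reaction rule (they gate state rules)
  net <- compile_network(sys, delays = "none")
  init <- default_initial_vector(net)
  init[["Cdc28_[cyclin]--0"]] <- FALSE   # source missing, presence retained
  init[["Cdc28_[T169]-P"]] <- TRUE
  nxt <- step_network(net, init)
  expect_true(nxt[["Cdc28_[cyclin]_ppi+_Cln1_[cdc28]"]])  # opportunity on
  nxt2 <- step_network(net, nxt,
                       clamps = c("Cdc28_[cyclin]--0" = FALSE))
  expect_false(nxt2[["Cdc28_[cyclin]--Cln1_[cdc28]"]])    # but no sources
})

test_that("producer/consumer pairs give population, not microstate, semantics", {
  sys <- tiny_phospho_system()
  net <- compile_network(sys, delays = "none")
  # from a state where both the modified and unmodified forms are present
  # and kinase and phosphatase both fire, both forms remain true at the
  # next step: no mutual exclusivity is enforced at runtime
  init <- default_initial_vector(net)
  init[["T_[r]-P"]] <- TRUE
  warm <- step_network(net, init)        # switch the reactions on
  expect_true(warm[["K_P+_T_[r]"]])
  expect_true(warm[["PPT_P-_T_[r]"]])
  nxt <- step_network(net, warm)
  expect_true(nxt[["T_[r]-P"]])
  expect_true(nxt[["T_[r]-0"]])
  att <- find_attractor(net, init)
  expect_identical(att$kind, "point")
  # an unproduced, unconsumed state holds its value (rule reduces to self)
  bsys <- tiny_bond_system()
  rule <- state_update_rule(bsys, "A_[b]--B_[a]")
  txt <- rxncycle:::expr_to_text(rule)
  expect_match(txt, "A_\\[b\\]--B_\\[a\\]")  # self-reference present
})

test_that("degradation clears the target and frees bound partners", {
  sys <- tiny_degradation_system()
  net <- compile_network(sys, delays = "none")
  att <- find_attractor(net, default_initial_vector(net))
  expect_identical(att$kind, "point")
  s <- att$states[1, ]
  # X is constitutively degraded and never resynthesised: all X states off
  expect_false(any(s[c("X_[p]--0", "X_[r]-0", "X_[r]-P", "X_[p]--P_[x]")]))
  # the partner's unbound state is re-produced, not sequestered
  expect_true(s[["P_[x]--0"]])
})

test_that("delay chains add k nodes and fire only after a sustained condition", {
  sys <- delayed_input_system()
  net0 <- compile_network(sys, delays = "none")
  k <- 5L
  net <- insert_delays(net0, c("K_P+_T_[r]" = k))
  expect_identical(nrow(net$nodes), nrow(net0$nodes) + k)
  expect_identical(sum(net$nodes$kind == "delay"), as.integer(k))
  # k = 0 is the identity
  expect_identical(insert_delays(net0, c("K_P+_T_[r]" = 0L))$nodes, net0$nodes)
  # double-delaying and unknown targets are errors
  expect_error(insert_delays(net, c("K_P+_T_[r]" = 2L)), "already delayed")
  expect_error(insert_delays(net0, c(nope = 3L)), "unknown reaction")

  fire_after <- function(n_true, k) {
    netk <- insert_delays(compile_network(sys, delays = "none"),
                          c("K_P+_T_[r]" = k))
    state <- default_initial_vector(netk)
    fired <- logical(0)
    for (t in seq_len(n_true + k + 5L)) {
      clamp <- c("[S]" = t <= n_true)
      state <- step_network(netk, state, clamp)
      fired <- c(fired, state[["K_P+_T_[r]"]])
    }
    fired
  }
  # condition true for k steps only: never fires; k+1 steps: fires once
  # (clamps take effect from step 0, so the k+1-long window closes at
  # step k+1)
  expect_false(any(fire_after(5L, 5L)))
  expect_identical(which(fire_after(6L, 5L)), 6L)
})

test_that("delayed firing equals the sliding-window conjunction of the undelayed condition", {
  sys <- delayed_input_system()
  for (seed in 1:20) {
    k <- 3L
    net0 <- compile_network(sys, delays = "none")
    netk <- insert_delays(compile_network(sys, delays = "none"),
                          c("K_P+_T_[r]" = k))
    sig <- rxncycle:::with_seed(seed, stats::runif(60) < 0.7)
    s0 <- step_network(net0, default_initial_vector(net0))  # warm presence
    sk <- step_network(netk, default_initial_vector(netk))
    u_hist <- logical(0)
    fired <- logical(0)
    for (t in seq_along(sig)) {
      clamp <- c("[S]" = sig[t])
      s0 <- step_network(net0, s0, clamp)
      sk <- step_network(netk, sk, clamp)
      u_hist <- c(u_hist, s0[["K_P+_T_[r]"]])  # undelayed reaction = u
      fired <- c(fired, sk[["K_P+_T_[r]"]])
    }
    # oracle: fires iff the undelayed condition held k+1 consecutive steps
    oracle <- vapply(seq_along(fired), function(t) {
      t > k && all(u_hist[(t - k):t])
    }, logical(1))
    expect_identical(fired, oracle, label = paste("seed", seed))
  }
})

test_that("the default delay rule covers transcription and slow-flagged reactions", {
  fx <- minicdc_net()$fx
  dl <- delay_spec(fx$system)
  cat_of <- rxncycle:::reaction_category(fx$system$reactions$rtype,
                                         fx$system$catalogue)
  expect_setequal(names(dl), fx$system$reactions$id[
    cat_of == "transcription" | fx$system$reactions$slow])
  expect_true(all(dl == 20L))
  expect_length(delay_spec(fx$system, rule = "none"), 0L)
  expect_error(delay_spec(fx$system, rule = c(bogus = 3L)), "unknown reaction")
})

test_that("the default initial vector is the native-form state", {
  net <- minicdc_net()$net
  v <- default_initial_vector(net)
  s <- net$system$states
  expect_true(all(v[s$id[s$neutral]]))
  non_neutral <- s$id[!s$neutral & s$variant != "global"]
  expect_false(any(v[non_neutral]))
  expect_false(any(v[net$nodes$id[net$nodes$kind %in%
                                    c("reaction", "gate", "delay")]]))
  globals <- s$id[s$variant == "global"]
  expect_false(any(v[setdiff(globals, "[Histones]")]))
  expect_true(v[["[Histones]"]])
  v2 <- default_initial_vector(net, overrides = c("[Nutrients]" = TRUE))
  expect_true(v2[["[Nutrients]"]])
  expect_error(default_initial_vector(net, overrides = c(zz = TRUE)),
               "unknown node")
  # empty network -> empty vector
  empty <- compile_network(rxncon_system(NULL), delays = "none")
  expect_length(default_initial_vector(empty), 0L)
})

test_that("compilation is deterministic and obeys the size law", {
  fx <- build_minicdc()
  j1 <- network_json(compile_network(fx$system))
  j2 <- network_json(compile_network(build_minicdc()$system))
  expect_identical(j1, j2)
  for (seed in c(3L, 11L, 42L)) {
    sys <- generate_random_system(generator_config(n_components = 8L,
                                                   seed = seed))
    net <- compile_network(sys, delays = "default", k = 4L)
    census <- node_census(net)
    s <- sys$states
    expect_identical(census[["state"]], sum(s$variant != "global"))
    expect_identical(census[["reaction"]], nrow(sys$reactions))
    expect_identical(census[["gate"]], length(sys$gates))
    expect_identical(census[["global"]], sum(s$variant == "global"))
    expect_identical(census[["delay"]], as.integer(sum(delay_spec(sys, k = 4L))))
    expect_identical(census[["total"]],
                     census[["state"]] + census[["reaction"]] +
                       census[["gate"]] + census[["global"]] +
                       census[["delay"]])
  }
})

test_that("compiling a system with undefined effectors fails loudly", {
  sys <- rxncon_system(
    data.frame(rtype = "syn", a_name = "A", no_turnover = TRUE,
               stringsAsFactors = FALSE),
    data.frame(target = "A_syn", modifier = "!", effector = "Ghost_[x]-P",
               stringsAsFactors = FALSE))
  expect_error(compile_network(sys), "Ghost")
})

test_that("components without synthesis or degradation conserve presence", {
  for (seed in 1:10) {
    sys <- generate_random_system(generator_config(n_components = 6L,
                                                   p_stable = 0.5,
                                                   seed = seed))
    net <- compile_network(sys, delays = "none")
    cat_of <- rxncycle:::reaction_category(sys$reactions$rtype, sys$catalogue)
    synth_or_deg <- unique(sys$reactions$b_name[
      cat_of %in% c("synthesis", "translation", "degradation")])
    conserved <- setdiff(sys$components$name, synth_or_deg)
    if (length(conserved) == 0L) next
    state <- default_initial_vector(net)
    for (t in 1:30) {
      state <- step_network(net, state)
      for (comp in conserved) {
        ids <- rxncycle:::component_state_nodes(sys, comp)
        expect_true(any(state[ids]),
                    label = paste("seed", seed, "comp", comp, "t", t))
      }
    }
  }
})

test_that("bnet export writes one sanitised rule per node", {
  net <- compile_network(tiny_bond_system(), delays = "none")
  path <- withr::local_tempfile(fileext = ".bnet")
  map <- write_bnet(net, path)
  lines <- readLines(path)
  expect_identical(lines[1], "targets, factors")
  expect_length(lines, nrow(net$nodes) + 1L)
  expect_false(any(grepl("\\[|\\]|--", sub(",.*", "", lines[-1]))))
  expect_identical(anyDuplicated(map), 0L)
})
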