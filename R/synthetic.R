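#' @title Synthetic reaction-contingency systems
#' @description A seeded random model generator with guaranteed-producible
#' contingencies, plus the fixed miniature cell-cycle fixture (miniCDC)
#' whose qualitative behaviour mirrors nutrient-dependent arrest, ordered
#' three-cycle progression and chemical arrests, so that every pipeline
#' stage is testable without external data.
#' @name synthetic-models
NULL

rr <- function(rtype, a, al = NA_character_, b = NA_character_,
               bl = NA_character_, slow = FALSE, no_turnover = FALSE) {
  data.frame(rtype = rtype, a_name = a, a_locus = al, b_name = b,
             b_locus = bl, slow = slow, no_turnover = no_turnover,
             stringsAsFactors = FALSE)
}

cc <- function(target, modifier, effector) {
  data.frame(target = target, modifier = modifier, effector = effector,
             stringsAsFactors = FALSE)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generator configuration
#'
#' @param n_components number of protein components.
#' @param p_stable probability that a component is a stable protein
#'   (no synthesis, no degradation).
#' @param p_mod probability that a component carries a regulated
#'   modification site.
#' @param p_bond expected number of binding partners per component.
#' @param contingency_density expected regulatory contingencies per
#'   reaction.
#' @param p_gate probability that a contingency effector is a Boolean gate
#'   over several states rather than a single state.
#' @param max_gate_arity maximal gate fan-in.
#' @param turnover guarantee that every modification is removable or
#'   degradable (mirrors the turnover assumption for curated models).
#' @param seed RNG seed; the seed fully determines the generated system.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_components = 10L, p_stable = 0.2,
                             p_mod = 0.6, p_bond = 0.8,
                             contingency_density = 1.0, p_gate = 0.15,
                             max_gate_arity = 3L, turnover = TRUE,
                             seed = 1L) {
  stopifnot(n_components >= 2L, contingency_density >= 0, p_gate >= 0,
            p_gate <= 1, max_gate_arity >= 2L)
  structure(list(n_components = as.integer(n_components),
                 p_stable = p_stable, p_mod = p_mod, p_bond = p_bond,
                 contingency_density = contingency_density, p_gate = p_gate,
                 max_gate_arity = as.integer(max_gate_arity),
                 turnover = isTRUE(turnover), seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a random, valid reaction-contingency system
#'
#' Builds a synthesis/degradation scaffold first, decorates it with
#' modification and binding reactions, then samples contingencies only
#' among states that are guaranteed producible, so generated systems never
#' contain dangling effectors and always compile. Identical seeds yield
#' identical systems.
#'
#' @param config a [generator_config()].
#' @return a [rxncon_system()].
#' @export
generate_random_system <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n <- config$n_components
    comps <- sprintf("C%02d", seq_len(n))
    stable <- stats::runif(n) < config$p_stable
    reactions <- list()
    conts <- list()
    add_rx <- function(...) reactions[[length(reactions) + 1L]] <<- rr(...)
    add_ct <- function(...) conts[[length(conts) + 1L]] <<- cc(...)

    for (i in seq_len(n)) {
      if (!stable[i]) {
        add_rx("syn", comps[i], b = comps[i])
        add_rx("deg", comps[i], b = comps[i])
      }
    }
    modded <- which(stats::runif(n) < config$p_mod)
    if (config$p_mod > 0 && length(modded) == 0L) {
      modded <- 1L  # a positive modification rate guarantees one site
    }
    for (i in modded) {
      kinase <- comps[sample.int(n, 1L)]
      add_rx("P+", kinase, b = comps[i], bl = "r1")
      removable <- !stable[i]  # degradation clears the modification
      if (config$turnover && !removable) {
        add_rx("P-", comps[sample.int(n, 1L)], b = comps[i], bl = "r1")
      } else if (!config$turnover && stats::runif(1) < 0.5) {
        add_rx("P-", comps[sample.int(n, 1L)], b = comps[i], bl = "r1")
      }
    }
    n_bonds <- stats::rpois(1L, config$p_bond * n / 2)
    for (k in seq_len(n_bonds)) {
      ij <- sample.int(n, 2L)
      add_rx("ppi+", comps[ij[1L]], paste0("d", ij[2L]),
             comps[ij[2L]], paste0("d", ij[1L]))
      if (stats::runif(1) < 0.3) {
        add_rx("ppi-", comps[ij[1L]], paste0("d", ij[2L]),
               comps[ij[2L]], paste0("d", ij[1L]))
      }
    }
    reactions <- do.call(rbind, reactions)
    reactions <- reactions[!duplicated(reaction_id(
      reactions$rtype, reactions$a_name, reactions$a_locus,
      reactions$b_name, reactions$b_locus)), , drop = FALSE]

    base <- rxncon_system(reactions)
    producible <- unique(c(names(base$index$producers),
                           names(base$index$synthesisers)))
    effector_pool <- setdiff(producible,
                             base$states$id[base$states$neutral])
    rx_ids <- base$reactions$id
    n_cont <- stats::rpois(1L, config$contingency_density * length(rx_ids))
    if (length(effector_pool) == 0L && n_cont > 0L) {
      stop("cannot sample contingencies: no producible non-neutral states")
    }
    gate_n <- 0L
    for (k in seq_len(n_cont)) {
      target <- rx_ids[sample.int(length(rx_ids), 1L)]
      modifier <- sample(c("!", "x", "k+", "k-"), 1L,
                         prob = c(0.45, 0.35, 0.1, 0.1))
      if (stats::runif(1) < config$p_gate && length(effector_pool) >= 2L) {
        gate_n <- gate_n + 1L
        gid <- sprintf("<G%02d>", gate_n)
        arity <- sample(2:config$max_gate_arity, 1L)
        kids <- sample(effector_pool, min(arity, length(effector_pool)))
        gtype <- sample(c("AND", "OR"), 1L)
        for (kid in kids) add_ct(gid, gtype, kid)
        add_ct(target, modifier, gid)
      } else {
        eff <- sample(effector_pool, 1L)
        if (eff == target) next
        add_ct(target, modifier, eff)
      }
    }
    contingencies <- if (length(conts) > 0L) do.call(rbind, conts) else NULL
    rxncon_system(reactions, contingencies)
  })
}

#' The miniature cell-division-cycle fixture (miniCDC)
#'
#' A fixed ~15-component reaction-contingency system with three regulatory
#' modules gating the G1/S, G2/M and M/G1 transitions of a coarse-grained
#' layer of three macro cycles (DNA: licensed -> replicating -> replicated
#' -> segregated; SPB: satellite -> duplicated -> separated; BUD: none ->
#' small -> large -> divided), coupled through input/output globals. The
#' wiring is an implementation artefact; the behavioural contract is the
#' test surface:
#' \enumerate{
#'   \item without nutrients the default initial vector settles into a
#'     point attractor with licensed DNA, SPB satellite and no bud (G0);
#'   \item releasing that state with nutrients yields a cyclic attractor
#'     traversing all three macro cycles in order;
#'   \item pheromone arrests at the G1 profile;
#'   \item the replication-poison analogue (HU) arrests with replicating
#'     DNA;
#'   \item deleting the G1 transcription driver (SBF) arrests in G1;
#'   \item deleting the CDK-inhibitor analogue (Sic1) remains viable.
#' }
#'
#' The G1/S module: nutrient-dependent Cln3 phosphorylates/activates SBF,
#' which drives CLN2/CLB5 expression; unphosphorylated Sic1 blocks the
#' START output until Cln2-bound CDK phosphorylates it, triggering its
#' degradation and shutting off its (Cln2-CDK-repressed) expression. The G2/M
#' module: CLB2 expression requires replicated DNA and a large bud; Clb2-
#' bound CDK is the MITOSIS output. The M/G1 module: mitotic CDK releases
#' Cdc14 from Net1, and free Cdc14 with segregated DNA and separated SPB
#' forms the RESET output driving licensing, SPB return and cytokinesis.
#' Commitment transitions additionally require nutrients. Far1 mediates
#' pheromone inhibition of CLN2 expression; a bystander module (Bys1)
#' exercises phenotypic neutrality of unconnected components.
#'
#' @return a list of class `minicdc_fixture` with elements `system` (the
#'   [rxncon_system()]), `cgm` (the [cgm_map()]), `inputs` (the global
#'   input ids), and `contract` (a data.frame describing the behavioural
#'   contract conditions).
#' @export
build_minicdc <- function() {
  components <- data.frame(
    name = c("Cdc28", "Cln3", "SBF", "Cln2", "Clb5", "Clb2", "Sic1",
             "Far1", "Net1", "Cdc14", "Chs2", "Bys1",
             "Fus3", "PPT1", "BysK",
             "CLN3g", "CLN2g", "CLB5g", "CLB2g", "SIC1g",
             "CLN3m", "CLN2m", "CLB5m", "CLB2m", "SIC1m"),
    kind = c(rep("protein", 12), rep("enzymatic-activity", 3),
             rep("gene", 5), rep("mRNA", 5)),
    protein = c(rep(NA, 15),
                "Cln3", "Cln2", "Clb5", "Clb2", "Sic1",
                "Cln3", "Cln2", "Clb5", "Clb2", "Sic1"),
    stringsAsFactors = FALSE)

  expression_rxns <- function(gene, mrna, prot) {
    rbind(rr("trsc", gene), rr("trsl", mrna), rr("deg", mrna, b = mrna),
          rr("deg", prot, b = prot))
  }
  reactions <- rbind(
    # stable scaffolding proteins kept at constant level
    rr("syn", "Cdc28", b = "Cdc28", no_turnover = TRUE),
    rr("syn", "SBF", b = "SBF", no_turnover = TRUE),
    rr("syn", "Far1", b = "Far1", no_turnover = TRUE),
    # G1/S module
    expression_rxns("CLN3g", "CLN3m", "Cln3"),
    rr("P+", "Cln3", b = "SBF", bl = "r1"),
    rr("P-", "PPT1", b = "SBF", bl = "r1"),
    expression_rxns("CLN2g", "CLN2m", "Cln2"),
    expression_rxns("CLB5g", "CLB5m", "Clb5"),
    rr("ppi+", "Cdc28", "cyclin", "Cln2", "cdc28"),
    rr("ppi+", "Cdc28", "cyclin", "Clb5", "cdc28"),
    rr("P+", "Cdc28", b = "Sic1", bl = "t2"),
    expression_rxns("SIC1g", "SIC1m", "Sic1"),
    # pheromone module
    rr("P+", "Fus3", b = "Far1", bl = "s1"),
    rr("P-", "PPT1", b = "Far1", bl = "s1"),
    # G2/M module
    expression_rxns("CLB2g", "CLB2m", "Clb2"),
    rr("ppi+", "Cdc28", "cyclin", "Clb2", "cdc28"),
    # M/G1 module
    rr("ppi+", "Net1", "cdc14", "Cdc14", "net1"),
    rr("ppi-", "Net1", "cdc14", "Cdc14", "net1"),
    # cytokinesis factor (constitutively competent septation machinery)
    rr("syn", "Chs2", b = "Chs2", no_turnover = TRUE),
    rr("P+", "Cdc28", b = "Chs2", bl = "c1"),
    rr("P-", "PPT1", b = "Chs2", bl = "c1"),
    # bystander module (no regulatory coupling to the cycle)
    rr("syn", "Bys1", b = "Bys1", no_turnover = TRUE),
    rr("P+", "BysK", b = "Bys1", bl = "b1"),
    rr("P-", "PPT1", b = "Bys1", bl = "b1"),
    # coarse-grained DNA cycle
    rr("msyn", "[DNAlicensed]", b = "[DNAlicensed]"),
    rr("mt", "[DNAlicensed]", b = "[DNAreplicating]"),
    rr("mt", "[DNAreplicating]", b = "[DNAreplicated]", slow = TRUE),
    rr("mt", "[DNAreplicated]", b = "[DNAsegregated]"),
    rr("mt", "[DNAsegregated]", b = "[DNAlicensed]"),
    # coarse-grained SPB cycle
    rr("msyn", "[SPBsatellite]", b = "[SPBsatellite]"),
    rr("mt", "[SPBsatellite]", b = "[SPBduplicated]"),
    rr("mt", "[SPBduplicated]", b = "[SPBseparated]"),
    rr("mt", "[SPBseparated]", b = "[SPBsatellite]"),
    # coarse-grained bud cycle
    rr("msyn", "[BUDnone]", b = "[BUDnone]"),
    rr("mt", "[BUDnone]", b = "[BUDsmall]"),
    rr("mt", "[BUDsmall]", b = "[BUDlarge]", slow = TRUE),
    rr("mt", "[BUDlarge]", b = "[BUDdivided]"),
    rr("mt", "[BUDdivided]", b = "[BUDnone]")
  )

  bond_cln2 <- "Cdc28_[cyclin]--Cln2_[cdc28]"
  bond_clb5 <- "Cdc28_[cyclin]--Clb5_[cdc28]"
  bond_clb2 <- "Cdc28_[cyclin]--Clb2_[cdc28]"
  sic1_active <- "Sic1_[t2]-0"
  cdc14_free <- "Cdc14_[net1]--0"

  contingencies <- rbind(
    # G1/S regulatory module
    cc("CLN3g_trsc", "!", "[Nutrients]"),
    cc("CLN2g_trsc", "!", "SBF_[r1]-P"),
    cc("CLN2g_trsc", "x", "Far1_[s1]-P"),
    cc("CLB5g_trsc", "!", "SBF_[r1]-P"),
    cc("Cdc28_P+_Sic1_[t2]", "!", bond_cln2),
    cc("Sic1_deg", "!", "Sic1_[t2]-P"),
    cc("SIC1g_trsc", "x", bond_cln2),
    # pheromone signalling
    cc("Fus3_P+_Far1_[s1]", "!", "[Pheromone]"),
    # Pho85-analogue positive influence, non-binding in the Boolean regime
    cc("Cdc28_[cyclin]_ppi+_Cln2_[cdc28]", "k+", "SBF_[r1]-P"),
    # G2/M regulatory module
    cc("<G2M>", "AND", "[DNAreplicated]"),
    cc("<G2M>", "AND", "[BUDlarge]"),
    cc("CLB2g_trsc", "!", "<G2M>"),
    # M/G1 regulatory module
    cc("Net1_[cdc14]_ppi-_Cdc14_[net1]", "!", bond_clb2),
    # input/output layer
    cc("[START]", "!", bond_cln2),
    cc("[START]", "!", bond_clb5),
    cc("[START]", "x", sic1_active),
    cc("[MITOSIS]", "!", bond_clb2),
    cc("[RESET]", "!", cdc14_free),
    cc("[RESET]", "!", "[DNAsegregated]"),
    cc("[RESET]", "!", "[SPBseparated]"),
    # DNA cycle gating (sources as requirements so delays see them)
    cc("[DNAlicensed]_msyn", "x", "[DNAreplicating]"),
    cc("[DNAlicensed]_msyn", "x", "[DNAreplicated]"),
    cc("[DNAlicensed]_msyn", "x", "[DNAsegregated]"),
    cc("[DNAlicensed]_mt_[DNAreplicating]", "!", "[DNAlicensed]"),
    cc("[DNAlicensed]_mt_[DNAreplicating]", "!", "[START]"),
    cc("[DNAlicensed]_mt_[DNAreplicating]", "!", "[Nutrients]"),
    cc("[DNAreplicating]_mt_[DNAreplicated]", "!", "[DNAreplicating]"),
    cc("[DNAreplicating]_mt_[DNAreplicated]", "!", "[Histones]"),
    cc("[DNAreplicating]_mt_[DNAreplicated]", "x", "[HU]"),
    cc("[DNAreplicated]_mt_[DNAsegregated]", "!", "[DNAreplicated]"),
    cc("[DNAreplicated]_mt_[DNAsegregated]", "!", "[MITOSIS]"),
    cc("[DNAsegregated]_mt_[DNAlicensed]", "!", "[DNAsegregated]"),
    cc("[DNAsegregated]_mt_[DNAlicensed]", "!", "[RESET]"),
    # SPB cycle gating
    cc("[SPBsatellite]_msyn", "x", "[SPBduplicated]"),
    cc("[SPBsatellite]_msyn", "x", "[SPBseparated]"),
    cc("[SPBsatellite]_mt_[SPBduplicated]", "!", "[SPBsatellite]"),
    cc("[SPBsatellite]_mt_[SPBduplicated]", "!", "[START]"),
    cc("[SPBsatellite]_mt_[SPBduplicated]", "!", "[Nutrients]"),
    cc("[SPBduplicated]_mt_[SPBseparated]", "!", "[SPBduplicated]"),
    cc("[SPBduplicated]_mt_[SPBseparated]", "!", "[MITOSIS]"),
    cc("[SPBseparated]_mt_[SPBsatellite]", "!", "[SPBseparated]"),
    cc("[SPBseparated]_mt_[SPBsatellite]", "!", "[RESET]"),
    # bud cycle gating
    cc("[BUDnone]_msyn", "x", "[BUDsmall]"),
    cc("[BUDnone]_msyn", "x", "[BUDlarge]"),
    cc("[BUDnone]_msyn", "x", "[BUDdivided]"),
    cc("[BUDnone]_mt_[BUDsmall]", "!", "[BUDnone]"),
    cc("[BUDnone]_mt_[BUDsmall]", "!", "[START]"),
    cc("[BUDnone]_mt_[BUDsmall]", "!", "[Nutrients]"),
    cc("[BUDsmall]_mt_[BUDlarge]", "!", "[BUDsmall]"),
    cc("[BUDlarge]_mt_[BUDdivided]", "!", "[BUDlarge]"),
    cc("[BUDlarge]_mt_[BUDdivided]", "!", "[RESET]"),
    cc("[BUDlarge]_mt_[BUDdivided]", "!", "Chs2_[c1]-0"),
    cc("[BUDdivided]_mt_[BUDnone]", "!", "[BUDdivided]")
  )

  sys <- rxncon_system(reactions, contingencies, components)
  cgm <- cgm_map(
    dna = c("[DNAlicensed]", "[DNAreplicating]", "[DNAreplicated]",
            "[DNAsegregated]"),
    spb = c("[SPBsatellite]", "[SPBduplicated]", "[SPBseparated]"),
    bud = c("[BUDnone]", "[BUDsmall]", "[BUDlarge]", "[BUDdivided]"),
    replicated = "[DNAreplicated]", segregated = "[DNAsegregated]",
    division = "[BUDdivided]")
  contract <- data.frame(
    id = c("g0_arrest", "cycle", "pheromone_arrest", "hu_arrest",
           "driver_deletion", "inhibitor_deletion"),
    condition = c("no nutrients, default vector",
                  "nutrients from G0",
                  "nutrients + pheromone from G0",
                  "nutrients + HU from G0",
                  "nutrients, SBF deleted, from G0",
                  "nutrients, Sic1 deleted, from G0"),
    expectation = c("point attractor: DNA licensed, SPB satellite, no bud",
                    "cyclic attractor, ordered traversal of all three cycles",
                    "point arrest, G1 profile",
                    "point arrest, DNA replicating",
                    "point arrest, G1",
                    "viable full cycle"),
    stringsAsFactors = FALSE)
  structure(list(system = sys, cgm = cgm,
                 inputs = c("[Nutrients]", "[Pheromone]", "[HU]",
                            "[Histones]"),
                 contract = contract,
                 # regression values computed once by simulation, then frozen
                 metadata = list(wild_type_period = 60L,
                                 g0_transient = 29L)),
            class = "minicdc_fixture")
}

#' Compute the miniCDC wild-type G0 state
#'
#' Simulates the compiled fixture from the default initial vector without
#' nutrients to its nutrient-free point attractor (G0) and returns that
#' state, the conventional start point for release and mutant simulations.
#'
#' @param net compiled miniCDC network.
#' @return named logical state vector.
#' @export
minicdc_g0 <- function(net) {
  att <- find_attractor(net, default_initial_vector(net),
                        clamps = c("[Nutrients]" = FALSE), max_steps = 2000L)
  if (att$kind != "point") {
    stop("miniCDC did not reach a nutrient-free point attractor (kind: ",
         att$kind, ")")
  }
  att$states[1L, ]
}

#' A random Boolean network (not derived from a reaction-contingency
#' system)
#'
#' Small arbitrary synchronous networks used to exercise the simulator
#' against brute-force oracles: each node gets a random update expression
#' over up to `max_inputs` regulators.
#'
#' @param n number of nodes (node ids `n01`, `n02`, ...).
#' @param seed RNG seed.
#' @param max_inputs maximal regulators per node.
#' @return a `boolean_network` (without provenance system).
#' @export
random_boolean_network <- function(n, seed = 1L, max_inputs = 3L) {
  with_seed(seed, {
    ids <- sprintf("n%02d", seq_len(n))
    rules <- vector("list", n)
    names(rules) <- ids
    for (i in seq_len(n)) {
      k <- sample.int(min(max_inputs, n), 1L)
      inputs <- sample(ids, k)
      lits <- lapply(inputs, function(x) {
        if (stats::runif(1) < 0.4) e_not(e_ref(x)) else e_ref(x)
      })
      rules[[i]] <- if (length(lits) == 1L) {
        lits[[1L]]
      } else if (stats::runif(1) < 0.5) {
        e_junction("and", lits)
      } else {
        e_junction("or", lits)
      }
    }
    nodes <- data.frame(id = ids, kind = "state", stringsAsFactors = FALSE)
    # a minimal provenance stub so default_initial_vector() can see neutrals
    sysstub <- list(states = data.frame(id = ids, neutral = FALSE,
                                        stringsAsFactors = FALSE))
    structure(list(nodes = nodes, rules = rules,
                   delays = stats::setNames(integer(0), character(0)),
                   system = sysstub),
              class = "boolean_network")
  })
}
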