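# Shared builders and independent oracles for the test suite.

# Brute-force attractor oracle: simulate step by step, storing every state,
# and find the first recurrence by linear scan over the stored matrix.
# Independent of find_attractor's hashing logic.
naive_attractor <- function(net, init, clamps = NULL, max_steps = 20000L) {
  state <- init
  if (!is.null(clamps) && length(clamps) > 0L) state[names(clamps)] <- clamps
  seenm <- matrix(state, nrow = 1L)
  for (t in seq_len(max_steps)) {
    state <- step_network(net, state, clamps)
    hit <- which(apply(seenm, 1L, function(r) all(r == state)))
    if (length(hit) > 0L) {
      first <- unname(hit[1L]) - 1L
      period <- t - first
      block <- seenm[(first + 1L):t, , drop = FALSE]
      colnames(block) <- names(init)
      return(list(period = period, transient = first, states = block))
    }
    seenm <- rbind(seenm, state)
  }
  list(period = NA_integer_, transient = NA_integer_, states = NULL)
}

# canonical sort of an attractor block so phase does not matter
sort_block <- function(states) {
  keys <- apply(states, 1L, function(r) paste(as.integer(r), collapse = ""))
  out <- states[order(keys), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# one unregulated bond-formation reaction between two proteins
tiny_bond_system <- function() {
  rxncon_system(data.frame(rtype = "ppi+", a_name = "A", a_locus = "b",
                           b_name = "B", b_locus = "a",
                           stringsAsFactors = FALSE))
}

# phosphorylation with phosphatase and turnover machinery
tiny_phospho_system <- function(with_removal = TRUE, no_turnover = FALSE) {
  rx <- data.frame(rtype = "P+", a_name = "K", a_locus = NA, b_name = "T",
                   b_locus = "r", no_turnover = no_turnover,
                   stringsAsFactors = FALSE)
  if (with_removal) {
    rx <- rbind(rx, data.frame(rtype = "P-", a_name = "PPT", a_locus = NA,
                               b_name = "T", b_locus = "r",
                               no_turnover = FALSE, stringsAsFactors = FALSE))
  }
  rxncon_system(rx)
}

# a degradable multi-state component: bond to a partner, one residue whose
# modification is cleared by the degradation itself (no phosphatase)
tiny_degradation_system <- function() {
  rxncon_system(rbind(
    data.frame(rtype = "ppi+", a_name = "X", a_locus = "p", b_name = "P",
               b_locus = "x", stringsAsFactors = FALSE),
    data.frame(rtype = "P+", a_name = "K", a_locus = NA, b_name = "X",
               b_locus = "r", stringsAsFactors = FALSE),
    data.frame(rtype = "deg", a_name = "X", a_locus = NA, b_name = "X",
               b_locus = NA, stringsAsFactors = FALSE)))
}

# input-gated reaction for delay-chain tests: K phosphorylates T only
# under the global input [S]
delayed_input_system <- function() {
  rxncon_system(
    rbind(
      data.frame(rtype = "P+", a_name = "K", a_locus = NA, b_name = "T",
                 b_locus = "r", stringsAsFactors = FALSE),
      data.frame(rtype = "P-", a_name = "PPT", a_locus = NA, b_name = "T",
                 b_locus = "r", stringsAsFactors = FALSE)),
    data.frame(target = "K_P+_T_[r]", modifier = "!", effector = "[S]",
               stringsAsFactors = FALSE))
}

minicdc_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- build_minicdc()
      cache <<- list(fx = fx, net = compile_network(fx$system))
    }
    cache
  }
})

minicdc_g0_state <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- minicdc_g0(minicdc_net()$net)
    cache
  }
})
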