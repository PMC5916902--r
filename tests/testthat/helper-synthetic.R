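# Shared fixtures: everything is generated in code at test time.

# A small all-CRAC panel mirroring the default one (one specific RBP, two
# general binders), sized for fast unit tests.
small_crac_panel <- function(n_replicates = 2L, depth = 1e5) {
  list(
    rbp_spec("rbp_a", "CRAC_COUNT", n_replicates = n_replicates,
             depth = depth, affinity_sdlog = 1.3),
    rbp_spec("rbp_b", "CRAC_COUNT", n_replicates = n_replicates,
             depth = depth, affinity_sdlog = 0.5),
    rbp_spec("rbp_c", "CRAC_COUNT", n_replicates = n_replicates,
             depth = depth, affinity_sdlog = 0.5)
  )
}

# Independent naive motif matcher (position-by-position, N wildcard on
# either side, U equivalent to T): the oracle scan_motif is checked against.
naive_motif_starts <- function(sequence, pattern) {
  sc <- strsplit(chartr("U", "T", toupper(sequence)), "")[[1L]]
  pc <- strsplit(chartr("U", "T", toupper(pattern)), "")[[1L]]
  L <- length(pc)
  n <- length(sc)
  if (n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    s <- sc[j:(n - L + j)]
    ok <- ok & (pc[j] == "N" | s == "N" | s == pc[j])
  }
  which(ok)
}

random_sequence <- function(length, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, length, replace = TRUE), collapse = "")
}

# Brute-force enrichment oracle: exhaustive same-sign-side p over all
# possible same-size sets of a small universe.
exhaustive_enrichment_p <- function(scores, set) {
  ids <- names(scores)
  all_sets <- utils::combn(ids, length(set), simplify = FALSE)
  all_es <- vapply(all_sets, function(s) {
    running_sum_enrichment_score(scores, s)
  }, numeric(1))
  obs <- running_sum_enrichment_score(scores, set)
  if (obs >= 0) {
    side <- all_es[all_es >= 0]
    sum(side >= obs) / length(side)
  } else {
    side <- all_es[all_es < 0]
    sum(side <= obs) / length(side)
  }
}
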