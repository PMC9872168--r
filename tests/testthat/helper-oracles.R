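# Independent oracles and random-instance generators used across the
# suite.  These deliberately use naive per-bond / per-character logic so
# they share no code path with the vectorized implementations they check.

random_rna <- function(n, bases = c("A", "C", "G", "U")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Naive digestion oracle: walk every bond, decide cleavage bond by bond,
# split.  Returns fragment sequences in 5'->3' order.
oracle_digest <- function(residues, prot_intervals, enzymes,
                          edge_rule = "edge_permissive") {
  res <- strsplit(residues, "", fixed = TRUE)[[1]]
  n <- length(res)
  prot <- rep(FALSE, n)
  if (!is.null(prot_intervals) && nrow(prot_intervals) > 0L)
    for (k in seq_len(nrow(prot_intervals)))
      for (j in (prot_intervals$start[k] + 1L):prot_intervals$end[k])
        prot[j] <- TRUE
  frags <- character(0)
  cur <- character(0)
  for (i in seq_len(n)) {
    cur <- c(cur, res[i])
    cleave <- FALSE
    if (i < n) {
      for (e in enzymes) {
        edge_ok <- if (edge_rule == "edge_permissive") !prot[i + 1L]
                   else (!prot[i] && !prot[i + 1L])
        if (res[i] %in% e$recognition && edge_ok) cleave <- TRUE
      }
    }
    if (cleave) {
      frags <- c(frags, paste(cur, collapse = ""))
      cur <- character(0)
    }
  }
  c(frags, paste(cur, collapse = ""))
}

# Random disjoint sorted protection intervals on [0, n).
random_intervals <- function(n, max_k = 3L) {
  k <- sample(0:max_k, 1L)
  if (k == 0L || n < 2L)
    return(data.frame(start = integer(), end = integer()))
  starts <- sort(sample(0:(n - 1L), k))
  iv <- data.frame(start = starts,
                   end = pmin(starts + sample(1:25, k, replace = TRUE), n))
  ir <- IRanges::reduce(IRanges::IRanges(iv$start + 1L, iv$end))
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Wrap raw intervals into a protection_map for a target (tests need maps
# that no real probe produces).
manual_pmap <- function(target, intervals, salt_mode = "high_salt") {
  structure(list(target_id = target$id, intervals = intervals,
                 salt_mode = salt_mode,
                 probes = data.frame(probe_id = character(),
                                     n_sites = integer())),
            class = "protection_map")
}

# Independent mass constants: monoisotopic masses of the free nucleoside
# 5'-monophosphates and water, summed from their elemental compositions
# (AMP C10H14N5O7P, CMP C9H14N3O8P, GMP C10H14N5O8P, UMP C9H13N2O9P).
NMP_MONO <- c(A = 347.063084, C = 323.051851, G = 363.057999,
              U = 324.035867)
WATER_MONO <- 18.0105646
HPO3_MONO <- 79.966331

# Chain with 5'-monophosphate / 3'-OH: sum of NMPs minus (n-1) waters.
oracle_chain_mass <- function(sequence, five_prime = "monophosphate",
                              three_prime = "hydroxyl") {
  b <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- sum(NMP_MONO[b]) - (length(b) - 1L) * WATER_MONO
  m <- m + switch(five_prime, monophosphate = 0, hydroxyl = -HPO3_MONO,
                  triphosphate = 2 * HPO3_MONO)
  m + switch(three_prime, hydroxyl = 0, phosphate = HPO3_MONO,
             cyclic_phosphate = HPO3_MONO - WATER_MONO)
}

# Naive full-scan probe binding oracle.
oracle_bindings <- function(target_res, probe_antisense_rna) {
  n <- nchar(target_res); m <- nchar(probe_antisense_rna)
  hits <- integer(0)
  for (s in 0:(n - m))
    if (substr(target_res, s + 1L, s + m) == probe_antisense_rna)
      hits <- c(hits, s)
  hits
}
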