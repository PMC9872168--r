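# Synthetic fixture generator.  Real assay substrates (the 86-nt and
# 2191-nt IVT transcripts and friends) are not bundled; instead, targets
# are generated with exactly the structural features the assay relies
# on, so every scenario is testable from code:
#   * a 5' end complementary to the chosen probe (optional),
#   * a pyrimidine at the probe's 3' boundary, so the protected fragment
#     length equals the probe length under the edge-permissive cleavage
#     convention (the probe-length band readout),
#   * pyrimidine spacing in unprotected regions guaranteeing that every
#     background fragment stays below the gel detection threshold under
#     RNase A alone (and a fortiori under the RNase A + T1 mixture),
#   * an optional poly(A) tail (which, having no cleavage sites, survives
#     digestion as its own detectable band - the 3'-end poly(A) readout),
#   * a capped / uncapped pool split at a chosen molar cap fraction.

#' Specification for a synthetic assay fixture
#'
#' @param target_length Total transcript length in nt (tail included).
#' @param probe_length Probe length in nt.
#' @param five_prime_match Should the probe be complementary to the
#'   target's 5' end (`TRUE`) or a scrambled non-binder (`FALSE`, the
#'   negative-control scenario)?
#' @param cap_fraction Molar fraction of the pool carrying a 5' cap 0;
#'   the remainder carries the primary transcript's 5'-triphosphate.
#' @param max_free_run Maximum run length (nt) without a pyrimidine
#'   allowed in unprotected regions; the default 7 keeps every
#'   background fragment below the default 8-nt detection threshold.
#'   Must be >= 1.
#' @param polyA_tail Length of an appended poly(A) tail (nt), 0 for none.
#' @param seed Integer seed fixing all randomness of the generator.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(target_length, probe_length = 20L,
                         five_prime_match = TRUE, cap_fraction = 0,
                         max_free_run = 7L, polyA_tail = 0L, seed = 1L) {
  target_length <- as.integer(target_length)
  probe_length <- as.integer(probe_length)
  max_free_run <- as.integer(max_free_run)
  polyA_tail <- as.integer(polyA_tail)
  if (max_free_run < 1L)
    stop("max_free_run < 1 is infeasible (every position would need to ",
         "be a cleavage site boundary)")
  if (cap_fraction < 0 || cap_fraction > 1)
    stop("cap_fraction must lie in [0, 1]")
  if (probe_length > target_length - polyA_tail)
    stop("probe_length must fit in the non-tail part of the target")
  if (probe_length < 10L) stop("probe_length must be >= 10")
  structure(list(target_length = target_length, probe_length = probe_length,
                 five_prime_match = isTRUE(five_prime_match),
                 cap_fraction = cap_fraction, max_free_run = max_free_run,
                 polyA_tail = polyA_tail, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic target pool, probe and expected assay summary
#'
#' Deterministic under `spec$seed` (byte-identical reruns).  See the
#' module header for the structural guarantees built into the sequence.
#'
#' @param spec A [fixture_spec()].
#' @param target_id,probe_id Identifiers for the generated records.
#' @return An `rpa_fixture` list: `target` (the uncapped parent
#'   [nucleic_seq()]), `probe` ([probe()]), `pool` (list of
#'   `list(seq, abundance)` ready for [simulate_protection_assay()]),
#'   and `summary` (expected protected-fragment length, cap fraction,
#'   tail length).
#' @export
generate_fixture <- function(spec,
                             target_id = sprintf("syn_%dnt", spec$target_length),
                             probe_id = sprintf("probe_%dnt", spec$probe_length)) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    body_len <- spec$target_length - spec$polyA_tail
    pyr <- c("C", "U")
    all4 <- c("A", "C", "G", "U")
    bases <- character(body_len)
    run <- 0L
    for (i in seq_len(body_len)) {
      b <- if (run >= spec$max_free_run - 1L) sample(pyr, 1L)
           else sample(all4, 1L)
      bases[i] <- b
      run <- if (b %in% pyr) 0L else run + 1L
    }
    if (spec$five_prime_match && !bases[spec$probe_length] %in% pyr)
      bases[spec$probe_length] <- sample(pyr, 1L)
    residues <- paste(c(bases, rep("A", spec$polyA_tail)), collapse = "")
    target <- nucleic_seq(target_id, residues, kind = "RNA",
                          five_prime = "triphosphate")
    pr <- if (spec$five_prime_match) {
      design_five_prime_probe(target, spec$probe_length, id = probe_id)
    } else {
      # scrambled negative control: random DNA with no perfect
      # complementarity anywhere on the target
      for (try in 1:100) {
        cand <- probe(probe_id, paste(sample(c("A", "C", "G", "T"),
                                             spec$probe_length,
                                             replace = TRUE),
                                      collapse = ""),
                      target_id = target$id)
        if (nrow(find_probe_bindings(target, cand)) == 0L) break
        cand <- NULL
      }
      if (is.null(cand)) stop("could not generate a non-binding probe")
      cand
    }
    pool <- list()
    if (spec$cap_fraction < 1) {
      unc <- target
      unc$id <- paste0(target_id, "_ppp")
      pool <- c(pool, list(list(seq = unc,
                                abundance = 1 - spec$cap_fraction)))
    }
    if (spec$cap_fraction > 0) {
      cap <- target
      cap$id <- paste0(target_id, "_cap0")
      cap$five_prime <- "cap0"
      pool <- c(pool, list(list(seq = cap, abundance = spec$cap_fraction)))
    }
    structure(list(
      target = target, probe = pr, pool = pool,
      summary = list(
        expected_protected_length = if (spec$five_prime_match)
          spec$probe_length else NA_integer_,
        cap_fraction = spec$cap_fraction,
        polyA_tail = spec$polyA_tail,
        seed = spec$seed)),
      class = "rpa_fixture")
  })
}

#' @export
print.rpa_fixture <- function(x, ...) {
  cat(sprintf("<rpa_fixture> target %s (%d nt), probe %s (%d nt), cap fraction %.2f, poly(A) %d nt\n",
              x$target$id, length(x$target), x$probe$id, length(x$probe),
              x$summary$cap_fraction, x$summary$polyA_tail))
  invisible(x)
}
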