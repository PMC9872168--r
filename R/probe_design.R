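# Antisense DNA probe design for identity, 5'-cap and poly(A) assays.
# Probes are cheap synthetic DNA oligos; the assay works because a
# DNA-RNA hybrid resists single-strand-specific RNases in excess salt.

#' Construct a DNA probe
#'
#' @param id Probe identifier (the synthesis order name).
#' @param sequence DNA sequence, 5' to 3' as ordered for synthesis
#'   (character or DNA [nucleic_seq()]).
#' @param target_id Identifier of the intended target, or `NA`.
#' @param intended_interval Optional length-2 integer vector
#'   `c(start, end)` (0-based, half-open target coordinates) the probe
#'   was designed against.
#' @return An `rpa_probe` object.  Probe length is bounded to 10-60 nt;
#'   the practical range for this assay is 16-25 nt, with 16-20 nt
#'   recommended for cap analysis (see [gel_config()] for the matching
#'   resolution window).
#' @export
probe <- function(id, sequence, target_id = NA_character_,
                  intended_interval = NULL) {
  seq <- if (inherits(sequence, "nucleic_seq")) sequence
         else nucleic_seq(id, sequence, kind = "DNA")
  if (seq$kind != "DNA") stop("probe '", id, "' must be DNA")
  if (length(seq) < 10L || length(seq) > 60L)
    stop("probe '", id, "' length ", length(seq),
         " nt outside the hard bounds [10, 60]")
  if (!is.null(intended_interval)) {
    stopifnot(length(intended_interval) == 2L)
    intended_interval <- as.integer(intended_interval)
    if (diff(intended_interval) != length(seq))
      stop("intended_interval width does not match probe length")
  }
  structure(list(id = id, seq = seq, target_id = target_id,
                 intended_interval = intended_interval),
            class = "rpa_probe")
}

#' @export
length.rpa_probe <- function(x) length(x$seq)

#' @export
print.rpa_probe <- function(x, ...) {
  iv <- if (is.null(x$intended_interval)) "unplaced"
        else sprintf("[%d,%d)", x$intended_interval[1], x$intended_interval[2])
  cat(sprintf("<rpa_probe> %s: %d nt vs target %s at %s\n  5'-%s-3'\n",
              x$id, length(x), x$target_id, iv, x$seq$residues))
  invisible(x)
}

#' Design a probe against the 5' end of a target
#'
#' The 5'-end probe is the workhorse of the cap assay: the protected
#' fragment carries the target's original 5' chemistry, so a cap 0
#' resolves from a triphosphate end as a slower band on the gel.
#'
#' @param target RNA [nucleic_seq()].
#' @param length Probe length in nt (default 20, the standard choice for
#'   cap analysis; must lie in 10 to `length(target)`).
#' @param id Probe identifier.
#' @return An [probe()] with `intended_interval = c(0, length)`.
#' @export
design_five_prime_probe <- function(target, length = 20L,
                                    id = sprintf("%s_5p_%dnt", target$id, length)) {
  stopifnot(inherits(target, "nucleic_seq"))
  if (target$kind != "RNA") stop("probe design targets must be RNA")
  length <- as.integer(length)
  if (length < 10L || length > base::length(target))
    stop("probe length must lie in [10, target length]")
  design_region_probe(target, 0L, length, id = id)
}

#' Design a probe against an arbitrary target region
#'
#' Builds the antisense DNA oligo over `[start, end)` of the target.
#' A warning is issued when the probe binds the target at more than one
#' site (non-unique; its protected fragment would not identify the
#' region).  A probe covering the target's 3' terminus is flagged as a
#' 3'-end / poly(A)-tail assay candidate.
#'
#' @param target RNA [nucleic_seq()].
#' @param start,end 0-based half-open target coordinates.
#' @param id Probe identifier.
#' @return An [probe()]; field `three_prime_candidate` is `TRUE` when
#'   `end == length(target)`.
#' @export
design_region_probe <- function(target, start, end,
                                id = sprintf("%s_%d_%d", target$id, start, end)) {
  stopifnot(inherits(target, "nucleic_seq"))
  if (target$kind != "RNA") stop("probe design targets must be RNA")
  start <- as.integer(start); end <- as.integer(end)
  n <- length(target)
  if (start < 0L || end > n || start >= end)
    stop("invalid interval [", start, ",", end, ") on a ", n, " nt target")
  sub <- nucleic_seq(id, substr(target$residues, start + 1L, end),
                     kind = "RNA", five_prime = "hydroxyl")
  p <- probe(id, reverse_complement(sub, out_kind = "DNA", id = id),
             target_id = target$id, intended_interval = c(start, end))
  p$three_prime_candidate <- end == n
  if (p$three_prime_candidate)
    message("probe '", id, "' covers the target 3' terminus: ",
            "3'-end / poly(A)-tail assay candidate")
  nsites <- nrow(find_probe_bindings(target, p))
  if (nsites > 1L)
    warning("probe '", id, "' binds the target at ", nsites,
            " sites (non-unique)")
  p
}

#' Predict the assay outcome for a candidate probe
#'
#' Runs the full in-silico assay (protection map, complete digestion,
#' detectability filter) and summarizes what the lane would show:
#' binding-site count, protected fragment length, background count
#' (detectable fragments from unprotected regions), and whether the
#' protected fragment sits in the gel's single-nucleotide resolution
#' window.
#'
#' @param target RNA [nucleic_seq()].
#' @param probe [probe()] or DNA [nucleic_seq()].
#' @param enzymes List of [enzyme_spec()]s (default: the RNase A + T1
#'   mixture, which minimizes background).
#' @param gel [gel_config()] supplying the detection threshold and
#'   resolution window.
#' @param salt_mode,edge_rule Passed to [build_protection_map()] and
#'   [digest_rna()].
#' @return A `probe_report` list: `probe_id`, `binding_sites`,
#'   `protected_fragment_length` (`NA` when nothing is protected),
#'   `protected_equals_probe`, `offtarget_detectable_fragments`,
#'   `within_resolution_window`, `edge_rule`.
#' @export
evaluate_probe <- function(target, probe,
                           enzymes = list(rnase_a(), rnase_t1()),
                           gel = gel_config(),
                           salt_mode = "high_salt",
                           edge_rule = "edge_permissive") {
  pr <- if (inherits(probe, "rpa_probe")) probe else probe(.probe_seq(probe)$id, probe)
  pmap <- build_protection_map(target, pr, salt_mode = salt_mode)
  frags <- digest_rna(target, pmap, enzymes = enzymes, edge_rule = edge_rule)
  det <- detectable_fragments(frags, min_len = gel$min_detectable)
  protected <- frags[frags$protected_overlap > 0L, , drop = FALSE]
  plen <- if (nrow(protected)) max(protected$length) else NA_integer_
  structure(list(
    probe_id = pr$id,
    binding_sites = pmap$probes$n_sites[1L],
    protected_fragment_length = plen,
    protected_equals_probe = isTRUE(plen == length(pr)),
    offtarget_detectable_fragments =
      sum(det$protected_overlap == 0L),
    within_resolution_window = isTRUE(
      plen >= gel$resolution_window[1] & plen <= gel$resolution_window[2]),
    edge_rule = edge_rule),
    class = "probe_report")
}

#' @export
print.probe_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<probe_report> %s\n  binding sites: %d\n",
    "  protected fragment: %s nt (equals probe length: %s)\n",
    "  detectable background fragments: %d\n",
    "  in single-nt resolution window: %s\n  edge rule: %s\n"),
    x$probe_id, x$binding_sites,
    ifelse(is.na(x$protected_fragment_length), "none",
           x$protected_fragment_length),
    x$protected_equals_probe, x$offtarget_detectable_fragments,
    x$within_resolution_window, x$edge_rule))
  invisible(x)
}

#' Write an oligo order sheet for a set of probes
#'
#' @param probes A [probe()] or list of them.
#' @param path Output TSV.
#' @return The path, invisibly; columns are id, sequence (5' to 3'),
#'   target, start, end, length.
#' @export
write_probe_sheet <- function(probes, path) {
  if (inherits(probes, "rpa_probe")) probes <- list(probes)
  df <- do.call(rbind, lapply(probes, function(p) data.frame(
    id = p$id, sequence = p$seq$residues, target = p$target_id,
    start = if (is.null(p$intended_interval)) NA_integer_
            else p$intended_interval[1],
    end = if (is.null(p$intended_interval)) NA_integer_
          else p$intended_interval[2],
    length = length(p))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
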