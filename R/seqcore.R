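# Sequence domain model shared by every other module.  A strand is more
# than its residues here: the assay logic depends on explicit 5'/3' end
# chemistries (a primary IVT transcript carries a 5'-triphosphate, the
# Vaccinia-capped product a cap 0, RNase cleavage products 5'-OH and
# 3'-phosphate ends), so they are first-class fields.

.five_prime_states <- c("triphosphate", "monophosphate", "hydroxyl", "cap0")
.three_prime_states <- c("hydroxyl", "phosphate", "cyclic_phosphate")

#' Construct a nucleic-acid strand with explicit end chemistry
#'
#' A `nucleic_seq` is a single DNA or RNA strand written 5' to 3' with an
#' explicit chemistry at each end.  The alphabet must match `kind` exactly
#' (`ACGT` for DNA, `ACGU` for RNA; mixing `T` and `U` is an error) and
#' the cap 0 structure (m7GpppN) is only valid on RNA.
#'
#' @param id Record identifier, preserved verbatim in all outputs.
#' @param residues Residue string, 5' to 3'.  Whitespace is stripped and
#'   case normalized to upper.
#' @param kind `"DNA"` or `"RNA"`.  When `NULL`, inferred from the
#'   alphabet: `U` implies RNA, `T` implies DNA; a sequence containing
#'   neither defaults to RNA (this package is mRNA-centric; pass
#'   `kind = "DNA"` explicitly for T-less oligos).
#' @param five_prime One of `"triphosphate"`, `"monophosphate"`,
#'   `"hydroxyl"`, `"cap0"`.  Defaults to `"triphosphate"` for RNA (an
#'   uncapped primary IVT transcript) and `"hydroxyl"` for DNA (a
#'   synthetic oligo).
#' @param three_prime One of `"hydroxyl"`, `"phosphate"`,
#'   `"cyclic_phosphate"`.
#' @return An object of class `nucleic_seq`.
#' @examples
#' nucleic_seq("t1", "GGGAUC")                  # RNA, 5'-triphosphate
#' nucleic_seq("p1", "GATCCC", kind = "DNA")    # DNA, 5'-hydroxyl
#' @export
nucleic_seq <- function(id, residues, kind = NULL,
                        five_prime = NULL, three_prime = "hydroxyl") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (nchar(residues) < 1L)
    stop("sequence '", id, "' is empty")
  has_t <- grepl("T", residues, fixed = TRUE)
  has_u <- grepl("U", residues, fixed = TRUE)
  if (has_t && has_u)
    stop("sequence '", id, "' mixes T and U")
  if (is.null(kind))
    kind <- if (has_u) "RNA" else if (has_t) "DNA" else "RNA"
  kind <- match.arg(kind, c("DNA", "RNA"))
  alphabet <- if (kind == "DNA") "ACGT" else "ACGU"
  bad <- gsub(sprintf("[%s]", alphabet), "", residues)
  if (nzchar(bad))
    stop("sequence '", id, "' contains characters outside the ", kind,
         " alphabet: ", paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  five_prime <- match.arg(five_prime %||%
                            if (kind == "RNA") "triphosphate" else "hydroxyl",
                          .five_prime_states)
  three_prime <- match.arg(three_prime, .three_prime_states)
  if (five_prime == "cap0" && kind != "RNA")
    stop("cap0 is only valid on RNA (sequence '", id, "')")
  structure(list(id = id, kind = kind, residues = residues,
                 five_prime = five_prime, three_prime = three_prime),
            class = "nucleic_seq")
}

#' @export
length.nucleic_seq <- function(x) nchar(x$residues)

#' @export
print.nucleic_seq <- function(x, ...) {
  n <- length(x)
  shown <- if (n > 60L) paste0(substr(x$residues, 1L, 57L), "...") else x$residues
  cat(sprintf("<nucleic_seq> %s: %d nt %s [5'-%s, 3'-%s]\n  %s\n",
              x$id, n, x$kind, x$five_prime, x$three_prime, shown))
  invisible(x)
}

.as_xstring <- function(seq) {
  if (seq$kind == "RNA") Biostrings::RNAString(seq$residues)
  else Biostrings::DNAString(seq$residues)
}

#' Reverse complement of a strand
#'
#' Returns the reverse complement in the requested alphabet (A pairs with
#' T for DNA output, with U for RNA output).  End chemistries of the
#' result are reset to hydroxyl/hydroxyl: the reverse complement is a new
#' synthetic strand, not a chemical transformation of the input.
#'
#' @param seq A [nucleic_seq()].
#' @param out_kind Output alphabet, `"DNA"` or `"RNA"`; defaults to the
#'   input's kind.
#' @param id Identifier for the result; default appends `"_rc"`.
#' @return A `nucleic_seq` of kind `out_kind`.
#' @examples
#' reverse_complement(nucleic_seq("x", "GAUC"), out_kind = "DNA")  # "GATC"
#' @export
reverse_complement <- function(seq, out_kind = seq$kind,
                               id = paste0(seq$id, "_rc")) {
  stopifnot(inherits(seq, "nucleic_seq"))
  out_kind <- match.arg(out_kind, c("DNA", "RNA"))
  rc <- as.character(Biostrings::reverseComplement(.as_xstring(seq)))
  rc <- if (out_kind == "DNA") chartr("U", "T", rc) else chartr("T", "U", rc)
  nucleic_seq(id, rc, kind = out_kind,
              five_prime = "hydroxyl", three_prime = "hydroxyl")
}

# Accept either a bare DNA nucleic_seq or an rpa_probe wherever a probe is
# expected.
.probe_seq <- function(probe) {
  if (inherits(probe, "rpa_probe")) probe <- probe$seq
  stopifnot(inherits(probe, "nucleic_seq"))
  if (probe$kind != "DNA")
    stop("probes are DNA oligonucleotides; got an RNA sequence ('",
         probe$id, "')")
  probe
}

#' Find every perfect binding site of a DNA probe on an RNA target
#'
#' Binding is all-or-nothing: a probe binds at `[s, e)` iff the target
#' subsequence over that interval equals the probe's reverse complement
#' (as RNA) at every position.  This mirrors the assay's readout logic, in
#' which a probe lacking perfect complementarity protects nothing and the
#' target is completely digested.  No mismatch tolerance is modeled.
#'
#' @param target RNA [nucleic_seq()].
#' @param probe DNA [nucleic_seq()] or [probe()].
#' @return A data frame with columns `start`, `end` (0-based, half-open
#'   target coordinates), one row per binding site, sorted by `start`.
#'   Zero rows when no perfect match exists.
#' @export
find_probe_bindings <- function(target, probe) {
  stopifnot(inherits(target, "nucleic_seq"))
  if (target$kind != "RNA") stop("binding targets must be RNA")
  probe <- .probe_seq(probe)
  if (length(probe) > length(target))
    stop("probe '", probe$id, "' (", length(probe),
         " nt) is longer than target '", target$id, "' (", length(target), " nt)")
  expected <- reverse_complement(probe, out_kind = "RNA")$residues
  hits <- Biostrings::matchPattern(expected, .as_xstring(target))
  ir <- methods::as(hits, "IRanges")
  out <- data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  out[order(out$start), , drop = FALSE]
}

# Merge possibly overlapping 0-based half-open intervals into a disjoint
# sorted set (IRanges does the arithmetic; coordinates converted at the
# boundary).
.merge_intervals <- function(df) {
  if (is.null(df) || nrow(df) == 0L)
    return(data.frame(start = integer(), end = integer()))
  ir <- IRanges::reduce(IRanges::IRanges(start = df$start + 1L, end = df$end))
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Read sequences from a FASTA file
#'
#' Standard multi-record FASTA (wrapped or unwrapped); record ids are the
#' full header lines, preserved verbatim.  Kind is inferred per record
#' from the alphabet unless overridden; records containing neither `T`
#' nor `U` are ambiguous and read as RNA with a warning.
#'
#' @param path FASTA file.
#' @param kind `"auto"` (default), `"DNA"`, or `"RNA"` applied to all
#'   records.
#' @param five_prime,three_prime End chemistries for all records; `NULL`
#'   `five_prime` gives the kind-specific default (RNA: triphosphate,
#'   the uncapped primary IVT transcript; DNA: hydroxyl).
#' @return A list of [nucleic_seq()] objects.
#' @export
read_fasta <- function(path, kind = c("auto", "DNA", "RNA"),
                       five_prime = NULL, three_prime = "hydroxyl") {
  kind <- match.arg(kind)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- names(set)
  lapply(seq_along(set), function(i) {
    res <- toupper(as.character(set[[i]]))
    if (!nzchar(res)) stop("empty FASTA record '", ids[i], "' in ", path)
    k <- if (kind == "auto") {
      if (!grepl("[TU]", res)) {
        warning("record '", ids[i], "' contains neither T nor U; reading as RNA")
        "RNA"
      } else NULL
    } else kind
    nucleic_seq(ids[i], res, kind = k,
                five_prime = five_prime, three_prime = three_prime)
  })
}

#' Write sequences to a FASTA file
#'
#' @param seqs A [nucleic_seq()] or list of them.
#' @param path Output file.
#' @param width Line-wrap width (nt).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "nucleic_seq")) seqs <- list(seqs)
  res <- vapply(seqs, function(s) s$residues, character(1))
  names(res) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(Biostrings::BStringSet(res), filepath = path,
                              width = width)
  invisible(path)
}
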