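# Theoretical oligoribonucleotide masses and probe-tiling design for the
# mass-spectrometry variant of the protection assay (RNase mass mapping).
#
# Masses are computed from elemental compositions.  The internal
# convention: the per-residue mass is the nucleoside 5'-monophosphate
# minus water, so that sum(residues) + water gives the chain with a
# 5'-monophosphate and 3'-hydroxyl; end-chemistry adjustments are applied
# relative to that baseline.  Consequences used as invariants elsewhere:
# a 2',3'-cyclic phosphate weighs one water less than the linear
# 3'-phosphate, and cutting a phosphodiester bond (hydrolysis) adds one
# water, so the fragment masses of a digest sum to the parent mass plus
# (number of cuts) x water under linear-phosphate products.

.atomic_masses <- list(
  monoisotopic = c(H = 1.0078250319, C = 12, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151),
  average = c(H = 1.00794, C = 12.0107, N = 14.0067, O = 15.9994,
              P = 30.973762))

.formula_mass <- function(counts, mode) {
  sum(.atomic_masses[[mode]][names(counts)] * counts)
}

# Elemental compositions: residue = nucleoside 5'-monophosphate - H2O.
.residue_formulas <- list(
  A = c(C = 10, H = 12, N = 5, O = 6, P = 1),
  C = c(C = 9,  H = 12, N = 3, O = 7, P = 1),
  G = c(C = 10, H = 12, N = 5, O = 7, P = 1),
  U = c(C = 9,  H = 11, N = 2, O = 8, P = 1))
.water_formula <- c(H = 2, O = 1)
.hpo3_formula <- c(H = 1, P = 1, O = 3)
# 7-methylguanosine nucleoside (guanosine + CH2)
.m7g_formula <- c(C = 11, H = 15, N = 5, O = 5)

#' Monoisotopic and average mass table for RNA fragments
#'
#' Per-residue masses plus end-chemistry adjustments relative to the
#' 5'-monophosphate / 3'-hydroxyl baseline.  The cap 0 adjustment adds
#' the m7Gppp moiety (7-methylguanosine joined through a 5'-5'
#' triphosphate bridge) and applies only to a 5'-terminal fragment.
#'
#' @return An `rna_mass_table` list with elements `residues` (matrix,
#'   rows A/C/G/U, columns monoisotopic/average), `water`, `five_prime`
#'   and `three_prime` adjustment matrices.
#' @export
rna_mass_table <- function() {
  modes <- c("monoisotopic", "average")
  residues <- vapply(modes, function(m)
    vapply(.residue_formulas, .formula_mass, numeric(1), mode = m),
    numeric(4))
  water <- vapply(modes, function(m) .formula_mass(.water_formula, m),
                  numeric(1))
  hpo3 <- vapply(modes, function(m) .formula_mass(.hpo3_formula, m),
                 numeric(1))
  m7g <- vapply(modes, function(m) .formula_mass(.m7g_formula, m),
                numeric(1))
  five <- rbind(triphosphate = 2 * hpo3,
                monophosphate = c(0, 0),
                hydroxyl = -hpo3,
                cap0 = 2 * hpo3 + m7g - water)
  three <- rbind(hydroxyl = c(0, 0),
                 phosphate = hpo3,
                 cyclic_phosphate = hpo3 - water)
  colnames(five) <- colnames(three) <- modes
  structure(list(residues = residues, water = water,
                 five_prime = five, three_prime = three),
            class = "rna_mass_table")
}

#' Theoretical mass of an RNA fragment with its end chemistries
#'
#' @param fragment A fragment row ([digest_rna()] output), a data frame
#'   of such rows, or an RNA [nucleic_seq()].
#' @param table A [rna_mass_table()].
#' @param mode `"monoisotopic"` or `"average"`.
#' @return Mass(es) in Da, one per fragment.
#' @examples
#' g3p <- nucleic_seq("g", "G", five_prime = "hydroxyl",
#'                    three_prime = "phosphate")
#' fragment_mass(g3p)  # guanosine 3'-monophosphate, 363.058 Da
#' @export
fragment_mass <- function(fragment, table = rna_mass_table(),
                          mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  if (inherits(fragment, "nucleic_seq")) {
    if (fragment$kind != "RNA") stop("mass table covers RNA residues only")
    fragment <- data.frame(sequence = fragment$residues,
                           five_prime = fragment$five_prime,
                           three_prime = fragment$three_prime)
  }
  res <- table$residues[, mode]
  vapply(seq_len(nrow(fragment)), function(i) {
    f5 <- fragment$five_prime[i]; f3 <- fragment$three_prime[i]
    if (!f5 %in% rownames(table$five_prime))
      stop("unknown 5' chemistry: ", f5)
    if (!f3 %in% rownames(table$three_prime))
      stop("unknown 3' chemistry: ", f3)
    bases <- strsplit(fragment$sequence[i], "", fixed = TRUE)[[1]]
    if (!all(bases %in% names(res)))
      stop("non-RNA residue in fragment ", i)
    sum(res[bases]) + table$water[mode] +
      table$five_prime[f5, mode] + table$three_prime[f3, mode]
  }, numeric(1))
}

#' Tabulate fragment masses for export
#'
#' @param fragments A [digest_rna()] result.
#' @param table A [rna_mass_table()].
#' @param path Optional TSV output path.
#' @return The fragment table with `monoisotopic` and `average` columns.
#' @export
fragment_mass_report <- function(fragments, table = rna_mass_table(),
                                 path = NULL) {
  fragments$monoisotopic <- fragment_mass(fragments, table, "monoisotopic")
  fragments$average <- fragment_mass(fragments, table, "average")
  if (!is.null(path))
    utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  fragments
}

# ---- internal fast digest machinery shared by the coverage functions ----
# A cut set is represented by the 0-based positions b such that the bond
# between residues b-1 and b is cleaved; fragment [a, b) masses come from
# prefix sums of residue masses.

.tile_env <- function(target, enzymes, table, mode) {
  res <- strsplit(target$residues, "", fixed = TRUE)[[1]]
  n <- length(res)
  cut_enzyme <- integer(max(n - 1L, 0L))
  if (n > 1L) for (j in rev(seq_along(enzymes)))
    cut_enzyme[res[-n] %in% enzymes[[j]]$recognition] <- j
  cuts <- which(cut_enzyme > 0L)              # 1-based bond j: cut after res j
  prod3 <- vapply(enzymes, function(e) e$product_3prime, character(1))
  rmass <- table$residues[, mode]
  prefix <- c(0, cumsum(rmass[res]))
  adj5 <- table$five_prime[, mode]; adj3 <- table$three_prime[, mode]
  frag_mass <- function(a, b) {               # 0-based half-open [a, b)
    m5 <- if (a == 0L) adj5[[target$five_prime]] else adj5[["hydroxyl"]]
    m3 <- if (b == n) adj3[[target$three_prime]]
          else adj3[[prod3[cut_enzyme[b]]]]
    prefix[b + 1L] - prefix[a + 1L] + table$water[mode] + m5 + m3
  }
  starts <- c(0L, cuts); ends <- c(cuts, n)
  list(n = n, cuts = cuts, frag_starts = starts, frag_ends = ends,
       frag_len = ends - starts,
       frag_masses = vapply(seq_along(starts), function(i)
         frag_mass(starts[i], ends[i]), numeric(1)),
       frag_mass = frag_mass)
}

.mass_unique <- function(mass, others, tolerance) {
  length(others) == 0L || min(abs(others - mass)) > tolerance
}

#' Sequence coverage of an unprobed ("traditional") RNase mass map
#'
#' Digests the target with no probe present and counts a position as
#' covered when its fragment is detectable and its mass is unique within
#' `tolerance_da` among all fragments of the digest (two identical-mass
#' fragments identify neither).  An uncut target is a single full-length
#' fragment, trivially mass-unique, and counts as covered when
#' detectable.
#'
#' @param target RNA [nucleic_seq()].
#' @param enzymes List of [enzyme_spec()]s (default RNase T1, the
#'   classic mass-mapping nuclease).
#' @param tolerance_da Mass-uniqueness tolerance in Da (default 0.01,
#'   monoisotopic; raise it for lower-resolution instruments).
#' @param min_frag_len,max_frag_len MS detectability limits in nt
#'   (defaults 3 and unbounded: mono- and dinucleotides are assumed lost
#'   in the low-mass region).
#' @param mode,table Mass mode and table (see [rna_mass_table()]).
#' @return A `mass_map` list: `coverage` fraction, `covered` logical per
#'   position, `fragments` data frame with `detectable` and `unique`
#'   flags.
#' @export
baseline_mass_map <- function(target, enzymes = list(rnase_t1()),
                              tolerance_da = 0.01,
                              min_frag_len = 3L, max_frag_len = Inf,
                              mode = "monoisotopic",
                              table = rna_mass_table()) {
  stopifnot(inherits(target, "nucleic_seq"), target$kind == "RNA",
            tolerance_da > 0)
  env <- .tile_env(target, enzymes, table, mode)
  k <- length(env$frag_starts)
  det <- env$frag_len >= min_frag_len & env$frag_len <= max_frag_len
  uniq <- vapply(seq_len(k), function(i)
    .mass_unique(env$frag_masses[i], env$frag_masses[-i], tolerance_da),
    logical(1))
  covered <- logical(env$n)
  for (i in which(det & uniq))
    covered[(env$frag_starts[i] + 1L):env$frag_ends[i]] <- TRUE
  structure(list(
    coverage = mean(covered), covered = covered,
    fragments = data.frame(start = env$frag_starts, end = env$frag_ends,
                           length = env$frag_len, mass = env$frag_masses,
                           detectable = det, unique = uniq)),
    class = "mass_map")
}

#' @export
print.mass_map <- function(x, ...) {
  cat(sprintf("<mass_map> coverage %.1f%% of %d nt (%d fragments, %d identifying)\n",
              100 * x$coverage, length(x$covered), nrow(x$fragments),
              sum(x$fragments$detectable & x$fragments$unique)))
  invisible(x)
}

#' Greedy probe tiling for maximal mass-mapping coverage
#'
#' Designs a series of protection probes, one per simulated digestion
#' round (the bench format: one probe per assay tube), so that each
#' round's protected fragment is MS-detectable and mass-unique within
#' `tolerance_da` against every other fragment of that round's digest.
#' Selection is greedy set cover over target positions: each round picks
#' the candidate probe interval adding the most not-yet-covered
#' positions, ties broken by leftmost start then shortest probe; probe
#' intervals of different rounds do not overlap.  The unprobed digest is
#' always included as round 0 (a practitioner runs it anyway), so tiling
#' coverage is never below [baseline_mass_map()] coverage; a target too
#' short for any probe yields an empty design at the baseline coverage.
#'
#' @param target RNA [nucleic_seq()].
#' @param enzymes List of [enzyme_spec()]s.
#' @param probe_len_range Length-2 integer vector of allowed probe
#'   lengths (nt), within the 10-60 hard bounds; default 16-20, the
#'   range recommended for single-nucleotide work.
#' @param tolerance_da Mass-uniqueness tolerance in Da.
#' @param min_frag_len,max_frag_len MS detectability limits in nt.
#' @param max_rounds Cap on the number of probes (default unlimited).
#' @param multiplex If `TRUE`, additionally evaluates all selected
#'   probes co-incubated in a single pot and reports that experiment's
#'   coverage instead of the per-round union.  Off by default.
#' @param include_baseline Include the unprobed digest as round 0.
#' @param mode,table Mass mode and table.
#' @return A `tiling_design` list: `probes` (list of [probe()]s),
#'   `rounds` (data frame: probe interval, protected fragment, coverage
#'   gain), `covered`, `coverage`, `uncovered_intervals`,
#'   `baseline_coverage`, `multiplex`.
#' @export
design_tiling <- function(target, enzymes = list(rnase_t1()),
                          probe_len_range = c(16L, 20L),
                          tolerance_da = 0.01,
                          min_frag_len = 3L, max_frag_len = Inf,
                          max_rounds = Inf, multiplex = FALSE,
                          include_baseline = TRUE,
                          mode = "monoisotopic", table = rna_mass_table()) {
  stopifnot(inherits(target, "nucleic_seq"), target$kind == "RNA",
            tolerance_da > 0, length(probe_len_range) == 2L)
  probe_len_range <- as.integer(probe_len_range)
  if (probe_len_range[1] < 10L || probe_len_range[2] > 60L ||
      probe_len_range[1] > probe_len_range[2])
    stop("probe_len_range must be ordered and within the [10, 60] bounds")
  n <- length(target)
  base <- baseline_mass_map(target, enzymes, tolerance_da, min_frag_len,
                            max_frag_len, mode, table)
  env <- .tile_env(target, enzymes, table, mode)
  covered <- if (include_baseline) base$covered else logical(n)

  # Candidate probe intervals [s, s+L): under the edge-permissive
  # convention a probe suppresses the bonds whose downstream residue it
  # covers, so the protected fragment [a, b) runs from the last surviving
  # cut before s to the first cut at or after s+L.
  cand <- do.call(rbind, lapply(probe_len_range[1]:probe_len_range[2],
                                function(L) {
    if (L > n) return(NULL)
    s <- 0:(n - L)
    pad_a <- c(0L, env$cuts)        # last surviving cut before the probe
    pad_b <- c(env$cuts, n)         # first surviving cut at/after its end
    ia <- findInterval(s - 0.5, env$cuts)
    ib <- findInterval(s + L - 0.5, env$cuts) + 1L
    data.frame(s = s, L = L, a = pad_a[ia + 1L],
               b = pad_b[pmin(ib, length(pad_b))])
  }))
  probes <- list(); rounds <- NULL
  if (!is.null(cand)) {
    chosen <- matrix(integer(0), ncol = 2)  # s, e of accepted probes
    repeat {
      if (length(probes) >= max_rounds) break
      cum <- c(0, cumsum(!covered))
      gain <- cum[cand$b + 1L] - cum[cand$a + 1L]
      ord <- order(-gain, cand$s, cand$L)
      pick <- NULL
      for (i in ord) {
        if (gain[i] <= 0) break
        s <- cand$s[i]; e <- s + cand$L[i]
        if (nrow(chosen) &&
            any(s < chosen[, 2] & e > chosen[, 1])) next  # overlaps a probe
        a <- cand$a[i]; b <- cand$b[i]
        len <- b - a
        if (len < min_frag_len || len > max_frag_len) next
        # mass uniqueness of the merged (protected) fragment against the
        # rest of this round's digest
        merged <- env$frag_mass(a, b)
        inside <- env$frag_starts >= a & env$frag_ends <= b
        if (!.mass_unique(merged, env$frag_masses[!inside], tolerance_da))
          next
        pick <- list(i = i, s = s, e = e, a = a, b = b, gain = gain[i])
        break
      }
      if (is.null(pick)) break
      pr <- suppressMessages(design_region_probe(target, pick$s, pick$e))
      probes[[length(probes) + 1L]] <- pr
      chosen <- rbind(chosen, c(pick$s, pick$e))
      covered[(pick$a + 1L):pick$b] <- TRUE
      rounds <- rbind(rounds, data.frame(
        round = length(probes), probe_id = pr$id,
        probe_start = pick$s, probe_end = pick$e,
        fragment_start = pick$a, fragment_end = pick$b,
        gain = pick$gain))
    }
  }
  if (multiplex && length(probes)) {
    pmap <- build_protection_map(target, probes, salt_mode = "high_salt")
    fr <- digest_rna(target, pmap, enzymes = enzymes)
    fr$mass <- fragment_mass(fr, table, mode)
    det <- fr$length >= min_frag_len & fr$length <= max_frag_len
    covered <- if (include_baseline) base$covered else logical(n)
    for (i in which(det & fr$protected_overlap > 0)) {
      if (.mass_unique(fr$mass[i], fr$mass[-i], tolerance_da))
        covered[(fr$start[i] + 1L):fr$end[i]] <- TRUE
    }
  }
  runs <- rle(!covered)
  stops <- cumsum(runs$lengths)
  uncovered <- data.frame(start = (stops - runs$lengths)[runs$values],
                          end = stops[runs$values])
  structure(list(probes = probes, rounds = rounds, covered = covered,
                 coverage = mean(covered), uncovered_intervals = uncovered,
                 baseline_coverage = base$coverage, multiplex = multiplex),
            class = "tiling_design")
}

#' @export
print.tiling_design <- function(x, ...) {
  cat(sprintf("<tiling_design> %d probes, coverage %.1f%% (baseline %.1f%%)%s\n",
              length(x$probes), 100 * x$coverage, 100 * x$baseline_coverage,
              if (x$multiplex) " [multiplex pot]" else ""))
  if (!is.null(x$rounds))
    for (i in seq_len(nrow(x$rounds)))
      cat(sprintf("  round %d: probe [%d,%d) -> fragment [%d,%d), +%d nt\n",
                  x$rounds$round[i], x$rounds$probe_start[i],
                  x$rounds$probe_end[i], x$rounds$fragment_start[i],
                  x$rounds$fragment_end[i], x$rounds$gain[i]))
  invisible(x)
}
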