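# Denaturing urea-PAGE lane prediction.
#
# Only ordering and resolvability on the gel are scientifically
# meaningful for this assay, so mobility is modeled ordinally through an
# "apparent length" in DNA-length equivalents: RNA runs about one
# nt-equivalent slower than DNA of the same length, and a 5' cap 0 adds a
# further retardation resolvable on a single-nucleotide gel.  The map to
# relative mobility, 1 / (1 + apparent_length / 100), is monotone and
# fixed; absolute migration distances are not modeled.

#' Gel configuration for lane prediction
#'
#' @param rna_offset Apparent-length increment (nt-equivalents) for RNA
#'   relative to DNA of equal length.  Default 1.0: RNA of length L
#'   co-migrates with DNA of length L + 1.
#' @param cap0_offset Additional increment for a 5' cap 0.  The true
#'   electrophoretic increment of the cap structure is not established;
#'   the default 1.0 nt-equivalent is the minimal value resolvable on a
#'   single-nucleotide gel and is flagged as a configurable placeholder
#'   in reports.
#' @param resolution_window Length-2 vector: the nominal-length range
#'   (nt) over which the gel resolves single nucleotides (default 16-24).
#' @param resolution_in_window,resolution_out_window Minimal apparent
#'   length difference (nt-equivalents) resolvable for band pairs inside
#'   / outside the window (defaults 1 and 3).
#' @param min_detectable Minimum nominal length (nt) for a species to be
#'   visible at all (default 8).
#' @return A `gel_config` list.
#' @export
gel_config <- function(rna_offset = 1.0, cap0_offset = 1.0,
                       resolution_window = c(16, 24),
                       resolution_in_window = 1.0,
                       resolution_out_window = 3.0,
                       min_detectable = 8L) {
  stopifnot(rna_offset >= 0, cap0_offset >= 0,
            length(resolution_window) == 2L,
            resolution_window[1] > 0,
            resolution_window[1] <= resolution_window[2],
            resolution_in_window > 0, resolution_out_window > 0,
            min_detectable >= 1)
  structure(list(rna_offset = rna_offset, cap0_offset = cap0_offset,
                 resolution_window = as.numeric(resolution_window),
                 resolution_in_window = resolution_in_window,
                 resolution_out_window = resolution_out_window,
                 min_detectable = as.integer(min_detectable)),
            class = "gel_config")
}

#' Apparent electrophoretic length of a species
#'
#' DNA of length L defines the length scale (apparent length L); uncapped
#' RNA runs at L + `rna_offset`; cap 0 RNA at L + `rna_offset` +
#' `cap0_offset`.  Vectorized over species.
#'
#' @param kind `"DNA"` or `"RNA"` (recycled).
#' @param nominal_length Length(s) in nt.
#' @param five_prime 5' chemistry; only `"cap0"` affects mobility.
#' @param config A [gel_config()].
#' @return Apparent length(s) in nt-equivalents.
#' @export
apparent_length <- function(kind, nominal_length, five_prime = "hydroxyl",
                            config = gel_config()) {
  stopifnot(all(kind %in% c("DNA", "RNA")))
  nominal_length +
    ifelse(kind == "RNA", config$rna_offset, 0) +
    ifelse(kind == "RNA" & five_prime == "cap0", config$cap0_offset, 0)
}

.relative_mobility <- function(apparent) 1 / (1 + apparent / 100)

# Internal: normalize a species table (id, kind, nominal_length,
# five_prime, abundance, capped).
.species_frame <- function(species) {
  need <- c("id", "kind", "nominal_length", "five_prime", "abundance")
  if (!all(need %in% names(species)))
    stop("species table must have columns: ", paste(need, collapse = ", "))
  if (any(species$abundance < 0)) stop("abundances must be >= 0")
  if (is.null(species$capped)) species$capped <- species$five_prime == "cap0"
  species
}

#' Convert digestion fragments to gel species
#'
#' @param fragments A [digest_rna()] result.
#' @param abundance Molar abundance shared by all fragments of this
#'   digest (one molecule yields one of each fragment), unless the
#'   fragment table already carries an `abundance` column.
#' @return A species data frame for [predict_lane()].
#' @export
fragments_to_species <- function(fragments, abundance = 1) {
  if (nrow(fragments) == 0L)
    return(data.frame(id = character(), kind = character(),
                      nominal_length = integer(), five_prime = character(),
                      abundance = numeric(), capped = logical()))
  data.frame(
    id = sprintf("%s:%d-%d", fragments$parent_id, fragments$start,
                 fragments$end),
    kind = "RNA",
    nominal_length = fragments$length,
    five_prime = fragments$five_prime,
    abundance = fragments$abundance %||% rep(abundance, nrow(fragments)),
    capped = fragments$capped)
}

#' Predict the urea-PAGE lane for a set of species
#'
#' Species below the detection threshold (nominal length <
#' `min_detectable`) or with zero abundance are dropped.  The rest are
#' placed at their apparent lengths and merged into bands wherever two
#' adjacent species differ by less than the applicable resolution: the
#' fine (in-window) resolution applies to a pair when either member's
#' nominal length lies in the single-nucleotide window, the coarse one
#' otherwise.  Band intensity is the summed molar abundance of its
#' members (staining differences between DNA and RNA are ignored).
#'
#' @param species Data frame with columns `id`, `kind`,
#'   `nominal_length`, `five_prime`, `abundance` (and optionally
#'   `capped`); build one with [fragments_to_species()].
#' @param config A [gel_config()].
#' @return A data frame of bands sorted by decreasing mobility (fastest,
#'   i.e. shortest, first): `band`, `kind` (`"DNA"`, `"RNA"` or
#'   `"DNA+RNA"`), `nominal_length` (intensity-weighted mean),
#'   `apparent_length`, `relative_mobility`, `intensity`, `capped` (any
#'   member capped), `species` (comma-joined member ids).
#' @export
predict_lane <- function(species, config = gel_config()) {
  sp <- .species_frame(species)
  sp <- sp[sp$abundance > 0 & sp$nominal_length >= config$min_detectable, ,
           drop = FALSE]
  if (nrow(sp) == 0L)
    return(data.frame(band = integer(), kind = character(),
                      nominal_length = numeric(), apparent_length = numeric(),
                      relative_mobility = numeric(), intensity = numeric(),
                      capped = logical(), species = character()))
  sp$apparent <- apparent_length(sp$kind, sp$nominal_length, sp$five_prime,
                                 config)
  sp <- sp[order(sp$apparent), , drop = FALSE]
  w <- config$resolution_window
  in_win <- sp$nominal_length >= w[1] & sp$nominal_length <= w[2]
  band_id <- integer(nrow(sp))
  band_id[1] <- 1L
  for (i in seq_len(nrow(sp))[-1]) {
    resol <- if (in_win[i] || in_win[i - 1L]) config$resolution_in_window
             else config$resolution_out_window
    band_id[i] <- if (sp$apparent[i] - sp$apparent[i - 1L] < resol)
      band_id[i - 1L] else band_id[i - 1L] + 1L
  }
  bands <- do.call(rbind, lapply(split(sp, band_id), function(g) {
    kinds <- unique(g$kind)
    data.frame(
      kind = if (length(kinds) == 1L) kinds else "DNA+RNA",
      nominal_length = stats::weighted.mean(g$nominal_length, g$abundance),
      apparent_length = stats::weighted.mean(g$apparent, g$abundance),
      intensity = sum(g$abundance),
      capped = any(g$capped),
      species = paste(g$id, collapse = ","))
  }))
  bands <- bands[order(bands$apparent_length), , drop = FALSE]
  bands$band <- seq_len(nrow(bands))
  bands$relative_mobility <- .relative_mobility(bands$apparent_length)
  rownames(bands) <- NULL
  bands[, c("band", "kind", "nominal_length", "apparent_length",
            "relative_mobility", "intensity", "capped", "species")]
}

#' Capping efficiency from two band intensities
#'
#' The fraction of target molecules carrying a cap 0, estimated as
#' intensity(capped band) / (intensity(capped) + intensity(uncapped)).
#' Scale-invariant: multiplying all intensities by a positive constant
#' leaves it unchanged.
#'
#' @param lane A [predict_lane()] result.
#' @param capped_band,uncapped_band Band numbers (the `band` column) of
#'   the capped and uncapped protected-fragment bands.
#' @return Fraction in `[0, 1]`.  Both intensities zero is an error
#'   (nothing to quantify).
#' @export
capping_efficiency <- function(lane, capped_band, uncapped_band) {
  get_int <- function(b) {
    i <- match(b, lane$band)
    if (is.na(i)) stop("no band numbered ", b, " in this lane")
    lane$intensity[i]
  }
  ic <- get_int(capped_band); iu <- get_int(uncapped_band)
  if (ic < 0 || iu < 0) stop("band intensities must be >= 0")
  if (ic + iu == 0) stop("both bands have zero intensity; capping ",
                         "efficiency is undefined")
  ic / (ic + iu)
}

#' Simulate the full protection assay on a pool of molecules
#'
#' Each pool member (typically the capped and uncapped forms of one
#' transcript, with molar abundances) is digested under the shared
#' probe-protection map; the surviving fragments plus the free DNA probe
#' are placed on a predicted lane.  The free probe is present in excess
#' in the bench assay; its lane intensity is set to the total pool
#' abundance.
#'
#' @param pool A single RNA [nucleic_seq()], or a list of
#'   `list(seq = <nucleic_seq>, abundance = <number>)` entries.
#' @param probe [probe()] or DNA [nucleic_seq()].
#' @param enzymes List of [enzyme_spec()]s.
#' @param gel A [gel_config()].
#' @param salt_mode,edge_rule Digestion conditions (see
#'   [build_protection_map()], [digest_rna()]).
#' @return An `rpa_assay` list: `fragments` (all fragments of all pool
#'   members with `abundance` and `member` columns), `lane`
#'   (see [predict_lane()]), `probe`, `gel`, `salt_mode`, `edge_rule`.
#' @export
simulate_protection_assay <- function(pool, probe,
                                      enzymes = list(rnase_a()),
                                      gel = gel_config(),
                                      salt_mode = "high_salt",
                                      edge_rule = "edge_permissive") {
  if (inherits(pool, "nucleic_seq"))
    pool <- list(list(seq = pool, abundance = 1))
  frags <- do.call(rbind, lapply(pool, function(m) {
    stopifnot(inherits(m$seq, "nucleic_seq"))
    pmap <- build_protection_map(m$seq, probe, salt_mode = salt_mode)
    f <- digest_rna(m$seq, pmap, enzymes = enzymes, edge_rule = edge_rule)
    f$abundance <- m$abundance
    f$member <- m$seq$id
    f
  }))
  species <- fragments_to_species(frags)
  pr <- .probe_seq(probe)
  species <- rbind(species, data.frame(
    id = pr$id, kind = "DNA", nominal_length = length(pr),
    five_prime = pr$five_prime,
    abundance = sum(vapply(pool, function(m) m$abundance, numeric(1))),
    capped = FALSE))
  structure(list(fragments = frags,
                 lane = predict_lane(species, gel),
                 probe = probe, gel = gel,
                 salt_mode = salt_mode, edge_rule = edge_rule),
            class = "rpa_assay")
}

#' @export
print.rpa_assay <- function(x, ...) {
  cat(sprintf("<rpa_assay> %s, %s edge rule; cap0 mobility offset %.1f nt-eq (configurable placeholder)\n",
              x$salt_mode, x$edge_rule, x$gel$cap0_offset))
  if (nrow(x$lane) == 0L) { cat("  (empty lane)\n"); return(invisible(x)) }
  for (i in seq_len(nrow(x$lane)))
    cat(sprintf("  band %d: %s, apparent %.1f nt-eq, intensity %.3g%s\n",
                x$lane$band[i], x$lane$kind[i], x$lane$apparent_length[i],
                x$lane$intensity[i],
                if (x$lane$capped[i]) " [capped]" else ""))
  invisible(x)
}

#' Estimate capping efficiency from a simulated assay
#'
#' Locates the lane bands carrying the capped and uncapped protected
#' fragments and applies [capping_efficiency()].  A missing band (e.g. a
#' fully capped pool has no uncapped band) contributes zero intensity;
#' both missing is an error, as is co-migration of the two species into
#' one band (the gel then cannot quantify capping).
#'
#' @param assay A [simulate_protection_assay()] result.
#' @return Fraction of capped molecules in `[0, 1]`.
#' @export
estimate_capping_efficiency <- function(assay) {
  stopifnot(inherits(assay, "rpa_assay"))
  fr <- assay$fragments
  prot <- fr[fr$protected_overlap > 0, , drop = FALSE]
  ids <- sprintf("%s:%d-%d", prot$parent_id, prot$start, prot$end)
  find_band <- function(want_capped) {
    sel <- ids[prot$capped == want_capped]
    if (length(sel) == 0L) return(NA_integer_)
    hit <- which(vapply(strsplit(assay$lane$species, ",", fixed = TRUE),
                        function(s) any(sel %in% s), logical(1)))
    if (length(hit) == 0L) NA_integer_ else assay$lane$band[hit[1L]]
  }
  bc <- find_band(TRUE); bu <- find_band(FALSE)
  if (is.na(bc) && is.na(bu))
    stop("no protected fragment band on the lane; cannot estimate capping")
  if (!is.na(bc) && !is.na(bu) && bc == bu)
    stop("capped and uncapped fragments co-migrate in band ", bc,
         "; increase cap0_offset resolution or probe placement")
  ic <- if (is.na(bc)) 0 else assay$lane$intensity[match(bc, assay$lane$band)]
  iu <- if (is.na(bu)) 0 else assay$lane$intensity[match(bu, assay$lane$band)]
  if (ic + iu == 0) stop("both candidate bands have zero intensity")
  ic / (ic + iu)
}

#' Schematic lane plot
#'
#' Draws bands as horizontal bars at their relative mobility, darker for
#' higher intensity — a planning sketch, not a densitometric rendering.
#'
#' @param lane A [predict_lane()] result.
#' @param main Plot title.
#' @export
plot_lane <- function(lane, main = "predicted urea-PAGE lane") {
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1), xlab = "",
                 ylab = "relative mobility", xaxt = "n", main = main)
  if (nrow(lane) == 0L) return(invisible(NULL))
  shade <- 1 - 0.8 * lane$intensity / max(lane$intensity)
  for (i in seq_len(nrow(lane))) {
    y <- lane$relative_mobility[i]
    graphics::rect(0.3, y - 0.004, 0.7, y + 0.004,
                   col = grDevices::gray(shade[i]), border = NA)
    graphics::text(0.75, y, sprintf("%.1f nt-eq%s", lane$apparent_length[i],
                                    if (lane$capped[i]) " (cap0)" else ""),
                   adj = 0, cex = 0.8)
  }
  invisible(NULL)
}
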