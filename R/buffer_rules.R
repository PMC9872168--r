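# Empirical integration of in vitro transcription (IVT) and Vaccinia
# capping reaction buffers into one recipe, from per-component statistics
# over published recipes.
#
# The three integration rules:
#   (1) a component essential for one reaction type (present in 100% of
#       that type's recipes) is included even if absent from the other;
#   (2) a component that is non-essential on its side and absent from the
#       other side is excluded;
#   (3) a component occurring in both sides takes the higher of the two
#       medians — unless flagged detrimental to the other reaction, or
#       flagged as having evidence that the lowest amount works as well,
#       in which case the lower value is used.
# Detrimental/lowest-equivalent evidence cannot be inferred from the
# recipe table itself, so those are explicit user flags.

.component_synonyms <- c(
  "tris" = "Tris-HCl", "tris-hcl" = "Tris-HCl", "tris hcl" = "Tris-HCl",
  "trishcl" = "Tris-HCl",
  "mgcl2" = "MgCl2", "magnesium chloride" = "MgCl2",
  "dtt" = "DTT", "dithiothreitol" = "DTT",
  "spermidine" = "Spermidine",
  "ntp" = "NTPs", "ntps" = "NTPs", "rntps" = "NTPs",
  "kcl" = "KCl", "potassium chloride" = "KCl",
  "nacl" = "NaCl", "sodium chloride" = "NaCl",
  "triton x-100" = "Triton X-100", "triton" = "Triton X-100",
  "tween-20" = "Tween-20", "tween 20" = "Tween-20",
  "sam" = "SAM", "s-adenosyl methionine" = "SAM",
  "gtp" = "GTP")

#' Canonicalize buffer component names
#'
#' Case, spacing and common synonyms (Tris/Tris-HCl, DTT/dithiothreitol,
#' ...) are collapsed to one canonical spelling; unknown names pass
#' through verbatim with a warning so that typos surface rather than
#' silently splitting a component's statistics.
#'
#' @param x Character vector of component names.
#' @param extra Optional named character vector of additional synonyms
#'   (`c("hepes" = "HEPES")`), checked before the shipped table.
#' @return Canonical names, same length as `x`.
#' @export
canonical_component <- function(x, extra = NULL) {
  syn <- c(extra, .component_synonyms)
  key <- tolower(trimws(gsub("[[:space:]]+", " ", x)))
  out <- unname(syn[key])
  unknown <- is.na(out) & !x %in% syn
  if (any(unknown))
    warning("unknown component name(s) kept verbatim: ",
            paste(unique(x[unknown]), collapse = ", "))
  ifelse(is.na(out), x, out)
}

#' Read a buffer recipe table
#'
#' Delimited text with header columns `source`, `reaction_type`
#' (`IVT` or `capping`), `component`, `concentration_mM` (at 1x working
#' strength).  Component names are canonicalized on read.
#'
#' @param path Input file.
#' @param sep Field separator (default tab).
#' @param synonyms Extra synonyms for [canonical_component()].
#' @return A data frame, one row per (source, component).
#' @export
read_recipe_table <- function(path, sep = "\t", synonyms = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("source", "reaction_type", "component", "concentration_mM")
  if (!all(need %in% names(df)))
    stop("recipe table must have columns: ", paste(need, collapse = ", "))
  if (!all(df$reaction_type %in% c("IVT", "capping")))
    stop("reaction_type must be 'IVT' or 'capping'")
  if (any(df$concentration_mM <= 0))
    stop("concentrations must be > 0 (absent components are absent rows, ",
         "not zeros)")
  df$component <- canonical_component(df$component, extra = synonyms)
  df
}

#' Per-component statistics over recipes of one reaction type
#'
#' Frequency is the fraction of that type's recipes (sources) containing
#' the component; the median concentration is taken over the recipes
#' that contain it (absence is absence, not zero).  A component is
#' essential iff its frequency is exactly 1.  With an even number of
#' containing recipes the median is the mean of the two central values.
#'
#' @param recipes A [read_recipe_table()] data frame.
#' @param reaction_type `"IVT"` or `"capping"`.
#' @return A `component_stats` data frame: `component`, `reaction_type`,
#'   `n_recipes` (total of the type), `n_with` (containing recipes),
#'   `frequency`, `median_conc`, `essential`.
#' @export
summarize_components <- function(recipes, reaction_type = c("IVT", "capping")) {
  reaction_type <- match.arg(reaction_type)
  sub <- recipes[recipes$reaction_type == reaction_type, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no recipes of type '", reaction_type, "'")
  n_recipes <- length(unique(sub$source))
  out <- do.call(rbind, lapply(split(sub, sub$component), function(g) {
    n_with <- length(unique(g$source))
    data.frame(component = g$component[1], reaction_type = reaction_type,
               n_recipes = n_recipes, n_with = n_with,
               frequency = n_with / n_recipes,
               median_conc = stats::median(g$concentration_mM),
               essential = n_with == n_recipes)
  }))
  rownames(out) <- NULL
  class(out) <- c("component_stats", "data.frame")
  out
}

#' Integrate IVT and capping buffer statistics into one recipe
#'
#' Applies the three integration rules (see the module header) to the
#' two [summarize_components()] tables.  Every input component appears
#' exactly once in the output, included with a rule tag or excluded with
#' `rule2_excluded`; the provenance column records which rule decided
#' each concentration.
#'
#' @param stats_ivt,stats_cap [summarize_components()] results for the
#'   IVT and capping sides.
#' @param flags Named character vector mapping component names to
#'   `"detrimental"` (the higher concentration would harm the other
#'   reaction; use the lower) or `"lowest_equivalent"` (evidence that
#'   the lowest amount works as well; use the lower).  A component
#'   flagged twice is an error.
#' @return An `integrated_recipe`: data frame `components` (`component`,
#'   `concentration_mM` at 1x, `provenance`, `included`) plus
#'   `scale_factor = 1`.
#' @export
integrate_recipes <- function(stats_ivt, stats_cap, flags = character()) {
  stopifnot(inherits(stats_ivt, "data.frame"), inherits(stats_cap, "data.frame"))
  if (length(flags)) {
    if (anyDuplicated(names(flags)))
      stop("component(s) flagged more than once: ",
           paste(unique(names(flags)[duplicated(names(flags))]), collapse = ", "))
    bad <- !flags %in% c("detrimental", "lowest_equivalent", "none")
    if (any(bad)) stop("unknown flag value(s): ",
                       paste(flags[bad], collapse = ", "))
  }
  all_comp <- union(stats_ivt$component, stats_cap$component)
  rows <- lapply(all_comp, function(cc) {
    iv <- stats_ivt[stats_ivt$component == cc, , drop = FALSE]
    cp <- stats_cap[stats_cap$component == cc, , drop = FALSE]
    flag <- if (cc %in% names(flags)) flags[[cc]] else "none"
    if (nrow(iv) && nrow(cp)) {            # occurs in both -> rule 3
      m <- c(iv$median_conc, cp$median_conc)
      if (flag == "lowest_equivalent")
        data.frame(component = cc, concentration_mM = min(m),
                   provenance = "rule3_lowest_equivalent", included = TRUE)
      else if (flag == "detrimental")
        data.frame(component = cc, concentration_mM = min(m),
                   provenance = "rule3_detrimental", included = TRUE)
      else
        data.frame(component = cc, concentration_mM = max(m),
                   provenance = "rule3_max", included = TRUE)
    } else {
      side <- if (nrow(iv)) iv else cp
      if (side$essential)                  # essential on its side -> rule 1
        data.frame(component = cc, concentration_mM = side$median_conc,
                   provenance = "rule1_include_essential", included = TRUE)
      else                                 # non-essential, absent other side
        data.frame(component = cc, concentration_mM = NA_real_,
                   provenance = "rule2_excluded", included = FALSE)
    }
  })
  structure(list(components = do.call(rbind, rows), scale_factor = 1),
            class = "integrated_recipe")
}

#' Scale an integrated recipe to an N-times stock
#'
#' Multiplies every included concentration by `scale` and optionally
#' appends reaction substrates (which are consumables, not buffer
#' chemistry, and therefore bypass the integration rules) with
#' provenance `substrate_added`.
#'
#' @param recipe An [integrate_recipes()] result.
#' @param scale Positive integer stock factor (e.g. 10 for a 10x stock).
#' @param substrates Optional named numeric vector of substrate
#'   concentrations already expressed at the stock scale (e.g.
#'   `c(SAM = 1, GTP = 5)` for a 10x stock).
#' @return An `integrated_recipe` at `scale` times working strength.
#' @export
emit_stock <- function(recipe, scale, substrates = NULL) {
  stopifnot(inherits(recipe, "integrated_recipe"))
  scale <- as.numeric(scale)
  if (length(scale) != 1L || scale < 1 || scale != round(scale))
    stop("scale must be a positive integer")
  comp <- recipe$components
  comp$concentration_mM <- ifelse(comp$included,
                                  comp$concentration_mM * scale, NA_real_)
  if (!is.null(substrates)) {
    stopifnot(!is.null(names(substrates)), all(substrates > 0))
    comp <- rbind(comp, data.frame(component = names(substrates),
                                   concentration_mM = unname(substrates),
                                   provenance = "substrate_added",
                                   included = TRUE))
  }
  structure(list(components = comp,
                 scale_factor = recipe$scale_factor * scale),
            class = "integrated_recipe")
}

#' @export
print.integrated_recipe <- function(x, ...) {
  cat(sprintf("<integrated_recipe> %gx stock\n", x$scale_factor))
  inc <- x$components[x$components$included, , drop = FALSE]
  exc <- x$components[!x$components$included, , drop = FALSE]
  for (i in seq_len(nrow(inc)))
    cat(sprintf("  %-14s %8.3g mM  [%s]\n", inc$component[i],
                inc$concentration_mM[i], inc$provenance[i]))
  if (nrow(exc))
    cat("  excluded (rule 2):", paste(exc$component, collapse = ", "), "\n")
  invisible(x)
}

#' Export an integrated recipe as TSV and/or JSON with provenance
#'
#' @param recipe An [integrate_recipes()] or [emit_stock()] result.
#' @param path_tsv,path_json Optional output paths.
#' @return The component data frame, invisibly.
#' @export
write_recipe <- function(recipe, path_tsv = NULL, path_json = NULL) {
  stopifnot(inherits(recipe, "integrated_recipe"))
  if (!is.null(path_tsv))
    utils::write.table(recipe$components, path_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(list(scale_factor = recipe$scale_factor,
                              components = recipe$components),
                         path_json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  invisible(recipe$components)
}
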