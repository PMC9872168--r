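recipes_path <- system.file("extdata", "buffer_recipes_synthetic.tsv",
                            package = "rnaseprotect")

test_that("component names canonicalize through the synonym table", {
  expect_equal(canonical_component(c("tris", "Tris-HCl", "dithiothreitol",
                                     "MGCL2")),
               c("Tris-HCl", "Tris-HCl", "DTT", "MgCl2"))
  expect_warning(out <- canonical_component(c("DTT", "mystery salt")),
                 "mystery salt")
  expect_equal(out, c("DTT", "mystery salt"))
  expect_equal(canonical_component("hepes", extra = c(hepes = "HEPES")),
               "HEPES")
})

test_that("recipe tables read with validation", {
  rec <- read_recipe_table(recipes_path)
  expect_setequal(unique(rec$reaction_type), c("IVT", "capping"))
  expect_equal(length(unique(rec$source[rec$reaction_type == "IVT"])), 11L)
  # "Tris" rows in the capping sources canonicalize to Tris-HCl
  expect_true(all(rec$component[rec$reaction_type == "capping" &
                                  grepl("Tris", rec$component)] == "Tris-HCl"))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\treaction_type\tcomponent\tconcentration_mM",
               "a\tIVT\tDTT\t0"), bad)
  expect_error(read_recipe_table(bad), "> 0")
  writeLines(c("source\treaction_type\tcomponent\tconcentration_mM",
               "a\tPCR\tDTT\t1"), bad)
  expect_error(read_recipe_table(bad), "IVT")
})

test_that("summaries use containing-recipe medians and 100%-frequency essentiality", {
  stats <- summarize_components(read_recipe_table(recipes_path), "IVT")
  row <- function(cc) stats[stats$component == cc, ]
  expect_equal(row("Tris-HCl")$median_conc, 41.1)
  expect_equal(row("MgCl2")$median_conc, 9.9)
  expect_equal(row("DTT")$median_conc, 7.4)
  expect_equal(row("Spermidine")$median_conc, 1.8)
  expect_equal(row("NTPs")$median_conc, 2.0)
  expect_true(all(vapply(c("Tris-HCl", "MgCl2", "DTT", "Spermidine", "NTPs"),
                         function(cc) row(cc)$essential, logical(1))))
  expect_equal(row("KCl")$frequency, 1 / 11, tolerance = 1e-12)
  expect_false(row("KCl")$essential)
  expect_false(row("NaCl")$essential)
  expect_error(summarize_components(
    read_recipe_table(recipes_path)[1:5, ], "capping"), "no recipes")
})

test_that("medians match a sort-based oracle, even counts averaged", {
  set.seed(44)
  for (rep in 1:15) {
    k <- sample(2:12, 1)
    tab <- data.frame(source = paste0("s", 1:k), reaction_type = "IVT",
                      component = "DTT",
                      concentration_mM = round(stats::runif(k, 0.1, 50), 2))
    st <- summarize_components(tab, "IVT")
    v <- sort(tab$concentration_mM)
    med <- if (k %% 2 == 1) v[(k + 1) / 2] else mean(v[k / 2 + 0:1])
    expect_equal(st$median_conc, med)
  }
  expect_equal(summarize_components(
    data.frame(source = c("a", "b", "c"), reaction_type = "IVT",
               component = "X", concentration_mM = c(1, 2, 100)),
    "IVT")$median_conc, 2)
})

test_that("integration applies rules 1-3 with exact provenance", {
  rec <- read_recipe_table(recipes_path)
  ivt <- summarize_components(rec, "IVT")
  cap <- summarize_components(rec, "capping")
  ir <- integrate_recipes(ivt, cap, flags = c(DTT = "lowest_equivalent"))
  comp <- ir$components
  row <- function(cc) comp[comp$component == cc, ]
  # rule 3 max: shared components take the higher median
  expect_equal(row("Tris-HCl")$concentration_mM, 50)
  expect_equal(row("Tris-HCl")$provenance, "rule3_max")
  expect_equal(row("MgCl2")$concentration_mM, 9.9)
  expect_equal(row("MgCl2")$provenance, "rule3_max")
  expect_equal(row("KCl")$concentration_mM, 5)
  # rule 3 lowest-equivalent flag: take the lower median
  expect_equal(row("DTT")$concentration_mM, 1.0)
  expect_equal(row("DTT")$provenance, "rule3_lowest_equivalent")
  # rule 1: essential on one side, absent from the other
  expect_equal(row("Spermidine")$concentration_mM, 1.8)
  expect_equal(row("Spermidine")$provenance, "rule1_include_essential")
  expect_equal(row("NTPs")$concentration_mM, 2.0)
  expect_equal(row("NTPs")$provenance, "rule1_include_essential")
  # rule 2: non-essential and absent from the other side
  for (cc in c("NaCl", "Triton X-100", "Tween-20")) {
    expect_equal(row(cc)$provenance, "rule2_excluded")
    expect_false(row(cc)$included)
  }
  # every input component appears exactly once
  expect_setequal(comp$component, union(ivt$component, cap$component))
  expect_false(anyDuplicated(comp$component) > 0)
})

test_that("flag handling: detrimental takes the lower value, double flags error", {
  mk <- function(comp, med, ess = TRUE, type = "IVT")
    data.frame(component = comp, reaction_type = type, n_recipes = 4L,
               n_with = 4L, frequency = 1, median_conc = med,
               essential = ess)
  ir <- integrate_recipes(mk("NaCl", 100), mk("NaCl", 10, type = "capping"),
                          flags = c(NaCl = "detrimental"))
  expect_equal(ir$components$concentration_mM, 10)
  expect_equal(ir$components$provenance, "rule3_detrimental")
  expect_error(integrate_recipes(mk("X", 1), mk("X", 2, type = "capping"),
                                 flags = c(X = "detrimental",
                                           X = "lowest_equivalent")),
               "more than once")
  expect_error(integrate_recipes(mk("X", 1), mk("X", 2, type = "capping"),
                                 flags = c(X = "harmful")), "unknown flag")
})

test_that("integration is idempotent on its own output", {
  rec <- read_recipe_table(recipes_path)
  ir <- integrate_recipes(summarize_components(rec, "IVT"),
                          summarize_components(rec, "capping"),
                          flags = c(DTT = "lowest_equivalent"))
  inc <- ir$components[ir$components$included, ]
  as_stats <- function(type) data.frame(
    component = inc$component, reaction_type = type,
    n_recipes = 1L, n_with = 1L, frequency = 1,
    median_conc = inc$concentration_mM, essential = TRUE)
  again <- integrate_recipes(as_stats("IVT"), as_stats("capping"))
  expect_equal(again$components$component, inc$component)
  expect_equal(again$components$concentration_mM, inc$concentration_mM)
})

test_that("stock emission scales and appends substrates with provenance", {
  rec <- read_recipe_table(recipes_path)
  ir <- integrate_recipes(summarize_components(rec, "IVT"),
                          summarize_components(rec, "capping"),
                          flags = c(DTT = "lowest_equivalent"))
  stock <- emit_stock(ir, 10, substrates = c(SAM = 1, GTP = 5))
  comp <- stock$components
  row <- function(cc) comp[comp$component == cc, ]
  expect_equal(row("Tris-HCl")$concentration_mM, 500)
  expect_equal(row("MgCl2")$concentration_mM, 99)
  expect_equal(row("DTT")$concentration_mM, 10)
  expect_equal(row("Spermidine")$concentration_mM, 18)
  expect_equal(row("NTPs")$concentration_mM, 20)
  expect_equal(row("SAM")$provenance, "substrate_added")
  expect_equal(row("GTP")$concentration_mM, 5)
  expect_equal(stock$scale_factor, 10)
  expect_equal(emit_stock(ir, 1)$components$concentration_mM,
               ir$components$concentration_mM)
  expect_error(emit_stock(ir, 2.5), "integer")
  # export carries the provenance column
  tsv <- withr::local_tempfile(fileext = ".tsv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_recipe(stock, path_tsv = tsv, path_json = jsn)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_true("provenance" %in% names(back))
  expect_equal(jsonlite::read_json(jsn)$scale_factor, 10)
})
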