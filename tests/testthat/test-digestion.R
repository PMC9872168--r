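test_that("enzyme presets carry the textbook specificities", {
  expect_setequal(rnase_a()$recognition, c("C", "U"))
  expect_equal(rnase_t1()$recognition, "G")
  expect_equal(rnase_a()$product_5prime, "hydroxyl")
  expect_equal(rnase_t1(product_3prime = "cyclic_phosphate")$product_3prime,
               "cyclic_phosphate")
  expect_error(enzyme_spec("x", "B"), "subset")
})

test_that("unprotected digestion cleaves after every recognition base", {
  fa <- digest_rna(nucleic_seq("x", "ACGAU"), enzymes = list(rnase_a()))
  expect_equal(fa$sequence, c("AC", "GAU"))
  ft <- digest_rna(nucleic_seq("x", "GGAUG"), enzymes = list(rnase_t1()))
  expect_equal(ft$sequence, c("G", "G", "AUG"))
  # empty enzyme list: intact parent
  f0 <- digest_rna(nucleic_seq("x", "ACGAU"), enzymes = list())
  expect_equal(f0$sequence, "ACGAU")
  expect_equal(f0$five_prime, "triphosphate")
})

test_that("protection shields the hybrid; edge conventions differ by design", {
  x <- nucleic_seq("x", "ACGUACGUAC")
  pm <- manual_pmap(x, data.frame(start = 0L, end = 4L))
  both <- list(rnase_a(), rnase_t1())
  fp <- digest_rna(x, pm, both, edge_rule = "edge_permissive")
  expect_equal(fp$sequence, c("ACGU", "AC", "G", "U", "AC"))
  expect_equal(fp$length[1], 4L)               # fragment length = probe length
  ff <- digest_rna(x, pm, both, edge_rule = "free_base_required")
  expect_equal(ff$sequence[1], "ACGUAC")       # runs one cut further 3'
  expect_true(all(fp$protected_overlap[1] == 4L))
})

test_that("fragment end chemistries follow the cut provenance", {
  x <- nucleic_seq("x", "GGAUACGA", five_prime = "cap0",
                   three_prime = "phosphate")
  fr <- digest_rna(x, enzymes = list(rnase_t1(),
                                     rnase_a(product_3prime = "cyclic_phosphate")))
  # cuts: G|G|AU(A)... first-listed enzyme claims G cuts
  expect_equal(fr$five_prime[1], "cap0")
  expect_true(fr$capped[1])
  expect_true(all(fr$five_prime[-1] == "hydroxyl"))
  expect_false(any(fr$capped[-1]))
  expect_equal(fr$three_prime[nrow(fr)], "phosphate")  # parent 3' inherited
  g_cut <- which(substr(fr$sequence, nchar(fr$sequence),
                        nchar(fr$sequence)) == "G" & seq_len(nrow(fr)) < nrow(fr))
  expect_true(all(fr$three_prime[g_cut] == "phosphate"))
  u_cut <- which(substr(fr$sequence, nchar(fr$sequence),
                        nchar(fr$sequence)) == "U")
  expect_true(all(fr$three_prime[u_cut] == "cyclic_phosphate"))
})

test_that("build_protection_map merges overlaps and voids under low salt", {
  set.seed(8)
  target <- nucleic_seq("t", random_rna(40))
  p1 <- suppressWarnings(design_region_probe(target, 0, 20))
  p2 <- suppressWarnings(design_region_probe(target, 10, 30))
  pm <- build_protection_map(target, list(p1, p2))
  expect_equal(pm$intervals, data.frame(start = 0L, end = 30L))
  low <- build_protection_map(target, list(p1, p2), salt_mode = "low_salt")
  expect_equal(nrow(low$intervals), 0L)
  expect_equal(low$probes$n_sites, c(1L, 1L))  # bindings still reported
  # a non-binding probe is reported, not fatal
  nb <- probe("nb", paste(rep("A", 20), collapse = ""))
  pm2 <- build_protection_map(target, list(p1, nb))
  expect_equal(pm2$probes$n_sites[2], 0L)
  expect_equal(pm2$intervals, data.frame(start = 0L, end = 20L))
})

test_that("digestion matches the bond-marking oracle on random instances", {
  set.seed(33)
  enzymes_pool <- list(list(rnase_a()), list(rnase_t1()),
                       list(rnase_a(), rnase_t1()))
  for (rep in 1:60) {
    n <- sample(2:300, 1)
    x <- nucleic_seq("r", random_rna(n))
    iv <- random_intervals(n)
    pm <- manual_pmap(x, iv)
    ez <- enzymes_pool[[sample(3, 1)]]
    rule <- sample(c("edge_permissive", "free_base_required"), 1)
    got <- digest_rna(x, pm, ez, edge_rule = rule)
    expect_equal(got$sequence, oracle_digest(x$residues, iv, ez, rule))
    # conservation: concatenation reproduces the parent, intervals abut
    expect_equal(paste(got$sequence, collapse = ""), x$residues)
    expect_equal(got$start[1], 0L)
    expect_equal(got$end[nrow(got)], n)
    if (nrow(got) > 1)
      expect_equal(got$start[-1], got$end[-nrow(got)])
  }
})

test_that("each protected interval stays within a single fragment", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(30:400, 1)
    x <- nucleic_seq("r", random_rna(n))
    iv <- random_intervals(n)
    fr <- digest_rna(x, manual_pmap(x, iv), list(rnase_a(), rnase_t1()))
    for (k in seq_len(nrow(iv))) {
      host <- fr$start <= iv$start[k] & fr$end >= iv$end[k]
      expect_true(any(host))
    }
  }
})

test_that("the A+T1 mixture leaves C/U/G only at fragment 3' ends", {
  set.seed(6)
  for (rep in 1:20) {
    fr <- digest_rna(nucleic_seq("r", random_rna(sample(10:500, 1))),
                     enzymes = list(rnase_a(), rnase_t1()))
    interior <- substr(fr$sequence, 1, nchar(fr$sequence) - 1L)
    expect_false(any(grepl("[CUG]", interior)))
  }
})

test_that("adding an enzyme never decreases the fragment count", {
  set.seed(7)
  for (rep in 1:25) {
    x <- nucleic_seq("r", random_rna(sample(5:400, 1)))
    iv <- random_intervals(length(x))
    pm <- manual_pmap(x, iv)
    n_a <- nrow(digest_rna(x, pm, list(rnase_a())))
    n_t <- nrow(digest_rna(x, pm, list(rnase_t1())))
    n_at <- nrow(digest_rna(x, pm, list(rnase_a(), rnase_t1())))
    expect_gte(n_at, n_a)
    expect_gte(n_at, n_t)
  }
})

test_that("detectable_fragments applies the length threshold", {
  fr <- data.frame(length = c(24L, 3L, 2L))
  expect_equal(detectable_fragments(fr)$length, 24L)
  expect_equal(detectable_fragments(fr, min_len = 1L), fr)
  expect_equal(nrow(detectable_fragments(fr, min_len = 30L)), 0L)
})

test_that("fragments export to TSV and FASTA and read back", {
  fr <- digest_rna(nucleic_seq("x", "ACGAUGGAUC"), enzymes = list(rnase_a()))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fragments(fr, tsv)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(back$sequence, fr$sequence)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fragments_fasta(fr, fa)
  expect_equal(vapply(read_fasta(fa, kind = "RNA"), `[[`, "", "residues"),
               fr$sequence)
})
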