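test_that("filter cascade applies the documented rules in order", {
  expect_identical(filter_small_molecule("CCO")$reason, "too_short")
  expect_identical(filter_small_molecule("CCCCCCCCC[Si](=O)[Si](=O)CCCC")$reason,
                   "silicon_oxide_polymer")
  expect_identical(filter_small_molecule("CCCCCCCCCC[Si][Si]CCC")$reason,
                   "silicon_chain")
  d <- filter_small_molecule("Cl.NCCCCCCCCCCCCCCCCCC(=O)O")
  expect_true(d$kept)
  expect_identical(d$emitted,
                   unname(smi_canonicalize("NCCCCCCCCCCCCCCCCCC(=O)O")[1]))
  d2 <- filter_small_molecule("NCCCCCCCCCCCC(=O)O.OCCCCCCCCCCCCCCCCCCCC")
  expect_true(d2$kept)
  expect_length(d2$emitted, 2L)
  # the length threshold applies to the raw string, before stripping:
  # a 19-character salt-bearing record dies on length, not on stripping
  expect_identical(filter_small_molecule("Cl.NCCCCCCCCC(=O)O")$reason,
                   "too_short")
})

test_that("cascade order is pinned: a short string with silicon dies on length", {
  expect_identical(filter_small_molecule("[Si][Si]")$reason, "too_short")
})

test_that("curation fixture reproduces hand-computed survivors and histogram", {
  fx <- gen_curation_fixture()
  reasons <- vapply(fx$records, function(r) filter_small_molecule(r)$reason,
                    character(1), USE.NAMES = FALSE)
  expect_identical(reasons, fx$expected_reasons)
  res <- curate_small_molecules(fx$records)
  expect_identical(res$stats[names(fx$expected_stats)], fx$expected_stats)
  expected <- sort(unname(smi_canonicalize(fx$expected_survivors)))
  expect_identical(sort(res$kept), expected)
  # survivors are their own canonical form
  expect_identical(sort(unname(smi_canonicalize(res$kept)[seq_along(res$kept)])),
                   sort(res$kept))
})

test_that("duplicates and the empty stream are counted correctly", {
  rec <- rep("CCCCCCCCCCCCCCCCCCCCO", 2L)
  res <- curate_small_molecules(rec)
  expect_length(res$kept, 1L)
  expect_identical(unname(res$stats[["duplicate"]]), 1L)
  empty <- curate_small_molecules(character(0))
  expect_length(empty$kept, 0L)
  expect_true(all(empty$stats == 0L))
})

test_that("peptide confidence filter uses strict > 0.7 and length <= 100", {
  rec <- data.frame(
    sequence = c(strrep("A", 50), strrep("A", 101), strrep("A", 50),
                 strrep("A", 100), strrep("A", 50)),
    pTM = c(0.8, 0.9, 0.7, 0.71, 0.9),
    pLDDT = c(0.9, 0.9, 0.9, 0.71, 0.7))
  expect_identical(filter_peptide_records(rec),
                   c(TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("cluster representative maximizes pTM x pLDDT with first-wins ties", {
  m <- data.frame(id = c("a", "b"), pTM = c(0.8, 0.95), pLDDT = c(0.9, 0.71))
  expect_identical(select_representative(m)$id, "a")   # 0.72 > 0.6745
  single <- data.frame(id = "z", pTM = 0.5, pLDDT = 0.5)
  expect_identical(select_representative(single)$id, "z")
  tie <- data.frame(id = c("p", "q"), pTM = c(0.8, 0.9), pLDDT = c(0.9, 0.8))
  expect_identical(select_representative(tie)$id, "p")
  expect_error(select_representative(data.frame()), class = "smiclm_badarg")
})

test_that("epoch sampling upsamples lipids, downsamples molecules, is seeded", {
  pools <- list(lipid = paste0("L", 1:5),
                peptide = paste0("P", 1:7),
                small_molecule = paste0("S", 1:100))
  s1 <- build_epoch_sample(pools, sizes = c(small_molecule = 40L),
                           lipid_upsample = 5L, seed = 4L)
  expect_identical(unname(s1$composition[["lipid"]]), 25L)
  expect_identical(unname(s1$composition[["peptide"]]), 7L)
  expect_identical(unname(s1$composition[["small_molecule"]]), 40L)
  expect_identical(sum(s1$composition), nrow(s1$entries))
  s2 <- build_epoch_sample(pools, sizes = c(small_molecule = 40L),
                           lipid_upsample = 5L, seed = 4L)
  expect_identical(s1$entries, s2$entries)
  s3 <- build_epoch_sample(pools, sizes = c(small_molecule = 40L),
                           lipid_upsample = 5L, seed = 5L)
  expect_false(identical(s1$entries$smiles, s3$entries$smiles))
  sm3 <- s3$entries$smiles[s3$entries$source == "small_molecule"]
  expect_length(unique(sm3), 40L)   # sampling without replacement
  expect_error(build_epoch_sample(pools, sizes = c(small_molecule = 101L)),
               class = "smiclm_badarg")
})

test_that("peptide score TSV and FASTA readers work together", {
  skip_if_not_installed("Biostrings")
  d <- tempfile(); dir.create(d)
  writeLines(c(">p1 desc", "ACDEF", ">p2", "GGKKL"),
             file.path(d, "p.fasta"))
  utils::write.table(data.frame(id = c("p1", "p2"), pTM = c(0.9, 0.5),
                                pLDDT = c(0.95, 0.9), cluster_id = c(1L, 1L)),
                     file.path(d, "s.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  fa <- read_peptide_fasta(file.path(d, "p.fasta"))
  expect_identical(fa$id, c("p1", "p2"))
  expect_identical(fa$sequence, c("ACDEF", "GGKKL"))
  sc <- read_peptide_scores(file.path(d, "s.tsv"))
  merged <- merge(fa, sc, by = "id")
  expect_identical(filter_peptide_records(merged), c(TRUE, FALSE))
})
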