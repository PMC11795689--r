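# Cohort orchestration: generate, audit against truth labels, summarize,
# compare, determinism.

small_truth <- function(seed = 4) {
  default_truth_config(seed = seed, n_clean = 2, n_stack = 2,
                       n_stack_lowconf = 1, n_comp = 1, n_clash = 1,
                       n_hyd = 1, n_helix = 2, n_coil = 2,
                       unit_lengths = c(8, 12, 16), n_rungs = 6)
}

test_that("cohort generation writes the FASTA and manifest", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "cohort.fasta"); mf <- file.path(dir, "manifest.tsv")
  out <- cohort_generate(seed = 1, out_fasta = fa, out_manifest = mf)
  expect_equal(nrow(out$manifest), 78)
  expect_equal(sum(grepl("^>", readLines(fa))), 78)
  man <- utils::read.table(mf, header = TRUE, sep = "\t")
  expect_equal(nrow(man), 78)
  prem <- cohort_generate(seed = 1, design = "preliminary")
  expect_equal(nrow(prem$manifest), 31)   # expanded random entries
})

test_that("auditing a forged cohort recovers the ground truth", {
  dir <- withr::local_tempdir()
  out <- forge_truth_cohort(small_truth(), outdir = dir)
  rep <- cohort_audit(dir, out$manifest)
  expect_equal(nrow(rep), nrow(out$manifest))
  truth <- out$truth
  ids <- vapply(truth, `[[`, "", "id")
  for (k in seq_len(nrow(rep))) {
    t <- truth[[match(rep$seq_id[k], ids)]]
    expect_identical(rep$fold_class[k], t$fold_class)
    expect_identical(rep$problematic[k], t$problematic)
  }
  # problematic fraction equals the injected fraction exactly
  expect_equal(sum(rep$problematic),
               sum(vapply(truth, `[[`, TRUE, "problematic")))
})

test_that("audit reports are byte-identical across repeated runs", {
  dir <- withr::local_tempdir()
  out <- forge_truth_cohort(small_truth()[1:4], outdir = dir)
  f1 <- file.path(dir, "r1.tsv"); f2 <- file.path(dir, "r2.tsv")
  cohort_audit(dir, out$manifest, out_tsv = f1)
  cohort_audit(dir, out$manifest, out_tsv = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("unmatched structure files are warned about and skipped", {
  dir <- withr::local_tempdir()
  out <- forge_truth_cohort(small_truth()[1:2], outdir = dir)
  orphan <- build_helix("AEKQLAEKQL")
  write_structure(orphan, file.path(dir, "orphan.pdb"))
  expect_warning(rep <- cohort_audit(dir, out$manifest), "orphan")
  expect_equal(nrow(rep), 2)
  expect_error(cohort_audit(dir, out$manifest, hard_fail = TRUE), "orphan")
  # empty directory: empty report, no error
  empty <- withr::local_tempdir()
  expect_equal(nrow(cohort_audit(empty, out$manifest)), 0)
})

test_that("cohort summaries report fractions the way the protocol does", {
  expect_identical(format_fraction(32, 78), "32 of 78 (41 %)")
  rep <- data.frame(
    fold_class = c(rep("beta_solenoid", 3), "alpha_helical", "none"),
    mean_plddt = c(95, 85, 65, 45, 72),
    categorical_fail = c(TRUE, FALSE, FALSE, FALSE, TRUE),
    problematic = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  s <- cohort_summarize(rep)
  expect_equal(s$n, 5)
  expect_equal(unname(s$fold_counts["beta_solenoid"]), 3L)
  expect_equal(sum(s$plddt_bands), nrow(rep))   # bands partition the cohort
  expect_equal(unname(s$plddt_bands), c(1L, 2L, 1L, 1L))
  expect_equal(s$n_problematic, 2)
  expect_identical(s$problematic, "2 of 5 (40 %)")
  e <- cohort_summarize(data.frame())
  expect_equal(e$n, 0)
  expect_error(cohort_summarize(data.frame(x = 1)), "malformed")
})

test_that("cross-directory comparison finds self-identity and misses", {
  dir <- withr::local_tempdir()
  out <- forge_truth_cohort(small_truth()[c(1, 9)], outdir = dir)
  cmp <- cohort_compare(dir, c(self = dir), out$manifest)
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$tm >= 1 - 1e-6))
  expect_true(all(cmp$rmsd <= 1e-6))
  expect_error(cohort_compare(dir, c(x = file.path(dir, "nope")),
                              out$manifest), "missing directory")
})
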