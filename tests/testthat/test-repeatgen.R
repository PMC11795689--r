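# Sequence-design protocol: pools, units, tandems, cohorts, mutants,
# propensity means, repeat perfection, FASTA.

test_that("propensity pools are disjoint and cover the 20 residues", {
  p <- amino_pools()
  expect_length(p$beta, 7)
  expect_length(p$alpha, 7)
  expect_length(p$neutral, 6)
  expect_length(intersect(p$beta, p$alpha), 0)
  expect_length(intersect(p$beta, p$neutral), 0)
  expect_length(intersect(p$alpha, p$neutral), 0)
  expect_setequal(unlist(p), strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
})

test_that("make_unit draws from the scheme pools, deterministically", {
  u <- make_unit(4, "beta", seed = 7)
  expect_equal(nchar(u), 4)
  expect_true(all(strsplit(u, "")[[1]] %in% c("C", "F", "I", "T", "V", "W", "Y")))
  expect_identical(make_unit(6, "all", seed = 3), make_unit(6, "all", seed = 3))
  expect_identical(make_unit(50, "alpha+neutral", seed = 1),
                   make_unit(50, "alpha+neutral", seed = 1))
  ab <- strsplit(make_unit(200, "alpha+beta", seed = 2), "")[[1]]
  expect_true(all(ab %in% c(amino_pools()$alpha, amino_pools()$beta)))
  expect_error(make_unit(0, "beta", seed = 7), "positive")
  expect_error(make_unit(5, "gamma", seed = 7))
})

test_that("make_unit sampling is uniform over the full pool", {
  u <- make_unit(100000, "all", seed = 42)
  counts <- table(factor(strsplit(u, "")[[1]],
                         levels = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("tandem concatenates the unit exactly n_copies times", {
  s <- tandem("QTSTVIGTIASTETSSSTGI", 10)
  expect_equal(nchar(s$full), 200)
  expect_identical(s$full, strrep("QTSTVIGTIASTETSSSTGI", 10))
  expect_identical(tandem("A", 1)$full, "A")
  expect_identical(tandem("AB", 3)$full, "ABABAB")
  expect_error(tandem("", 3), "non-empty")
  expect_error(tandem("AB", 0), ">= 1")
})

test_that("expanded cohort covers the length x scheme grid", {
  coh <- generate_expanded_cohort(seed = 1)
  expect_length(coh, 78)
  expect_true(all(vapply(coh, function(s) nchar(s$full) ==
                           10 * nchar(s$unit), logical(1))))
  one <- generate_expanded_cohort(lengths = 20, schemes = "beta", seed = 1)
  expect_length(one, 1)
  expect_equal(nchar(one[[1]]$full), 200)
  expect_length(generate_expanded_cohort(lengths = integer(0), seed = 1), 0)
  # property: count = |lengths| x |schemes| for arbitrary grids
  for (case in list(list(5:9, c("beta", "all")),
                    list(c(7, 13), c("alpha", "neutral", "beta+neutral")),
                    list(12, "alpha+beta"))) {
    expect_length(generate_expanded_cohort(case[[1]], case[[2]], seed = 2),
                  length(case[[1]]) * length(case[[2]]))
  }
  # reproducibility from the cohort seed
  expect_identical(
    vapply(generate_expanded_cohort(seed = 5), `[[`, "", "full"),
    vapply(generate_expanded_cohort(seed = 5), `[[`, "", "full"))
})

test_that("preliminary design expands to 31 random + 19 mutant entries", {
  d <- enumerate_preliminary_design(seed = 1)
  expect_equal(nrow(d), 50)
  expect_equal(sum(d$kind == "random"), 31)
  expect_equal(sum(d$kind == "mutant"), 19)
  counts <- table(d$scheme[d$kind == "random"])
  expect_equal(unname(counts[c("alpha", "beta", "neutral")]),
               as.integer(c(2, 3, 2)), ignore_attr = TRUE)
  expect_equal(unname(counts[c("alpha+neutral", "beta+neutral",
                               "alpha+beta")]),
               as.integer(c(3, 3, 3)), ignore_attr = TRUE)
  expect_equal(unname(counts["all"]), 15L, ignore_attr = TRUE)
  seqs <- attr(d, "sequences")
  expect_length(seqs, 31)
  expect_true(all(vapply(seqs, function(s) nchar(s$full), 1L) == 200))
})

test_that("alanine mutants replace one unit position in every rung", {
  s <- tandem("KCGF", 3)
  m <- alanine_mutant(s, 0)
  expect_identical(m$unit, "ACGF")
  expect_identical(m$full, strrep("ACGF", 3))
  expect_equal(nchar(m$full), nchar(s$full))
  expect_equal(m$n_copies, s$n_copies)
  expect_error(alanine_mutant(s, 1), "'C'")
  expect_error(alanine_mutant(s, 4), "unit_position")
})

test_that("propensity means match a per-residue summation oracle", {
  tab <- default_propensity_table()
  pa <- propensity_means(tandem("A", 5))
  expect_equal(unname(pa["mean_alpha"]), 1.42)
  pb <- propensity_means("AV")
  expect_equal(unname(pb["mean_beta"]), (0.83 + 1.70) / 2)
  coh <- generate_expanded_cohort(seed = 3)
  for (s in coh) {
    res <- strsplit(s$full, "")[[1]]
    oracle <- c(sum(tab$p_alpha[match(res, tab$res)]) / length(res),
                sum(tab$p_beta[match(res, tab$res)]) / length(res))
    expect_equal(unname(propensity_means(s)), oracle, tolerance = 1e-12)
  }
  # composition invariance: permuting the unit leaves the means unchanged
  s <- coh[[40]]
  perm <- paste(sample(strsplit(s$unit, "")[[1]]), collapse = "")
  expect_equal(propensity_means(tandem(perm, 10)), propensity_means(s))
  expect_error(propensity_means("AXB"), "X")
})

test_that("repeat-score normalization and the near-perfect threshold", {
  expect_equal(normalize_repeat_score(140, 20), 7.0)
  expect_false(is_near_perfect(normalize_repeat_score(140, 20)))
  expect_equal(normalize_repeat_score(150, 20), 7.5)
  expect_true(is_near_perfect(normalize_repeat_score(150, 20)))
  expect_equal(normalize_repeat_score(0, 5), 0)
  expect_error(normalize_repeat_score(10, 0), ">= 1")
})

test_that("repeat perfection is the mean column identity over copies", {
  expect_equal(repeat_perfection(strrep("QTSTVIGTIA", 10), 10), 1.0)
  expect_equal(repeat_perfection("ABCDWXYZ", 4), 0.5)
  set.seed(8)
  for (i in 1:10) {
    L <- sample(3:12, 1); k <- sample(2:6, 1)
    full <- paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                         L * k, replace = TRUE), collapse = "")
    expect_equal(repeat_perfection(full, L), brute_repeat_perfection(full, L))
  }
  expect_error(repeat_perfection("ABCDE", 4), "two copies")
})

test_that("FASTA output roundtrips the cohort", {
  coh <- generate_expanded_cohort(seed = 1)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(coh, f)
  back <- read_fasta_cohort(f)
  expect_length(back, 78)
  expect_identical(vapply(back, `[[`, "", "full"),
                   vapply(coh, `[[`, "", "full"), ignore_attr = TRUE)
  expect_identical(vapply(back, `[[`, "", "unit"),
                   vapply(coh, `[[`, "", "unit"), ignore_attr = TRUE)
  # 60-column wrapping
  expect_lte(max(nchar(readLines(f))), 80)
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(list(), f2)
  expect_equal(file.size(f2), 0)
})

test_that("cohort manifest carries design metadata and scores", {
  coh <- generate_expanded_cohort(lengths = c(5, 20), schemes = "beta",
                                  seed = 2)
  man <- cohort_manifest(coh)
  expect_equal(nrow(man), 2)
  expect_equal(man$repeat_perfection, c(1, 1))
  expect_true(all(c("seq_id", "unit", "unit_length", "n_copies", "scheme",
                    "seed", "mean_alpha", "mean_beta",
                    "repeat_perfection") %in% names(man)))
  expect_equal(nrow(cohort_manifest(list())), 0)
})
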