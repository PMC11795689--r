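# Plausibility diagnostics: secondary structure, environment classes, 3D/1D
# profile, charged stacks, exposed hydrophobics, clashes, fold classes,
# disorder, and the problematic rule.

test_that("secondary structure: helix, solenoid strands, degenerate chains", {
  h <- build_helix(strrep("AEKQLAEKQL", 10))
  expect_gte(mean(assign_ss(h) == "H"), 0.9)
  L <- 12
  m <- build_solenoid(solenoid_spec(tandem(clean_unit(L, 4), 8)))
  ss <- assign_ss(m)
  expect_gt(mean(ss == "E"), 0.5)
  tiny <- structure_model(data.frame(
    resno = 1:3, res1 = "A", name = "CA", element = "C",
    x = c(0, 3.8, 7.6), y = 0, z = 0, b = 0))
  expect_equal(assign_ss(tiny), rep("C", 3))
})

test_that("environment classes cover the 6 x 3 grid", {
  expect_identical(assign_environment(0.9, 0.5, "H"), "E_helix")
  expect_identical(assign_environment(0.02, 0.1, "E"), "B1_sheet")
  grid <- expand.grid(rel = c(0.9, 0.3, 0.3, 0.02, 0.02, 0.02),
                      pol = c(0.1, 0.5, 0.7, 0.1, 0.5, 0.7),
                      ss = c("H", "E", "C"), stringsAsFactors = FALSE)
  cls <- mapply(assign_environment, grid$rel, grid$pol, grid$ss)
  expect_length(unique(cls), 18)
  expect_setequal(unique(cls), environment_classes())
  expect_error(assign_environment(-0.1, 0.5, "H"), "rel_sasa")
  expect_error(assign_environment(0.5, 1.2, "H"), "polar_frac")
  expect_error(assign_environment(0.5, 0.5, "Q"), "unknown")
})

test_that("the default 3D/1D table is complete and favours matched environments", {
  tab <- default_3d1d_table()
  expect_equal(dim(tab), c(20, 19))
  expect_false(any(is.na(tab[, -1])))
  # buried charge is penalized; matched hydrophobic core rewarded
  expect_lt(tab[tab$res == "E", "B1_sheet"], -0.5)
  expect_gt(tab[tab$res == "V", "B1_sheet"], 0.3)
  expect_lt(tab[tab$res == "V", "E_sheet"], 0)
  # TSV round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_3d1d_table(tab, f)
  expect_equal(read_3d1d_table(f), tab)
})

test_that("3D/1D profile smoothing, mean and the 80%/0.1 rule", {
  m <- build_solenoid(solenoid_spec(tandem(clean_unit(10, 9), 4)))
  p1 <- profile_3d1d(m, raw_scores = rep(0.2, 40))
  expect_equal(p1$mean_3d1d, 0.2)
  expect_false(p1$categorical_fail)
  p2 <- profile_3d1d(m, raw_scores = rep(-0.1, 40))
  expect_true(p2$categorical_fail)
  expect_error(profile_3d1d(m, window = 4), "odd")
  expect_error(profile_3d1d(m, window = 0), "odd")
  # smoothing equals the brute-force moving average
  set.seed(13)
  for (w in c(5, 21)) {
    raw <- stats::rnorm(40)
    p <- profile_3d1d(m, raw_scores = raw, window = w)
    expect_equal(p$smoothed, brute_moving_average(raw, w), tolerance = 1e-12)
    expect_equal(p$mean_3d1d, mean(brute_moving_average(raw, w)))
  }
  # exactly 80% passing is not a categorical fail; below 80% is
  raw <- c(rep(0.5, 32), rep(-1, 8))   # smoothed with window 1
  expect_false(profile_3d1d(m, raw_scores = raw, window = 1)$categorical_fail)
  raw2 <- c(rep(0.5, 31), rep(-1, 9))
  expect_true(profile_3d1d(m, raw_scores = raw2, window = 1)$categorical_fail)
  # threshold consistency: raising the cutoff never turns fail into pass
  fail_at <- function(t) profile_3d1d(m, raw_scores = raw2, window = 1,
                                      score_min = t)$categorical_fail
  expect_true(all(vapply(seq(0.1, 0.6, by = 0.1), fail_at, logical(1))))
})

test_that("3D/1D mean is invariant under residue renumbering", {
  m <- build_solenoid(solenoid_spec(tandem(clean_unit(8, 2), 5)))
  m2 <- m
  m2$atoms$resno <- m2$atoms$resno + 100L
  p1 <- profile_3d1d(m); p2 <- profile_3d1d(m2)
  expect_equal(p1$mean_3d1d, p2$mean_3d1d)
  expect_equal(p1$raw, p2$raw)
})

test_that("charged stacks: detection, membership, compensation", {
  s <- tandem(clean_unit(12, 6), 10)
  m <- build_solenoid(solenoid_spec(s, injections = list(
    feature_injection("charged_stack", 4, "E"))))
  st <- detect_charged_stacks(m, 12)
  expect_length(st, 1)
  expect_equal(st[[1]]$unit_position, 4)
  expect_length(st[[1]]$members, 10)
  expect_identical(st[[1]]$sign, "negative")
  expect_false(st[[1]]$compensated)
  expect_lte(st[[1]]$min_member_dist, 7.0)
  mc <- build_solenoid(solenoid_spec(s, injections = list(
    feature_injection("charged_stack", 4, "E"),
    feature_injection("compensating_counter_charge", 10, "K"))))
  stc <- detect_charged_stacks(mc, 12)
  neg <- stc[[which(vapply(stc, `[[`, "", "sign") == "negative")]]
  expect_true(neg$compensated)
  # no charged inward residues: empty list
  expect_length(detect_charged_stacks(build_solenoid(solenoid_spec(s)), 12), 0)
  expect_error(detect_charged_stacks(m, 0), "unit_length")
})

test_that("exposed hydrophobics are found on the surface only", {
  s <- tandem(clean_unit(12, 9), 8)
  m <- build_solenoid(solenoid_spec(s, injections = list(
    feature_injection("surface_hydrophobic", 3, "F"))))
  hits <- detect_exposed_hydrophobics(m)
  expect_gte(sum(((hits - 1) %% 12) == 3), 8)
  # all-inward hydrophobics: no interior hits (terminal rungs excepted)
  mc <- build_solenoid(solenoid_spec(s))
  hits_c <- detect_exposed_hydrophobics(mc)
  rung <- (hits_c - 1) %/% 12 + 1
  expect_length(hits_c[rung %in% 2:7], 0)
  expect_length(detect_exposed_hydrophobics(m, hydrophobic_set = character(0)),
                0)
})

test_that("clash counting follows the van der Waals overlap rule", {
  two_c <- function(d) structure_model(data.frame(
    resno = c(1, 3), res1 = "A", name = "CB", element = "C",
    x = c(0, d), y = 0, z = 0, b = 0))
  expect_equal(count_clashes(two_c(3.1)), 0)   # 3.4 - 0.4 = 3.0 <= 3.1
  expect_equal(count_clashes(two_c(2.9)), 1)
  h <- build_helix(strrep("AEKQLAEKQL", 6))
  expect_equal(count_clashes(h), 0)
  expect_error(count_clashes(structure_model(data.frame(
    resno = 1, res1 = "X", name = "Q", element = "ZZ",
    x = 0, y = 0, z = 0, b = 0))), "ZZ")
})

test_that("fold classification covers the forge grid and is rigid-invariant", {
  for (L in c(5, 12, 20, 30)) for (nr in c(4, 10)) {
    m <- build_solenoid(solenoid_spec(tandem(clean_unit(L, L * nr), nr)))
    expect_identical(as.character(classify_fold(m, L)), "beta_solenoid")
  }
  h <- build_helix(strrep("AEKQLAEKQL", 8))
  expect_identical(as.character(classify_fold(h, 10)), "alpha_helical")
  co <- build_coil(strrep("GSNDPHGSND", 6), seed = 2)
  expect_identical(as.character(classify_fold(co, 10)), "none")
  # rigid-body invariance
  m <- build_solenoid(solenoid_spec(tandem(clean_unit(12, 3), 6)))
  for (sd in 1:5) {
    expect_identical(as.character(classify_fold(random_rigid(m, sd), 12)),
                     "beta_solenoid")
  }
  expect_error(classify_fold(m, 72), "unit_length")
})

test_that("the problematic rule matches its definition and is monotone", {
  uncomp <- list(structure(list(compensated = FALSE), class = "charged_stack"))
  comp <- list(structure(list(compensated = TRUE), class = "charged_stack"))
  expect_true(flag_problematic(82.4, 0.05, uncomp))
  expect_false(flag_problematic(60, -0.5, uncomp))
  expect_false(flag_problematic(85, 0.3, list()))
  # monotonicity at fixed pLDDT > 70: lowering the score or adding an
  # uncompensated stack never un-flags a model
  for (p in c(70.1, 85)) for (s in seq(-0.5, 0.5, by = 0.1)) {
    if (flag_problematic(p, s, list()))
      expect_true(flag_problematic(p, s - 0.2, list()))
    if (flag_problematic(p, s, comp))
      expect_true(flag_problematic(p, s, uncomp))
  }
})

test_that("disorder summaries use the 0.5 cohort-mean threshold", {
  expect_equal(disorder_flag(rep(0.5, 10)), list(mean = 0.5, flagged = TRUE))
  expect_false(disorder_flag(rep(0.49, 10))$flagged)
  expect_false(disorder_flag(rep(0, 5))$flagged)
  expect_error(disorder_flag(c(0.5, 1.4)), "0, 1")
})

test_that("audit_model integrates the diagnostics into one report", {
  s <- tandem(clean_unit(12, 21), 8)
  m <- build_solenoid(solenoid_spec(s, injections = list(
    feature_injection("charged_stack", 4, "D"))))
  rep <- audit_model(m, 12, seq_id = "fix", disorder = rep(0.2, 96))
  expect_s3_class(rep, "audit_report")
  expect_identical(rep$fold_class, "beta_solenoid")
  expect_equal(rep$mean_plddt, 90)
  expect_gte(length(rep$charged_stacks), 1)
  expect_true(rep$problematic)          # confident + uncompensated stack
  expect_equal(rep$disorder_mean, 0.2)
  expect_false(rep$disorder_flagged)
})
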