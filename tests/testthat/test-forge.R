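# Synthetic structure forge: geometry invariants, decoys, pLDDT annotation,
# feature injection, truth cohort.

test_that("forged solenoids keep chain continuity and rung periodicity", {
  for (L in c(5, 12, 20, 30)) for (nr in c(4, 10)) {
    m <- build_solenoid(solenoid_spec(tandem(clean_unit(L, L + nr), nr)))
    expect_equal(n_residues(m), L * nr)
    ca <- ca_xyz(m)
    d1 <- sqrt(rowSums(diff(ca)^2))
    expect_true(all(d1 >= 3.6 & d1 <= 4.0))
    i <- seq_len(nrow(ca) - L)
    dr <- sqrt(rowSums((ca[i + L, , drop = FALSE] - ca[i, , drop = FALSE])^2))
    expect_true(all(abs(dr - 4.8) <= 0.3))
    expect_true(all(dr >= 4.5 & dr <= 5.1))
  }
})

test_that("inward side chains are more buried than outward ones", {
  for (L in c(8, 14)) {
    m <- build_solenoid(solenoid_spec(tandem(clean_unit(L, L), 8)))
    sa <- sasa(m)
    inw <- ((sa$resno - 1) %% L) %in% seq(0, L - 1, by = 2)
    expect_lt(mean(sa$sc_rel_sasa[inw]), mean(sa$sc_rel_sasa[!inw]))
  }
})

test_that("solenoid spec validation fails before any geometry is built", {
  s <- tandem(clean_unit(8, 1), 6)
  expect_error(solenoid_spec(s, rise_per_rung = 0), "rise")
  expect_error(solenoid_spec(s, inward_positions = 8), "inward_positions")
  expect_error(solenoid_spec(s, plddt_profile = rep(101, 48)), "0, 100")
  expect_error(solenoid_spec(s, plddt_profile = rep(90, 3)), "length")
  expect_error(solenoid_spec(s, injections = list(
    feature_injection("charged_stack", 9, "E"))), "outside unit")
  expect_error(feature_injection("charged_stack", 1, "V"), "invalid")
  expect_error(build_solenoid(solenoid_spec(tandem(clean_unit(8, 1), 1))),
               "2 rungs")
})

test_that("injected features are realised geometrically", {
  s <- tandem(clean_unit(12, 3), 8)
  m_stack <- build_solenoid(solenoid_spec(s, injections = list(
    feature_injection("charged_stack", 4, "E"))))
  expect_true(all(residue_codes(m_stack)[seq(5, 96, by = 12)] == "E"))
  expect_gte(length(detect_charged_stacks(m_stack, 12)), 1)
  m_clean <- build_solenoid(solenoid_spec(s))
  expect_equal(count_clashes(m_clean), 0)
  m_clash <- build_solenoid(solenoid_spec(s, injections = list(
    feature_injection("clash", 2))))
  expect_gt(count_clashes(m_clash), 0)
})

test_that("ideal helix decoys have the ideal rise and helical geometry", {
  h <- build_helix(strrep("AEKQLMERAK", 10))
  ca <- ca_xyz(h)
  expect_equal(diff(range(ca[, 3])), 99 * 1.5, tolerance = 1 / (99 * 1.5))
  d1 <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d1 - 3.8) < 0.05))
  expect_gte(mean(assign_ss(h) == "H"), 0.9)
  expect_equal(n_residues(build_helix("A")), 1)
  expect_error(build_helix(""), "empty")
})

test_that("coil decoys are seeded, self-avoiding walks", {
  seq <- strrep("GSNDPH", 10)
  c1 <- build_coil(seq, seed = 7)
  c2 <- build_coil(seq, seed = 7)
  expect_identical(c1$atoms, c2$atoms)
  c3 <- build_coil(seq, seed = 8)
  expect_false(identical(c1$atoms, c3$atoms))
  ca <- ca_xyz(c1)
  D <- as.matrix(stats::dist(ca))
  sep <- abs(outer(seq_len(nrow(ca)), seq_len(nrow(ca)), "-"))
  expect_gte(min(D[sep >= 2]), 4.5)
  expect_identical(as.character(classify_fold(c1, 6)), "none")
  expect_error(build_coil(""), "empty")
})

test_that("pLDDT annotation dialects behave as the predictors do", {
  m <- build_solenoid(solenoid_spec(tandem(clean_unit(10, 2), 4)))
  n <- n_residues(m)
  mr <- annotate_plddt(m, rep(90, n), "residue_bfactor")
  expect_true(all(mr$atoms$b == 90))
  prof <- seq(40, 95, length.out = n)
  ma <- annotate_plddt(m, prof, "atomic_bfactor", seed = 3)
  expect_false(all(ma$atoms$b %in% prof))   # genuinely atomic
  rec <- residue_plddt(ma, "atomic_bfactor")
  expect_true(all(abs(rec - prof) <= 0.5))
  expect_identical(annotate_plddt(m, prof, "atomic_bfactor", seed = 3)$atoms,
                   ma$atoms)
  expect_error(annotate_plddt(m, rep(101, n)), "0, 100")
  expect_error(annotate_plddt(m, rep(90, n - 1)), "length")
})

test_that("truth cohort forging writes files plus matching labels", {
  cfg <- default_truth_config(seed = 2)[c(1, 7, 15, 26, 29)]
  dir <- withr::local_tempdir()
  out <- forge_truth_cohort(cfg, outdir = dir)
  expect_equal(nrow(out$manifest), 5)
  expect_length(out$truth, 5)
  files <- file.path(dir, out$manifest$file)
  expect_true(all(file.exists(files)))
  for (k in seq_along(files)) {
    m <- read_structure(files[k])
    dialect <- out$manifest$plddt_dialect[k]
    expect_lt(abs(mean_plddt(m, dialect) - out$truth[[k]]$mean_plddt), 0.5)
  }
  # empty config: empty manifest, no structure files
  dir2 <- withr::local_tempdir()
  out2 <- forge_truth_cohort(list(), outdir = dir2)
  expect_equal(nrow(out2$manifest), 0)
  expect_length(list.files(dir2, pattern = "\\.(pdb|cif)$"), 0)
})
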