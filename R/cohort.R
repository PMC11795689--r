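# Cohort orchestration: generate sequences -> forge (or ingest) structures
# -> audit -> compare -> summarize. The truth-cohort forge emits structure
# files plus ground-truth labels so detector recall/precision and the
# problematic fraction can be scored exactly.

# designed clean-solenoid unit: hydrophobic core positions, polar surface
.clean_solenoid_unit <- function(L) {
  core <- c("V", "I", "L", "F")
  surf <- c("S", "T", "N", "Q", "G")
  u <- character(L)
  even <- (seq_len(L) - 1) %% 2 == 0
  u[even] <- sample(core, sum(even), replace = TRUE)
  u[!even] <- sample(surf, sum(!even), replace = TRUE)
  paste(u, collapse = "")
}

# helix decoy unit: charged/polar helix formers only, so that an exposed
# helical surface is unambiguously environment-compatible whatever the draw
# (exposed alanine is scored as a mild surface hydrophobic and would blur
# the truth label of an otherwise clean decoy)
.helix_unit <- function(L) {
  paste(sample(c("E", "K", "Q", "R"), L, replace = TRUE), collapse = "")
}

#' Default configuration for the forged truth cohort
#'
#' A mixed cohort of clean solenoids, solenoids with injected implausible
#' features (uncompensated and compensated charged stacks, surface
#' hydrophobics, steric clashes), ideal helices and disordered coils, over
#' a range of unit lengths and both pLDDT dialects. Each entry records the
#' ground truth the audit should recover.
#'
#' @param seed Cohort seed (drives the per-entry sequence draws).
#' @param unit_lengths Unit lengths cycled over solenoid entries.
#' @param n_rungs Rungs per solenoid.
#' @param n_clean,n_stack,n_stack_lowconf,n_comp,n_clash,n_hyd,n_helix,n_coil
#'   Entry counts per category.
#' @return List of entry lists (a `truth_config`).
#' @export
default_truth_config <- function(seed = 1L,
                                 unit_lengths = c(5, 8, 12, 16, 20),
                                 n_rungs = 8L,
                                 n_clean = 6L, n_stack = 6L,
                                 n_stack_lowconf = 2L, n_comp = 3L,
                                 n_clash = 3L, n_hyd = 3L,
                                 n_helix = 4L, n_coil = 4L) {
  entries <- list()
  add <- function(kind, category, L, plddt, injections = character(0)) {
    i <- length(entries) + 1L
    entries[[i]] <<- list(
      id = sprintf("%s%02d_%s", substr(kind, 1, 3), i, category),
      kind = kind, category = category, unit_length = as.integer(L),
      n_rungs = as.integer(n_rungs), plddt = plddt,
      injections = injections,
      dialect = if (i %% 3 == 0) "atomic_bfactor" else "residue_bfactor",
      format = if (i %% 4 == 0) "mmcif" else "pdb",
      seed = as.integer(seed) + i)
  }
  cyc <- function(k, pool) pool[((seq_len(k) - 1) %% length(pool)) + 1]
  for (L in cyc(n_clean, unit_lengths)) add("solenoid", "clean", L, 90)
  for (L in cyc(n_stack, unit_lengths)) add("solenoid", "stack", L, 90,
                                            "charged_stack")
  for (L in cyc(n_stack_lowconf, unit_lengths)) add("solenoid",
    "stack_lowconf", L, 60, "charged_stack")
  # compensated entries use longer units so the two charged positions do not
  # dominate the 3D/1D mean
  for (L in cyc(n_comp, unit_lengths[unit_lengths >= 16])) add("solenoid",
    "compensated", L, 90, c("charged_stack", "compensating_counter_charge"))
  for (L in cyc(n_clash, unit_lengths)) add("solenoid", "clash", L, 90,
                                            "clash")
  for (L in cyc(n_hyd, unit_lengths)) add("solenoid", "surface_hydrophobic",
                                          L, 90, "surface_hydrophobic")
  for (L in cyc(n_helix, c(10, 12))) add("helix", "helix", L, 87)
  for (L in cyc(n_coil, c(10, 12))) add("coil", "coil", L, 40)
  entries
}

# realise one truth-config entry: model + truth label
.forge_entry <- function(e) {
  with_seed(e$seed, {
    L <- e$unit_length
    if (e$kind == "solenoid") {
      unit <- .clean_solenoid_unit(L)
      inj <- list()
      # injected positions: stack mid-wall (even = inward parity), others
      # offset from it
      p_stack <- 2L * (L %/% 4L)
      if ("charged_stack" %in% e$injections) {
        inj <- c(inj, list(feature_injection("charged_stack", p_stack, "E")))
        if (!"compensating_counter_charge" %in% e$injections) {
          # pack the facing inward position with a long-reach hydrophobic:
          # buried charge stacks sit against a packed core wall, and a
          # short-side-chain draw there would leave the stack half-open
          q <- (p_stack + L %/% 2L) %% L
          q <- q - (q %% 2L)
          if (q != p_stack) substr(unit, q + 1, q + 1) <- "F"
        }
      }
      seqr <- tandem(unit, e$n_rungs, scheme = "designed", seed = e$seed)
      if ("compensating_counter_charge" %in% e$injections)
        inj <- c(inj, list(feature_injection("compensating_counter_charge",
                                             (p_stack + L %/% 2L) %% L, "K")))
      if ("clash" %in% e$injections)
        inj <- c(inj, list(feature_injection("clash", p_stack)))
      if ("surface_hydrophobic" %in% e$injections)
        inj <- c(inj, list(feature_injection("surface_hydrophobic",
                                             (p_stack + 1L) %% L, "F")))
      model <- build_solenoid(solenoid_spec(
        seqr, plddt_profile = rep(e$plddt, L * e$n_rungs), injections = inj))
      fold_truth <- "beta_solenoid"
    } else if (e$kind == "helix") {
      unit <- .helix_unit(L)
      full <- paste(rep(unit, e$n_rungs), collapse = "")
      model <- build_helix(full, plddt_profile = rep(e$plddt, nchar(full)))
      fold_truth <- "alpha_helical"
    } else {
      unit <- .clean_solenoid_unit(L)
      full <- paste(rep(unit, e$n_rungs), collapse = "")
      model <- build_coil(full, seed = e$seed,
                          plddt_profile = rep(e$plddt, nchar(full)))
      fold_truth <- "none"
    }
    if (e$dialect == "atomic_bfactor")
      model <- annotate_plddt(model, rep(e$plddt, n_residues(model)),
                              "atomic_bfactor", seed = e$seed)
    has_stack <- "charged_stack" %in% e$injections
    compensated <- "compensating_counter_charge" %in% e$injections
    truth <- list(
      id = e$id, kind = e$kind, category = e$category,
      fold_class = fold_truth, unit_length = L, n_rungs = e$n_rungs,
      has_charged_stack = has_stack,
      stack_compensated = if (has_stack) compensated else NA,
      has_clash = "clash" %in% e$injections,
      has_surface_hydrophobic = "surface_hydrophobic" %in% e$injections,
      mean_plddt = e$plddt, plddt_dialect = e$dialect,
      problematic = e$plddt > 70 && has_stack && !compensated)
    list(model = model, truth = truth)
  })
}

#' Forge a truth-labelled cohort of structure files
#'
#' Writes one PDB/mmCIF file per config entry plus `truth.json` (ground
#' truth per model: fold class, injected features, mean pLDDT, expected
#' problematic flag) and `manifest.tsv` (seq_id, unit_length, dialect, file)
#' for the audit.
#'
#' @param config List of entries from [default_truth_config()].
#' @param seed Unused entropy anchor kept for call symmetry (entry seeds are
#'   fixed by the config).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `manifest` (data.frame) and `truth`
#'   (list of label records).
#' @export
forge_truth_cohort <- function(config, seed = 1L, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truths <- list(); rows <- list()
  for (e in config) {
    fe <- .forge_entry(e)
    ext <- if (e$format == "mmcif") "cif" else "pdb"
    fname <- paste0(e$id, ".", ext)
    write_structure(fe$model, file.path(outdir, fname), format = e$format)
    truths[[length(truths) + 1]] <- c(fe$truth, list(file = fname))
    rows[[length(rows) + 1]] <- data.frame(
      seq_id = e$id, unit_length = e$unit_length,
      n_copies = e$n_rungs, scheme = e$category,
      plddt_dialect = e$dialect, file = fname, stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(), unit_length = integer(),
               n_copies = integer(), scheme = character(),
               plddt_dialect = character(), file = character())
  jsonlite::write_json(truths, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(manifest = manifest, truth = truths))
}

#' Generate a sequence cohort (FASTA + manifest)
#'
#' @param out_fasta,out_manifest Output paths (skipped when `NULL`).
#' @param lengths,schemes,n_copies,seed As [generate_expanded_cohort()].
#' @param design `"expanded"` (default) or `"preliminary"`.
#' @return Invisibly, list with `sequences` and `manifest`.
#' @export
cohort_generate <- function(lengths = 5:30,
                            schemes = c("beta", "alpha+beta", "all"),
                            n_copies = 10, seed = 1L,
                            design = c("expanded", "preliminary"),
                            out_fasta = NULL, out_manifest = NULL) {
  design <- match.arg(design)
  seqs <- if (design == "expanded")
    generate_expanded_cohort(lengths, schemes, n_copies, seed)
  else attr(enumerate_preliminary_design(seed), "sequences")
  man <- cohort_manifest(seqs)
  if (!is.null(out_fasta)) write_fasta(seqs, out_fasta)
  if (!is.null(out_manifest))
    utils::write.table(man, out_manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(sequences = seqs, manifest = man))
}

#' Audit a directory of structure models against a manifest
#'
#' Every structure file whose base name matches a manifest `seq_id` is
#' audited; unmatched files are warned about and skipped (or abort with
#' `hard_fail = TRUE`). Output is deterministic for a given config: rows
#' are ordered by manifest order.
#'
#' @param structures_dir Directory of PDB/mmCIF files.
#' @param manifest data.frame with at least `seq_id` and `unit_length`
#'   (optional `plddt_dialect`).
#' @param config [audit_config()].
#' @param table 3D/1D score table.
#' @param out_tsv Optional report TSV path.
#' @param hard_fail Abort on unmatched files.
#' @return data.frame cohort report, one row per audited model, with the
#'   full per-model `audit_report`s in attribute `reports`.
#' @export
cohort_audit <- function(structures_dir, manifest, config = audit_config(),
                         table = default_3d1d_table(), out_tsv = NULL,
                         hard_fail = FALSE) {
  files <- list.files(structures_dir,
                      pattern = "\\.(pdb|cif|mmcif|ent)(\\.gz)?$",
                      full.names = TRUE)
  ids <- sub("\\.(pdb|cif|mmcif|ent)(\\.gz)?$", "", basename(files))
  unmatched <- setdiff(ids, manifest$seq_id)
  if (length(unmatched)) {
    msg <- paste("structure files without manifest entry (skipped):",
                 paste(unmatched, collapse = ", "))
    if (hard_fail) stop(msg) else warning(msg)
  }
  keep <- manifest$seq_id[manifest$seq_id %in% ids]
  rows <- list(); reports <- list()
  for (id in keep) {
    f <- files[ids == id][1]
    mrow <- manifest[manifest$seq_id == id, , drop = FALSE][1, ]
    dialect <- if ("plddt_dialect" %in% names(mrow) &&
                   !is.na(mrow$plddt_dialect)) mrow$plddt_dialect
      else "residue_bfactor"
    model <- read_structure(f)
    rep <- audit_model(model, mrow$unit_length, seq_id = id,
                       plddt_dialect = dialect, table = table,
                       config = config)
    reports[[id]] <- rep
    rows[[length(rows) + 1]] <- data.frame(
      seq_id = id, unit_length = as.integer(mrow$unit_length),
      scheme = if ("scheme" %in% names(mrow)) mrow$scheme else NA_character_,
      fold_class = rep$fold_class,
      mean_plddt = round(rep$mean_plddt, 4),
      mean_3d1d = round(rep$mean_3d1d, 4),
      frac_ge_threshold = round(rep$frac_ge_threshold, 4),
      categorical_fail = rep$categorical_fail,
      n_stacks = length(rep$charged_stacks),
      n_uncompensated_stacks = rep$n_uncompensated_stacks,
      n_exposed_hydrophobics = rep$n_exposed_hydrophobics,
      clash_count = rep$clash_count,
      disorder_mean = rep$disorder_mean,
      problematic = rep$problematic,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(out) <- NULL
  if (!is.null(out_tsv))
    utils::write.table(out, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  attr(out, "reports") <- reports
  out
}

#' Format a count as "k of n (p %)"
#'
#' @param k,n Counts; percentage is rounded to the nearest integer.
#' @export
format_fraction <- function(k, n) {
  pct <- if (n > 0) round(100 * k / n) else 0
  sprintf("%d of %d (%d %%)", k, n, pct)
}

#' Summarise a cohort audit report
#'
#' Counts and percentages per fold class, per pLDDT confidence band
#' (>90 very high, 70-90 confident, 50-70 low, <50 very low), categorical
#' 3D/1D failures and problematic models.
#'
#' @param report data.frame from [cohort_audit()].
#' @return List of summary blocks; percentages recomputable from counts.
#' @export
cohort_summarize <- function(report) {
  n <- nrow(report)
  if (n == 0)
    return(list(n = 0, fold_counts = integer(0), plddt_bands = c(
      very_high = 0L, confident = 0L, low = 0L, very_low = 0L),
      n_categorical_fail = 0L, n_problematic = 0L,
      problematic = format_fraction(0, 0)))
  if (!all(c("fold_class", "mean_plddt", "problematic") %in% names(report)))
    stop("malformed cohort report")
  fold_counts <- table(report$fold_class)
  bands <- cut(report$mean_plddt, c(-Inf, 50, 70, 90, Inf),
               labels = c("very_low", "low", "confident", "very_high"),
               right = FALSE)
  band_counts <- rev(table(bands))
  list(
    n = n,
    fold_counts = as.integer(fold_counts) |>
      stats::setNames(names(fold_counts)),
    fold_pct = round(100 * as.integer(fold_counts) / n) |>
      stats::setNames(names(fold_counts)),
    plddt_bands = as.integer(band_counts) |>
      stats::setNames(names(band_counts)),
    n_categorical_fail = sum(report$categorical_fail),
    n_problematic = sum(report$problematic),
    problematic = format_fraction(sum(report$problematic), n)
  )
}

#' Compare reference-method models to alternative-method models
#'
#' For each manifest sequence present in the reference directory and at
#' least one alternative directory, computes the TM-score (and CA RMSD)
#' between the reference and each alternative model of the same sequence.
#'
#' @param ref_dir Directory of reference models (e.g. AF2-style).
#' @param alt_dirs Named character vector of alternative directories.
#' @param manifest Cohort manifest (`seq_id`, `unit_length`).
#' @param out_tsv Optional output TSV.
#' @return data.frame with columns `seq_id`, `method`, `n`, `rmsd`, `tm`,
#'   `plddt_ref`, `plddt_alt`.
#' @export
cohort_compare <- function(ref_dir, alt_dirs, manifest, out_tsv = NULL) {
  if (is.null(names(alt_dirs)))
    names(alt_dirs) <- paste0("alt", seq_along(alt_dirs))
  for (d in alt_dirs) if (!dir.exists(d)) stop("missing directory: ", d)
  if (!dir.exists(ref_dir)) stop("missing directory: ", ref_dir)
  find_file <- function(dir, id) {
    f <- list.files(dir, pattern = paste0("^", id,
                    "\\.(pdb|cif|mmcif|ent)(\\.gz)?$"), full.names = TRUE)
    if (length(f)) f[1] else NA_character_
  }
  rows <- list()
  for (id in manifest$seq_id) {
    rf <- find_file(ref_dir, id)
    if (is.na(rf)) next
    ref <- read_structure(rf)
    for (m in names(alt_dirs)) {
      af <- find_file(alt_dirs[[m]], id)
      if (is.na(af)) next
      alt <- read_structure(af)
      cmp <- rank_model_rmsd(ref, alt, "ref", m)
      tm <- as.numeric(tm_score(ref, alt))
      rows[[length(rows) + 1]] <- data.frame(
        seq_id = id, method = m, n = cmp$n_matched,
        rmsd = round(cmp$rmsd, 4), tm = round(tm, 4),
        plddt_ref = round(cmp$plddt_a, 2), plddt_alt = round(cmp$plddt_b, 2),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (!is.null(out_tsv))
    utils::write.table(out, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
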