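# Model-plausibility diagnostics: environment classes and the 3D/1D
# compatibility profile with the 80%/0.1 categorical-fail rule, buried
# same-charge stack detection, exposed hydrophobics, steric clash counting,
# disorder flagging, and the "problematic" rule (confident pLDDT but poor
# 3D/1D score or an uncompensated internal charged stack).

.BURIAL_CLASSES <- c("E", "P1", "P2", "B1", "B2", "B3")
.SS_CLASSES <- c("helix", "sheet", "other")

# atom names tried, in order, for a residue's charge centre / side-chain
# centre (covers both full-atom files and the reduced forged representation)
.CHARGE_CENTER <- list(
  D = c("OD1", "OD2", "CG"), E = c("OE1", "OE2", "CD"),
  K = c("NZ"), R = c("NH1", "CZ", "NH2"), H = c("NE2", "ND1")
)

#' Map residue burial, surrounding polarity and secondary structure to an
#' environment class
#'
#' Six burial classes crossed with three secondary-structure states give the
#' 18 environment classes of the 3D/1D profile: exposed (`E`,
#' rel-SASA > 0.4), partially buried (`P1`/`P2` split at surrounding polar
#' fraction 0.67), and buried (`B1` < 0.45, `B2` < 0.58, `B3` >= 0.58 polar
#' fraction), each crossed with helix/sheet/other.
#'
#' @param rel_sasa Side-chain relative SASA in `[0, ~1.5]`.
#' @param polar_frac Fraction of surrounding atoms that are polar, `[0, 1]`.
#' @param ss Secondary-structure state `"H"`, `"E"` or `"C"` (also accepts
#'   `"helix"`, `"sheet"`, `"other"`).
#' @param exposed_min,buried_max Burial cutoffs (defaults 0.40 and 0.15).
#' @return Environment class string, e.g. `"B1_sheet"`.
#' @export
assign_environment <- function(rel_sasa, polar_frac, ss,
                               exposed_min = 0.40, buried_max = 0.15) {
  if (!is.finite(rel_sasa) || rel_sasa < 0)
    stop("rel_sasa must be a non-negative fraction")
  if (!is.finite(polar_frac) || polar_frac < 0 || polar_frac > 1)
    stop("polar_frac must be in [0, 1]")
  ssl <- switch(ss, H = , helix = "helix", E = , sheet = "sheet",
                C = , other = "other",
                stop("unknown secondary-structure state '", ss, "'"))
  burial <- if (rel_sasa > exposed_min) "E"
  else if (rel_sasa > buried_max) {
    if (polar_frac < 0.67) "P1" else "P2"
  } else {
    if (polar_frac < 0.45) "B1" else if (polar_frac < 0.58) "B2" else "B3"
  }
  paste(burial, ssl, sep = "_")
}

#' All 18 environment class labels
#' @export
environment_classes <- function() {
  as.vector(outer(.BURIAL_CLASSES, .SS_CLASSES, paste, sep = "_"))
}

#' Default 3D/1D residue-environment compatibility table
#'
#' A complete 20 x 18 table of compatibility scores between residue types
#' and environment classes, generated from a documented closed-form
#' heuristic: agreement between the residue's hydropathy and the class
#' burial level, agreement between residue polarity and surrounding
#' polarity, a secondary-structure propensity term, and a strong penalty
#' for charged residues buried in apolar surroundings. Scores are
#' dimensionless, roughly in `[-1.2, 0.8]`; positive means compatible.
#' A custom table can be supplied as TSV via [read_3d1d_table()].
#'
#' @return data.frame: column `res` plus one numeric column per class.
#' @export
default_3d1d_table <- function() {
  polarity <- c(A = 0.35, R = 1.0, N = 0.8, D = 1.0, C = 0.3, Q = 0.8,
                E = 1.0, G = 0.5, H = 0.8, I = 0.15, L = 0.15, K = 1.0,
                M = 0.3, F = 0.15, P = 0.5, S = 0.6, T = 0.6, W = 0.4,
                Y = 0.6, V = 0.15)
  cls_burial <- c(E = 0.25, P1 = 0.50, P2 = 0.45, B1 = 0.95, B2 = 0.85,
                  B3 = 0.70)
  cls_polar <- c(E = 0.80, P1 = 0.35, P2 = 0.75, B1 = 0.20, B2 = 0.50,
                 B3 = 0.75)
  prop <- default_propensity_table()
  classes <- environment_classes()
  out <- data.frame(res = .AA1, stringsAsFactors = FALSE)
  for (cl in classes) {
    parts <- strsplit(cl, "_")[[1]]
    bc <- parts[1]; ssl <- parts[2]
    score <- vapply(.AA1, function(aa) {
      b_aa <- (.KD[[aa]] + 4.5) / 9
      s <- 0.55 - 1.0 * abs(b_aa - cls_burial[[bc]]) -
        0.45 * abs(polarity[[aa]] - cls_polar[[bc]])
      if (aa %in% c("D", "E", "K", "R", "H")) {
        if (bc %in% c("B1", "B2")) s <- s - 0.5
        if (bc == "B3") s <- s - 0.2
      }
      i <- match(aa, prop$res)
      if (ssl == "helix") s <- s + 0.12 * (prop$p_alpha[i] - 1)
      if (ssl == "sheet") s <- s + 0.12 * (prop$p_beta[i] - 1)
      max(min(s, 0.8), -1.2)
    }, numeric(1))
    out[[cl]] <- round(unname(score), 3)
  }
  out
}

#' Read / write a 3D/1D score table as TSV
#'
#' @param path TSV with column `res` plus the 18 class columns.
#' @return data.frame in the layout of [default_3d1d_table()].
#' @export
read_3d1d_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("res", environment_classes())
  if (!all(need %in% names(tab)))
    stop("3D/1D table is missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  if (!setequal(tab$res, .AA1))
    stop("3D/1D table must cover exactly the 20 standard residues")
  if (any(is.na(tab[, environment_classes()])))
    stop("3D/1D table has missing cells")
  tab
}

#' @rdname read_3d1d_table
#' @param table Table to write.
#' @export
write_3d1d_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# fraction of polar (N/O) atoms among atoms of other residues within
# `shell` Angstrom of each residue's side-chain centroid
.polar_fraction <- function(model, shell = 6.0) {
  a <- model$atoms
  idx <- residue_atom_index(model)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  polar <- a$element %in% c("N", "O")
  vapply(seq_along(idx), function(k) {
    i <- idx[[k]]
    sc <- i[!(a$name[i] %in% c("N", "CA", "C", "O"))]
    if (!length(sc)) sc <- i[a$name[i] == "CA"]
    ctr <- colMeans(xyz[sc, , drop = FALSE])
    d2 <- rowSums(sweep(xyz, 2, ctr)^2)
    nb <- which(d2 < shell^2)
    nb <- setdiff(nb, i)
    if (!length(nb)) 0 else mean(polar[nb])
  }, numeric(1))
}

#' Per-residue 3D/1D environment compatibility profile
#'
#' Assigns each residue an environment class (burial from side-chain
#' relative SASA, surrounding polarity, CA-geometry secondary structure),
#' looks up its raw compatibility score, smooths with a centred moving
#' average (window truncated at the termini) and applies the categorical
#' rule: the model fails categorically when fewer than 80% of residues have
#' a smoothed score of at least 0.1.
#'
#' @param model A [structure_model()].
#' @param table 3D/1D score table (default [default_3d1d_table()]).
#' @param window Odd smoothing window length (default 21).
#' @param score_min Per-residue score threshold (default 0.1).
#' @param pass_frac Required fraction of residues at or above `score_min`
#'   (default 0.8).
#' @param sasa_table Optional precomputed [sasa()] result.
#' @param raw_scores Optional externally supplied per-residue raw scores
#'   (skips the structural environment computation; used by fixtures).
#' @return An `environment_profile`: list with `class`, `raw`, `smoothed`,
#'   `mean_3d1d`, `frac_ge_threshold`, `categorical_fail`.
#' @export
profile_3d1d <- function(model, table = default_3d1d_table(), window = 21,
                         score_min = 0.1, pass_frac = 0.8,
                         sasa_table = NULL, raw_scores = NULL) {
  if (window < 1 || window %% 2 == 0)
    stop("window must be a positive odd integer")
  if (is.null(raw_scores)) {
    if (is.null(sasa_table)) sasa_table <- sasa(model)
    ss <- assign_ss(model)
    pf <- .polar_fraction(model)
    res <- residue_codes(model)
    cls <- vapply(seq_along(res), function(k)
      assign_environment(sasa_table$sc_rel_sasa[k], pf[k], ss[k]),
      character(1))
    raw <- vapply(seq_along(res), function(k) {
      i <- match(res[k], table$res)
      if (is.na(i)) stop("residue '", res[k], "' missing from 3D/1D table")
      table[[cls[k]]][i]
    }, numeric(1))
  } else {
    raw <- raw_scores
    cls <- rep(NA_character_, length(raw))
  }
  n <- length(raw)
  half <- (window - 1) / 2
  smoothed <- vapply(seq_len(n), function(i) {
    mean(raw[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  frac <- mean(smoothed >= score_min)
  structure(list(class = cls, raw = raw, smoothed = smoothed,
                 mean_3d1d = mean(smoothed), frac_ge_threshold = frac,
                 categorical_fail = frac < pass_frac),
            class = "environment_profile")
}

#' @export
print.environment_profile <- function(x, ...) {
  cat(sprintf("3D/1D profile: %d residues, mean %.3f, %.0f%% >= 0.1%s\n",
              length(x$raw), x$mean_3d1d, 100 * x$frac_ge_threshold,
              if (x$categorical_fail) " [categorical FAIL]" else ""))
  invisible(x)
}

# charge-centre atom row for each residue (NA when residue has no match)
.charge_center_rows <- function(model) {
  a <- model$atoms
  idx <- residue_atom_index(model)
  res <- residue_codes(model)
  vapply(seq_along(idx), function(k) {
    i <- idx[[k]]
    for (nm in c(.CHARGE_CENTER[[res[k]]], "CB", "CA")) {
      j <- i[a$name[i] == nm]
      if (length(j)) return(j[1])
    }
    i[1]
  }, integer(1))
}

#' Detect buried same-charge stacks in a repeat-protein model
#'
#' A charged stack is a run of same-sign charged residues (D/E negative;
#' K/R and optionally H positive) occupying the same repeat-unit position
#' in consecutive rungs, linked when consecutive charge centres are within
#' `link_dist`, with at least `stack_min` members buried (side-chain
#' relative SASA at most `burial_max_relsasa`). A stack is compensated when
#' any member's charge centre has an opposite-sign charge centre within
#' `compensation_dist`.
#'
#' @param model A [structure_model()].
#' @param unit_length Repeat unit length (> 0).
#' @param stack_min Minimum members (default 3).
#' @param link_dist Maximum consecutive charge-centre distance (default 7.0).
#' @param burial_max_relsasa Burial cutoff on side-chain relative SASA
#'   (default 0.15).
#' @param compensation_dist Opposite-charge compensation radius (default 4.5).
#' @param his_positive Count histidine as positively charged (default TRUE).
#' @param sasa_table Optional precomputed [sasa()] result.
#' @return List of `charged_stack` objects: `unit_position` (0-based),
#'   `members` (residue indices), `sign`, `compensated`, `min_member_dist`,
#'   `n_buried`.
#' @export
detect_charged_stacks <- function(model, unit_length, stack_min = 3,
                                  link_dist = 7.0, burial_max_relsasa = 0.15,
                                  compensation_dist = 4.5,
                                  his_positive = TRUE, sasa_table = NULL) {
  if (!is.numeric(unit_length) || unit_length <= 0)
    stop("unit_length must be > 0")
  L <- as.integer(unit_length)
  res <- residue_codes(model)
  n <- length(res)
  pos_set <- if (his_positive) .POS_CHARGED else setdiff(.POS_CHARGED, "H")
  sign_of <- ifelse(res %in% .NEG_CHARGED, "negative",
                    ifelse(res %in% pos_set, "positive", NA))
  if (all(is.na(sign_of))) return(list())
  if (is.null(sasa_table)) sasa_table <- sasa(model)
  cc_rows <- .charge_center_rows(model)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  cc <- xyz[cc_rows, , drop = FALSE]
  charged_idx <- which(!is.na(sign_of))

  stacks <- list()
  for (p in 0:(L - 1)) {
    ridx <- which(((seq_len(n) - 1L) %% L) == p)   # residues at unit pos p
    k <- 1
    while (k <= length(ridx)) {
      i0 <- ridx[k]
      s <- sign_of[i0]
      if (is.na(s)) { k <- k + 1; next }
      run <- i0
      while (k < length(ridx)) {
        nxt <- ridx[k + 1]
        if (is.na(sign_of[nxt]) || sign_of[nxt] != s) break
        d <- sqrt(sum((cc[nxt, ] - cc[run[length(run)], ])^2))
        if (d > link_dist) break
        run <- c(run, nxt); k <- k + 1
      }
      k <- k + 1
      if (length(run) >= stack_min) {
        buried <- sasa_table$sc_rel_sasa[run] <= burial_max_relsasa
        if (sum(buried) >= stack_min) {
          dmin <- min(vapply(seq_len(length(run) - 1), function(q)
            sqrt(sum((cc[run[q + 1], ] - cc[run[q], ])^2)), numeric(1)))
          opp <- charged_idx[sign_of[charged_idx] != s]
          compensated <- FALSE
          if (length(opp)) {
            for (m in run) {
              d2 <- rowSums(sweep(cc[opp, , drop = FALSE], 2, cc[m, ])^2)
              if (min(d2) <= compensation_dist^2) { compensated <- TRUE; break }
            }
          }
          stacks[[length(stacks) + 1]] <- structure(
            list(unit_position = p, members = run, sign = s,
                 compensated = compensated, min_member_dist = dmin,
                 n_buried = sum(buried)),
            class = "charged_stack")
        }
      }
    }
  }
  stacks
}

#' Detect solvent-exposed hydrophobic residues
#'
#' @param model A [structure_model()].
#' @param relsasa_min Side-chain relative SASA threshold (default 0.5).
#' @param hydrophobic_set Residues counted as hydrophobic.
#' @param sasa_table Optional precomputed [sasa()] result.
#' @return Integer vector of residue indices (1-based, residue order).
#' @export
detect_exposed_hydrophobics <- function(model, relsasa_min = 0.5,
                                        hydrophobic_set = .HYDROPHOBIC,
                                        sasa_table = NULL) {
  if (!length(hydrophobic_set)) return(integer(0))
  if (is.null(sasa_table)) sasa_table <- sasa(model)
  res <- residue_codes(model)
  which(res %in% hydrophobic_set & sasa_table$sc_rel_sasa >= relsasa_min)
}

#' Count steric clashes
#'
#' Counts atom pairs at residue separation of at least 2 whose distance is
#' below the sum of their element van der Waals radii minus `tolerance`.
#'
#' @param model A [structure_model()].
#' @param tolerance Overlap tolerance, Angstrom (default 0.4).
#' @return Integer clash count.
#' @export
count_clashes <- function(model, tolerance = 0.4) {
  a <- model$atoms
  vdw <- vdw_radii()
  unknown <- setdiff(unique(a$element), names(vdw))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  r <- unname(vdw[a$element])
  # sequence separation follows the residue numbering
  ord <- a$resno
  xyz <- as.matrix(a[, c("x", "y", "z")])
  D <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(ord, ord, "-"))
  lim <- outer(r, r, "+") - tolerance
  sum(D < lim & sep >= 2 & upper.tri(D))
}

#' The confident-but-implausible ("problematic") rule
#'
#' A model is problematic when its mean pLDDT exceeds 70 but either its mean
#' 3D/1D score is below 0.1 or it contains an uncompensated internal charged
#' stack.
#'
#' @param mean_plddt Mean model pLDDT on the 0-100 scale.
#' @param mean_3d1d Mean smoothed 3D/1D score.
#' @param stacks List of stacks from [detect_charged_stacks()].
#' @param plddt_gate pLDDT confidence gate (default 70).
#' @param score_min 3D/1D score threshold (default 0.1).
#' @return Logical.
#' @export
flag_problematic <- function(mean_plddt, mean_3d1d, stacks = list(),
                             plddt_gate = 70, score_min = 0.1) {
  uncomp <- any(vapply(stacks, function(s) !isTRUE(s$compensated), logical(1)))
  mean_plddt > plddt_gate && (mean_3d1d < score_min || uncomp)
}

#' Summarise per-residue disorder probabilities
#'
#' @param probabilities Per-residue disorder probabilities in `[0, 1]`.
#' @param threshold Cohort-mean flag threshold (default 0.5).
#' @return List with `mean` and `flagged` (mean at or above threshold).
#' @export
disorder_flag <- function(probabilities, threshold = 0.5) {
  if (any(probabilities < 0 | probabilities > 1))
    stop("disorder probabilities must be in [0, 1]")
  m <- mean(probabilities)
  list(mean = m, flagged = m >= threshold)
}

#' Audit configuration defaults
#'
#' All thresholds of the plausibility audit in one list, overridable per
#' call. Rationale: burial at side-chain rel-SASA 0.15 and exposure at 0.5
#' are conventional buried/exposed cutoffs; stack linkage 7.0 Angstrom spans
#' one solenoid rung rise with margin; compensation 4.5 Angstrom is
#' salt-bridge range; the 0.1 score and 80% fraction implement the
#' categorical 3D/1D rule; the pLDDT gate 70 is the moderate-confidence
#' boundary.
#'
#' @param ... Named overrides.
#' @export
audit_config <- function(...) {
  cfg <- list(
    probe_radius = 1.4, n_points = 960L,
    window = 21L, score_min = 0.1, pass_frac = 0.8,
    stack_min = 3L, link_dist = 7.0, burial_max_relsasa = 0.15,
    compensation_dist = 4.5, his_positive = TRUE,
    hydrophobic_relsasa_min = 0.5, clash_tolerance = 0.4,
    plddt_gate = 70, disorder_threshold = 0.5
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown audit option(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Full plausibility audit of one model
#'
#' Runs every diagnostic once (sharing one SASA computation): mean pLDDT,
#' 3D/1D profile with categorical rule, charged stacks, exposed
#' hydrophobics, clash count, geometric fold class, optional disorder
#' summary, and the problematic flag.
#'
#' @param model A [structure_model()].
#' @param unit_length Repeat unit length.
#' @param seq_id Identifier carried into the report.
#' @param plddt_dialect pLDDT dialect for [residue_plddt()].
#' @param disorder Optional per-residue disorder probabilities.
#' @param table 3D/1D score table.
#' @param config [audit_config()] list.
#' @return An `audit_report` list.
#' @export
audit_model <- function(model, unit_length, seq_id = "model",
                        plddt_dialect = c("residue_bfactor", "atomic_bfactor"),
                        disorder = NULL, table = default_3d1d_table(),
                        config = audit_config()) {
  plddt_dialect <- match.arg(plddt_dialect)
  sa <- sasa(model, probe_radius = config$probe_radius,
             n_points = config$n_points)
  mp <- mean_plddt(model, plddt_dialect)
  prof <- profile_3d1d(model, table = table, window = config$window,
                       score_min = config$score_min,
                       pass_frac = config$pass_frac, sasa_table = sa)
  stacks <- detect_charged_stacks(
    model, unit_length, stack_min = config$stack_min,
    link_dist = config$link_dist,
    burial_max_relsasa = config$burial_max_relsasa,
    compensation_dist = config$compensation_dist,
    his_positive = config$his_positive, sasa_table = sa)
  hyd <- detect_exposed_hydrophobics(
    model, relsasa_min = config$hydrophobic_relsasa_min, sasa_table = sa)
  clashes <- count_clashes(model, tolerance = config$clash_tolerance)
  fold <- classify_fold(model, unit_length)
  dis <- if (!is.null(disorder))
    disorder_flag(disorder, config$disorder_threshold) else NULL
  structure(list(
    seq_id = seq_id, unit_length = as.integer(unit_length),
    mean_plddt = mp, profile = prof, mean_3d1d = prof$mean_3d1d,
    frac_ge_threshold = prof$frac_ge_threshold,
    categorical_fail = prof$categorical_fail,
    charged_stacks = stacks,
    n_uncompensated_stacks = sum(vapply(stacks, function(s)
      !isTRUE(s$compensated), logical(1))),
    exposed_hydrophobics = hyd, n_exposed_hydrophobics = length(hyd),
    clash_count = clashes,
    fold_class = as.character(fold), fold_details = attr(fold, "details"),
    disorder_mean = if (is.null(dis)) NA_real_ else dis$mean,
    disorder_flagged = if (is.null(dis)) NA else dis$flagged,
    problematic = flag_problematic(mp, prof$mean_3d1d, stacks,
                                   config$plddt_gate, config$score_min)
  ), class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("audit: %s  fold=%s  pLDDT=%.1f  3D/1D=%.3f%s\n",
              x$seq_id, x$fold_class, x$mean_plddt, x$mean_3d1d,
              if (x$categorical_fail) " (categorical fail)" else ""))
  cat(sprintf("  stacks=%d (uncompensated %d)  exposed hydrophobics=%d  clashes=%d%s\n",
              length(x$charged_stacks), x$n_uncompensated_stacks,
              x$n_exposed_hydrophobics, x$clash_count,
              if (isTRUE(x$problematic)) "  [PROBLEMATIC]" else ""))
  invisible(x)
}
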