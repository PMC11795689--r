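# Rank-to-rank and method-to-method comparison of models of the same
# sequence: single-pass Kabsch superposition RMSD (no outlier rejection) and
# TM-score with fragment-seeded iterative superposition search.

#' Optimal least-squares superposition (Kabsch algorithm)
#'
#' Finds the proper rotation (det = +1) and translation superposing point
#' set `coords_a` onto `coords_b` and the RMSD in the superposed frame.
#' Single pass, no outlier rejection; the inputs are not modified.
#'
#' @param coords_a,coords_b n x 3 matrices (n >= 3), identical
#'   correspondence by row.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   superposed copy of a is `a %*% t(rotation) + translation`), and `rmsd`.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3)
    stop("coordinate sets must be equal-size n x 3 matrices")
  if (nrow(a) < 3) stop("need at least 3 points to superpose")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite coordinates")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  if (min(svd(a0)$d) < 1e-8 && min(svd(b0)$d) < 1e-8)
    stop("degenerate (collinear) point set; superposition undefined")
  H <- crossprod(a0, b0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- as.numeric(cb - R %*% ca)
  diff <- b0 - a0 %*% t(R)
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums(diff^2))))
}

#' CA RMSD between two prediction ranks of the same sequence
#'
#' Models must carry identical sequences (identity correspondence; no
#' alignment is attempted). CA-only, single-pass superposition.
#'
#' @param model_a,model_b [structure_model()]s of the same sequence.
#' @param id_a,id_b Identifiers for the report.
#' @return A `comparison_result`: list with `pair`, `n_matched`, `rmsd`,
#'   `plddt_a`, `plddt_b` (and `tm_score = NA`).
#' @export
rank_model_rmsd <- function(model_a, model_b, id_a = "rank1", id_b = "rank2") {
  if (model_sequence(model_a) != model_sequence(model_b))
    stop("models have different sequences; rank comparison requires ",
         "identical sequences")
  fit <- kabsch_superpose(ca_xyz(model_a), ca_xyz(model_b))
  structure(list(pair = c(id_a, id_b), n_matched = n_residues(model_a),
                 rmsd = fit$rmsd, tm_score = NA_real_,
                 plddt_a = mean_plddt(model_a), plddt_b = mean_plddt(model_b)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("compare %s vs %s: n=%d rmsd=%.2f A tm=%s\n",
              x$pair[1], x$pair[2], x$n_matched,
              x$rmsd, ifelse(is.na(x$tm_score), "-",
                             sprintf("%.3f", x$tm_score))))
  invisible(x)
}

#' TM-score normalization distance scale
#'
#' `d0(L) = 1.24 (L - 15)^(1/3) - 1.8`, floored at 0.5 Angstrom (the floor
#' applies for all L <= 21).
#'
#' @param l_norm Normalization length.
#' @param floor_value Minimum d0 (default 0.5).
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(l_norm, floor_value = 0.5) {
  raw <- 1.24 * sign(l_norm - 15) * abs(l_norm - 15)^(1 / 3) - 1.8
  max(raw, floor_value)
}

#' TM-score between two models of the same sequence
#'
#' Identity (residue-by-residue) correspondence on CA atoms. The score is
#' the maximum over superpositions of
#' `(1/L_norm) * sum_i 1 / (1 + (d_i/d0)^2)`. Superpositions are seeded on
#' sliding fragments of lengths L, L/2 and L/4 and refined by iterating
#' Kabsch superposition on the residues within a distance cutoff until the
#' membership is stable (at most `max_iter` iterations); the full-length
#' superposition is always among the seeds, so the search can only improve
#' on it.
#'
#' @param model_a,model_b [structure_model()]s (or n x 3 CA matrices) with
#'   identical sequences/point counts.
#' @param normalize_by `"a"`, `"b"`, or `"shorter"`.
#' @param max_iter Refinement iterations per seed (default 20).
#' @return TM-score in (0, 1], with attribute `d0`.
#' @export
tm_score <- function(model_a, model_b, normalize_by = c("shorter", "a", "b"),
                     max_iter = 20L) {
  normalize_by <- match.arg(normalize_by)
  xa <- if (inherits(model_a, "structure_model")) {
    if (inherits(model_b, "structure_model") &&
        model_sequence(model_a) != model_sequence(model_b))
      stop("models have different sequences; TM-score requires identical ",
           "sequences")
    ca_xyz(model_a)
  } else as.matrix(model_a)
  xb <- if (inherits(model_b, "structure_model")) ca_xyz(model_b) else
    as.matrix(model_b)
  if (nrow(xa) != nrow(xb)) stop("point counts differ")
  n <- nrow(xa)
  l_norm <- switch(normalize_by, a = n, b = n, shorter = n)
  if (l_norm < 3) stop("normalization length must be >= 3")
  d0 <- tm_d0(l_norm)
  dcut <- max(d0, 3.5)

  score_of <- function(fit) {
    d <- sqrt(rowSums((sweep(xa %*% t(fit$rotation), 2, -fit$translation) -
                         xb)^2))
    list(score = sum(1 / (1 + (d / d0)^2)) / l_norm, d = d)
  }
  best <- -Inf
  frags <- unique(pmax(4L, c(n, n %/% 2L, n %/% 4L)))
  for (fl in frags) {
    starts <- unique(c(seq(1L, n - fl + 1L, by = max(1L, fl %/% 2L)),
                       n - fl + 1L))
    for (s0 in starts) {
      idx <- s0:(s0 + fl - 1L)
      fit <- tryCatch(kabsch_superpose(xa[idx, , drop = FALSE],
                                       xb[idx, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(fit)) next
      sc <- score_of(fit)
      best <- max(best, sc$score)
      prev <- idx
      for (it in seq_len(max_iter)) {
        keep <- which(sc$d < dcut)
        if (length(keep) < 3) keep <- order(sc$d)[seq_len(min(4, n))]
        if (identical(keep, prev)) break
        prev <- keep
        fit <- tryCatch(kabsch_superpose(xa[keep, , drop = FALSE],
                                         xb[keep, , drop = FALSE]),
                        error = function(e) NULL)
        if (is.null(fit)) break
        sc <- score_of(fit)
        best <- max(best, sc$score)
      }
    }
  }
  structure(min(best, 1), d0 = d0)
}

#' Is a TM-score a significant fold match?
#'
#' Uses the conventional 0.5 same-fold threshold.
#'
#' @param tm TM-score.
#' @param threshold Cutoff (default 0.5).
#' @export
tm_significant <- function(tm, threshold = 0.5) tm > threshold

#' Cross-method divergence table
#'
#' One row per non-reference method: TM-score against the reference model
#' of the same sequence plus both mean pLDDTs.
#'
#' @param models_by_method Named list of [structure_model()]s (same
#'   sequence; names are method labels).
#' @param reference Name of the reference method (default first AF2-like
#'   entry, else the first).
#' @param plddt_dialects Optional named character vector of pLDDT dialects
#'   per method.
#' @return data.frame with columns `method`, `tm_vs_reference`,
#'   `plddt_reference`, `plddt_method`, `significant_match`.
#' @export
divergence_table <- function(models_by_method, reference = NULL,
                             plddt_dialects = NULL) {
  if (length(models_by_method) < 2)
    stop("need at least 2 methods to compare")
  nms <- names(models_by_method)
  if (is.null(nms) || any(nms == ""))
    stop("models_by_method must be a fully named list")
  if (is.null(reference))
    reference <- if ("af2" %in% tolower(nms)) nms[tolower(nms) == "af2"][1]
      else nms[1]
  if (!reference %in% nms)
    stop("reference method '", reference, "' absent from models_by_method")
  dial <- function(m) {
    if (!is.null(plddt_dialects) && m %in% names(plddt_dialects))
      plddt_dialects[[m]] else "residue_bfactor"
  }
  ref <- models_by_method[[reference]]
  pr <- mean_plddt(ref, dial(reference))
  rows <- lapply(setdiff(nms, reference), function(m) {
    tm <- as.numeric(tm_score(ref, models_by_method[[m]]))
    data.frame(method = m, tm_vs_reference = tm,
               plddt_reference = pr,
               plddt_method = mean_plddt(models_by_method[[m]], dial(m)),
               significant_match = tm_significant(tm),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
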