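# Secondary-structure assignment from C-alpha geometry alone (P-SEA-style
# short-range distance criteria for helix, plus a sheet-register criterion
# for strands), so it works on reduced models without full backbone.

#' Assign secondary structure from C-alpha geometry
#'
#' Helix (`H`): P-SEA-style short-range CA distance windows
#' (d(i,i+2) ~ 5.4, d(i,i+3) ~ 5.0-5.3, d(i,i+4) ~ 6.2-6.4 Angstrom);
#' a match at i marks residues i..i+3.
#' Strand (`E`), assigned to non-helix residues: the local chain must be
#' extended (d(i-1,i+1) >= `ext_min`) and the residue must have a
#' cross-strand register partner — another CA at sequence separation >= 4
#' within sheet-pairing distance (4.2-5.7 Angstrom), which in a solenoid is
#' the equivalent residue of the neighbouring rung. Everything else is coil
#' (`C`). Models with fewer than 5 residues are all coil.
#'
#' @param model A [structure_model()] (only CA coordinates are used).
#' @param ext_min Minimum d(i-1,i+1) for a residue to count as extended.
#' @return Character vector over residues with values `"H"`, `"E"`, `"C"`.
#' @export
assign_ss <- function(model, ext_min = 5.0) {
  ca <- ca_xyz(model)
  n <- nrow(ca)
  ss <- rep("C", n)
  if (n < 5) return(ss)
  dk <- function(k) {
    i <- seq_len(n - k)
    sqrt(rowSums((ca[i + k, , drop = FALSE] - ca[i, , drop = FALSE])^2))
  }
  d2 <- dk(2); d3 <- dk(3); d4 <- dk(4)
  helix_start <- which(d2[seq_len(n - 4)] >= 4.6 & d2[seq_len(n - 4)] <= 6.0 &
                       d3[seq_len(n - 4)] >= 4.5 & d3[seq_len(n - 4)] <= 5.9 &
                       d4 >= 5.2 & d4 <= 7.3)
  for (i in helix_start) ss[i:(i + 3)] <- "H"

  notH <- which(ss != "H")
  if (length(notH)) {
    # extended local geometry: d(i-1, i+1)
    ext <- rep(FALSE, n)
    mid <- 2:(n - 1)
    ext[mid] <- d2[mid - 1] >= ext_min
    ext[1] <- d2[1] >= ext_min
    ext[n] <- d2[n - 2] >= ext_min
    # register partner at separation >= 4 within sheet-pairing distance
    D <- as.matrix(stats::dist(ca))
    sep <- abs(outer(seq_len(n), seq_len(n), "-"))
    partner <- (D >= 4.2 & D <= 5.7 & sep >= 4)
    has_partner <- rowSums(partner) > 0
    e <- notH[ext[notH] & has_partner[notH]]
    ss[e] <- "E"
  }
  ss
}

#' Geometric fold classification of a repeat-protein model
#'
#' A model is a `beta_solenoid` when the rung periodicity is present (the
#' median CA distance between residues one repeat unit apart lies in
#' 4.0-7.0 Angstrom with coefficient of variation < 0.25) and at least 25%
#' of residues are strand; `alpha_helical` when at least 60% of residues
#' are helix and the extent along the principal axis is consistent with an
#' extended helix (>= `helix_extent_min` Angstrom per residue); `none` when
#' no secondary-structure class reaches 25% and the rung test fails
#' (disordered); otherwise `other`.
#'
#' @param model A [structure_model()].
#' @param unit_length Repeat unit length (residues); must be smaller than
#'   the residue count.
#' @param helix_extent_min Minimum principal-axis extent per residue for the
#'   helix class (ideal helix: 1.5).
#' @return Fold class string (`"beta_solenoid"`, `"alpha_helical"`,
#'   `"none"`, `"other"`) with a `details` attribute (rung statistics and
#'   secondary-structure fractions).
#' @export
classify_fold <- function(model, unit_length, helix_extent_min = 1.1) {
  n <- n_residues(model)
  if (!is.numeric(unit_length) || unit_length < 1 || unit_length >= n)
    stop("unit_length must be in [1, residue count)")
  L <- as.integer(unit_length)
  ca <- ca_xyz(model)
  i <- seq_len(n - L)
  d_rung <- sqrt(rowSums((ca[i + L, , drop = FALSE] - ca[i, , drop = FALSE])^2))
  med <- stats::median(d_rung)
  cv <- if (mean(d_rung) > 0) stats::sd(d_rung) / mean(d_rung) else Inf
  if (length(d_rung) < 2) cv <- 0
  ss <- assign_ss(model)
  helix_frac <- mean(ss == "H")
  sheet_frac <- mean(ss == "E")
  rung_ok <- med >= 4.0 && med <= 7.0 && cv < 0.25
  # extent along the principal axis of the CA cloud
  cc <- sweep(ca, 2, colMeans(ca))
  pc1 <- svd(cc, nu = 0, nv = 1)$v[, 1]
  extent <- diff(range(cc %*% pc1))
  cls <- if (rung_ok && sheet_frac >= 0.25) "beta_solenoid"
  else if (helix_frac >= 0.6 && extent / n >= helix_extent_min) "alpha_helical"
  else if (max(helix_frac, sheet_frac) < 0.25 && !rung_ok) "none"
  else "other"
  attr(cls, "details") <- list(median_rung = med, cv_rung = cv,
                               helix_frac = helix_frac,
                               sheet_frac = sheet_frac,
                               axis_extent_per_residue = extent / n)
  cls
}
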