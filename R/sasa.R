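# Shrake-Rupley solvent-accessible surface area with a deterministic
# Fibonacci-spiral point set, plus relative (normalized) SASA at residue and
# side-chain level.

# deterministic quasi-uniform points on the unit sphere (golden-angle spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# per-atom accessible area for coordinates `xyz` (n x 3) with radii `rad`
.atom_sasa <- function(xyz, rad, probe = 1.4, n_points = 960L) {
  n <- nrow(xyz)
  S <- .sphere_points(n_points)
  out <- numeric(n)
  if (n > 1) {
    d2 <- as.matrix(stats::dist(xyz))^2
  } else d2 <- matrix(0, 1, 1)
  rp <- rad + probe
  for (i in seq_len(n)) {
    cutoff2 <- (rp[i] + rp)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    pts <- sweep(S * rp[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dd <- (pts[free, 1] - xyz[j, 1])^2 + (pts[free, 2] - xyz[j, 2])^2 +
            (pts[free, 3] - xyz[j, 3])^2
      free[free] <- dd >= rp[j]^2
    }
    out[i] <- 4 * pi * rp[i]^2 * sum(free) / n_points
  }
  out
}

# SASA radii for a model: element radii, with united-group radii for the
# reduced (forged) representation's CB and side-chain tip pseudo-atoms
.model_radii <- function(model, radii = c("auto", "element", "group")) {
  radii <- match.arg(radii)
  a <- model$atoms
  vdw <- vdw_radii()
  unknown <- setdiff(unique(a$element), names(vdw))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  r <- unname(vdw[a$element])
  reduced <- max(table(a$resno)) <= 6
  use_group <- radii == "group" || (radii == "auto" && reduced)
  if (use_group) {
    if ("radius" %in% names(a) && !any(is.na(a$radius))) return(a$radius)
    bb <- a$name %in% c("N", "CA", "C", "O")
    r[!bb & a$name == "CB"] <- .CB_RADIUS
    tip <- !bb & a$name != "CB"
    r[tip] <- ifelse(a$res1[tip] %in% names(.SC_TIP_RADIUS),
                     .SC_TIP_RADIUS[a$res1[tip]], .CB_RADIUS)
  }
  r
}

#' Solvent-accessible surface area per residue
#'
#' Shrake-Rupley sphere sampling with a deterministic golden-spiral point
#' set. Returns absolute and relative SASA at whole-residue and side-chain
#' level; relative values divide by the same quantity computed for the
#' residue extracted in isolation, which makes the normalization consistent
#' across full-atom and reduced (forged) representations. A fixed full-atom
#' Gly-X-Gly reference is available via `reference = "gxg"`.
#'
#' For glycine the CA atom stands in for the side chain.
#'
#' @param model A [structure_model()].
#' @param probe_radius Probe radius, Angstrom (default 1.4).
#' @param n_points Sphere sample points per atom (default 960).
#' @param radii `"auto"` (element radii, united-group radii for reduced
#'   models), `"element"`, or `"group"`.
#' @param reference `"isolated"` (default) or `"gxg"` for the fixed
#'   full-atom maxima table.
#' @return data.frame with columns `resno`, `res1`, `abs_sasa`, `rel_sasa`,
#'   `sc_abs_sasa`, `sc_rel_sasa`; per-atom areas in attribute `atom_sasa`.
#' @export
sasa <- function(model, probe_radius = 1.4, n_points = 960L,
                 radii = c("auto", "element", "group"),
                 reference = c("isolated", "gxg")) {
  reference <- match.arg(reference)
  a <- model$atoms
  r <- .model_radii(model, radii)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  area <- .atom_sasa(xyz, r, probe_radius, n_points)

  idx <- residue_atom_index(model)
  nres <- length(idx)
  resno <- residue_numbers(model)
  res1 <- residue_codes(model)
  abs_sasa <- rel_sasa <- sc_abs <- sc_rel <- numeric(nres)
  ref_cache <- new.env(parent = emptyenv())
  for (k in seq_len(nres)) {
    i <- idx[[k]]
    sc <- i[!(a$name[i] %in% c("N", "CA", "C", "O"))]
    if (!length(sc)) sc <- i[a$name[i] == "CA"]
    abs_sasa[k] <- sum(area[i])
    sc_abs[k] <- sum(area[sc])
    key <- paste(res1[k], paste(a$name[i], collapse = ","),
                 paste(round(r[i], 3), collapse = ","))
    ref <- if (!is.null(ref_cache[[key]])) ref_cache[[key]] else {
      iso <- .atom_sasa(xyz[i, , drop = FALSE], r[i], probe_radius, n_points)
      sc_local <- match(sc, i)
      v <- c(sum(iso), sum(iso[sc_local]))
      ref_cache[[key]] <- v
      v
    }
    if (reference == "gxg") ref[1] <- unname(.MAX_ASA_GXG[res1[k]])
    rel_sasa[k] <- if (ref[1] > 0) abs_sasa[k] / ref[1] else 0
    sc_rel[k] <- if (ref[2] > 0) sc_abs[k] / ref[2] else 0
  }
  out <- data.frame(resno = resno, res1 = res1, abs_sasa = abs_sasa,
                    rel_sasa = rel_sasa, sc_abs_sasa = sc_abs,
                    sc_rel_sasa = sc_rel, stringsAsFactors = FALSE)
  attr(out, "atom_sasa") <- area
  attr(out, "radii") <- r
  out
}
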