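# Synthetic structure forge: parametric beta-solenoid models of tandem
# repeats, ideal alpha-helix decoys and disordered-coil decoys, with
# injectable implausible features (buried charged stacks, surface
# hydrophobics, steric clashes) and pLDDT annotation. Stands in for
# predictor output so every audit stage is testable without running a
# predictor.
#
# Residues are reduced to backbone N, CA, C, O plus CB and a single
# side-chain terminal group pseudo-atom (charge centre for D/E/K/R/H, ring
# centroid for F/W/Y, functional-group centre otherwise). Glycine has no
# side chain, alanine only CB. Group pseudo-atoms carry united-group SASA
# radii (see sasa()); clash detection always uses element radii.

.CA_STEP <- 3.8       # consecutive C-alpha distance, Angstrom
# closest approach of side-chain tips to the core set: stadium side walls
# have parallel inward normals and interdigitate deeply; cap/circle regions
# have converging normals and need more clearance
.MIN_CORE_DEPTH_SIDE <- 1.6
.MIN_CORE_DEPTH_CAP <- 2.2

# distance from CB to the side-chain terminal group centre, Angstrom
.SC_REACH <- c(A = NA, R = 2.7, N = 1.0, D = 1.0, C = 0.9, Q = 1.7, E = 1.7,
               G = NA, H = 1.4, I = 1.2, L = 1.3, K = 2.3, M = 1.8, F = 1.9,
               P = 0.7, S = 0.6, T = 0.7, W = 2.3, Y = 2.4, V = 0.8)
.SC_TIP_NAME <- c(R = "NH1", N = "OD1", D = "OD1", C = "SG", Q = "OE1",
                  E = "OE1", H = "NE2", I = "CD1", L = "CD1", K = "NZ",
                  M = "SD", F = "CZ", P = "CG", S = "OG", T = "OG1",
                  W = "CZ2", Y = "OH", V = "CG1")
.SC_TIP_ELEM <- c(R = "N", N = "O", D = "O", C = "S", Q = "O", E = "O",
                  H = "N", I = "C", L = "C", K = "N", M = "S", F = "C",
                  P = "C", S = "O", T = "O", W = "C", Y = "O", V = "C")
# united-group SASA radii for the terminal pseudo-atoms (whole chemical
# group represented by one sphere) and the CB united CH2
.SC_TIP_RADIUS <- c(R = 2.2, N = 2.0, D = 2.1, C = 1.9, Q = 2.0, E = 2.1,
                    H = 2.2, I = 2.0, L = 2.0, K = 2.0, M = 2.0, F = 2.6,
                    P = 1.9, S = 1.8, T = 1.9, W = 2.7, Y = 2.6, V = 2.0)
.CB_RADIUS <- 2.0

#' Specify a parametric beta-solenoid model
#'
#' Describes the solenoid to forge: the repeat sequence, the rise per rung
#' (one rung = one repeat unit), the cross-section, which unit positions
#' point into the packed core, the pLDDT profile and any injected
#' implausible features.
#'
#' The cross-section is a stadium (flattened oval) when `n_sides = 2`: two
#' straight beta-sheet walls whose inward side chains interdigitate across a
#' packed core, the common flattened architecture of natural beta-solenoids.
#' `n_sides >= 3` gives a rounded regular polygon around a central axis.
#' Short units that cannot span the stadium fall back to a circular
#' cross-section automatically.
#'
#' @param sequence A [tandem()] repeat sequence (`n_copies` = rungs).
#' @param rise_per_rung Axial rise per rung, Angstrom (default 4.8).
#' @param n_sides Cross-section sides (default 2 = two packed sheets).
#' @param handedness `"left"` or `"right"`.
#' @param inward_positions Integer vector of 0-based unit positions whose
#'   side chains point into the core. Default: every other position of the
#'   unit (alternating in/out, as in a beta-sheet).
#' @param plddt_profile Per-residue pLDDT (0-100); default constant 90.
#' @param injections List of [feature_injection()] objects.
#' @param core_half_width Half-width of the stadium core slot, Angstrom.
#' @return A `solenoid_spec` object.
#' @export
solenoid_spec <- function(sequence, rise_per_rung = 4.8, n_sides = 2,
                          handedness = c("left", "right"),
                          inward_positions = NULL, plddt_profile = NULL,
                          injections = list(), core_half_width = 4.6) {
  stopifnot(inherits(sequence, "repeat_sequence"))
  handedness <- match.arg(handedness)
  L <- nchar(sequence$unit)
  if (rise_per_rung <= 0) stop("rise_per_rung must be > 0")
  if (n_sides < 2) stop("n_sides must be >= 2")
  if (L < n_sides) stop("unit length must be >= n_sides")
  if (is.null(inward_positions)) inward_positions <- seq(0, L - 1, by = 2)
  inward_positions <- as.integer(inward_positions)
  if (any(inward_positions < 0 | inward_positions >= L))
    stop("inward_positions must be 0-based unit positions in [0, ", L - 1, ")")
  n <- nchar(sequence$full)
  if (is.null(plddt_profile)) plddt_profile <- rep(90, n)
  if (length(plddt_profile) != n)
    stop("plddt_profile length must equal the full sequence length (", n, ")")
  if (any(plddt_profile < 0 | plddt_profile > 100))
    stop("pLDDT values must be in [0, 100]")
  for (inj in injections) {
    if (!inherits(inj, "feature_injection"))
      stop("injections must be feature_injection objects")
    if (inj$unit_position >= L)
      stop("injection unit_position ", inj$unit_position,
           " outside unit of length ", L)
  }
  structure(list(sequence = sequence, rise_per_rung = rise_per_rung,
                 n_sides = n_sides, handedness = handedness,
                 inward_positions = sort(unique(inward_positions)),
                 plddt_profile = plddt_profile, injections = injections,
                 core_half_width = core_half_width),
            class = "solenoid_spec")
}

#' Describe an implausible feature to inject into a forged solenoid
#'
#' Kinds: `charged_stack` places `residue_code` (D/E/K/R/H) at
#' `unit_position` in every rung, pointing into the core (a buried same-sign
#' charge stack); `compensating_counter_charge` places an opposite-sign
#' residue whose charge centre is brought within compensation distance of
#' the stack; `surface_hydrophobic` places a hydrophobic residue pointing
#' outward at every rung; `clash` displaces the side-chain tips of
#' `unit_position` pairwise so that non-bonded atoms overlap.
#'
#' @param kind One of `"charged_stack"`, `"surface_hydrophobic"`, `"clash"`,
#'   `"compensating_counter_charge"`.
#' @param unit_position 0-based unit position.
#' @param residue_code 1-letter residue code (required except for `clash`).
#' @param parameters Optional list (e.g. `target_dist` for compensation).
#' @export
feature_injection <- function(kind = c("charged_stack", "surface_hydrophobic",
                                       "clash", "compensating_counter_charge"),
                              unit_position, residue_code = NULL,
                              parameters = list()) {
  kind <- match.arg(kind)
  if (unit_position < 0) stop("unit_position must be >= 0")
  if (kind != "clash") {
    if (is.null(residue_code)) stop("injection '", kind, "' needs residue_code")
    ok <- switch(kind,
      charged_stack = c(.NEG_CHARGED, .POS_CHARGED),
      compensating_counter_charge = c(.NEG_CHARGED, .POS_CHARGED),
      surface_hydrophobic = .HYDROPHOBIC)
    if (!residue_code %in% ok)
      stop("residue '", residue_code, "' invalid for injection '", kind, "'")
  }
  structure(list(kind = kind, unit_position = as.integer(unit_position),
                 residue_code = residue_code, parameters = parameters),
            class = "feature_injection")
}

# ---- cross-section construction -------------------------------------------

# radius of the cross-section boundary at polar angle phi
.xsec_radius <- function(phi, shape) {
  if (shape$type == "circle") return(rep(shape$R, length(phi)))
  if (shape$type == "polygon")
    return(shape$R0 * (1 - shape$e * cos(shape$k * phi)))
  # stadium: straight sides at y = +/- rho for |x| <= a/2, semicircle caps
  rho <- shape$rho; a <- shape$a
  vapply(phi, function(p) {
    s <- sin(p); c <- cos(p)
    if (abs(s) > 1e-12 && abs(rho * c / s) <= a / 2) rho / abs(s)
    else (a / 2) * abs(c) + sqrt(max(rho^2 - (a / 2)^2 * s^2, 0))
  }, numeric(1))
}

.xsec_point <- function(phi, shape) {
  r <- .xsec_radius(phi, shape)
  cbind(r * cos(phi), r * sin(phi))
}

# march L equal chords (in-plane length c_xy, axial step dz each) around the
# boundary; returns the L angles if the loop closes at exactly 2*pi for the
# given shape, plus the closure error
.march_angles <- function(shape, L, c_xy, dz) {
  step3d <- function(phi0, d) {
    p0 <- .xsec_point(phi0, shape)
    f <- function(dphi) {
      p1 <- .xsec_point(phi0 + dphi, shape)
      sqrt(sum((p1 - p0)^2) + dz^2) - sqrt(c_xy^2 + dz^2)
    }
    stats::uniroot(f, c(1e-4, 2.6), tol = 1e-10)$root
  }
  phi <- numeric(L + 1)
  phi[1] <- pi / 2
  for (k in seq_len(L)) phi[k + 1] <- phi[k] + step3d(phi[k])
  list(phi = phi[seq_len(L)], closure = phi[L + 1] - phi[1] - 2 * pi)
}

# build the in-plane ring of L points with equal 3D chords ~ 3.8 A
.build_ring <- function(L, rise, n_sides, core_half_width) {
  dz <- rise / L
  c_xy <- sqrt(.CA_STEP^2 - dz^2)
  if (n_sides == 2) {
    rho <- core_half_width
    # a stadium needs perimeter beyond its caps; otherwise use a circle
    if (L * c_xy > 2 * pi * rho + 2.0) {
      closure_for <- function(a) {
        .march_angles(list(type = "stadium", rho = rho, a = a), L, c_xy, dz)$closure
      }
      a <- stats::uniroot(closure_for, c(1e-3, L * c_xy / 2), tol = 1e-8)$root
      shape <- list(type = "stadium", rho = rho, a = a)
      phi <- .march_angles(shape, L, c_xy, dz)$phi
      return(list(shape = shape, xy = .xsec_point(phi, shape)))
    }
    # fall through to circle
  } else if (n_sides >= 3) {
    e <- 0.08
    closure_for <- function(R0) {
      .march_angles(list(type = "polygon", R0 = R0, e = e, k = n_sides),
                    L, c_xy, dz)$closure
    }
    lo <- c_xy / (2 * sin(pi / L)) * 0.6
    hi <- c_xy / (2 * sin(pi / L)) * 1.6
    R0 <- stats::uniroot(closure_for, c(lo, hi), tol = 1e-8)$root
    shape <- list(type = "polygon", R0 = R0, e = e, k = n_sides)
    phi <- .march_angles(shape, L, c_xy, dz)$phi
    return(list(shape = shape, xy = .xsec_point(phi, shape)))
  }
  R <- c_xy / (2 * sin(pi / L))
  shape <- list(type = "circle", R = R)
  phi <- pi / 2 + 2 * pi * (seq_len(L) - 1) / L
  list(shape = shape, xy = .xsec_point(phi, shape))
}

# nearest point of the core (medial) set for a cross-section point, plus the
# local clearance floor for side-chain tips
.core_point <- function(p, shape) {
  if (shape$type == "stadium" && abs(p[1]) < shape$a / 2 - 1e-9)
    list(xy = c(p[1], 0), min_depth = .MIN_CORE_DEPTH_SIDE)
  else if (shape$type == "stadium")
    list(xy = c(sign(p[1]) * shape$a / 2, 0), min_depth = .MIN_CORE_DEPTH_CAP)
  else list(xy = c(0, 0), min_depth = .MIN_CORE_DEPTH_CAP)
}

# ---- backbone and side-chain placement ------------------------------------

# N, C, O positions from a CA trace
.place_backbone <- function(ca) {
  n <- nrow(ca)
  unit <- function(v) {
    nv <- sqrt(sum(v^2)); if (nv < 1e-9) c(1, 0, 0) else v / nv
  }
  N <- C <- O <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    u <- if (i > 1) unit(ca[i, ] - ca[i - 1, ]) else
      unit(ca[min(i + 1, n), ] - ca[i, ])
    v <- if (i < n) unit(ca[i + 1, ] - ca[i, ]) else u
    if (i == 1 && n > 1) u <- v
    N[i, ] <- ca[i, ] - 1.46 * u
    C[i, ] <- ca[i, ] + 1.52 * v
    w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    if (sqrt(sum(w^2)) < 1e-6) {
      w <- c(-u[2], u[1], 0)
      if (sqrt(sum(w^2)) < 1e-6) w <- c(0, -u[3], u[2])
    }
    # carbonyl O: perpendicular to the chain plane, tilted slightly back so
    # it clears the next residue's amide
    O[i, ] <- C[i, ] + 1.23 * unit(unit(w) - 0.3 * v)
  }
  list(N = N, C = C, O = O)
}

# assemble the atoms data.frame for one residue (reduced representation)
.residue_atoms <- function(resno, res1, ca, N, C, O, cb = NULL, tip = NULL,
                           plddt = 0) {
  nm <- c("N", "CA", "C", "O"); el <- c("N", "C", "C", "O")
  xyz <- rbind(N, ca, C, O)
  rad <- unname(vdw_radii()[el])
  if (!is.null(cb)) {
    nm <- c(nm, "CB"); el <- c(el, "C"); xyz <- rbind(xyz, cb)
    rad <- c(rad, .CB_RADIUS)
  }
  if (!is.null(tip)) {
    nm <- c(nm, .SC_TIP_NAME[[res1]]); el <- c(el, .SC_TIP_ELEM[[res1]])
    xyz <- rbind(xyz, tip); rad <- c(rad, .SC_TIP_RADIUS[[res1]])
  }
  data.frame(resno = resno, res1 = res1, name = nm, element = el,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], b = plddt,
             radius = rad, stringsAsFactors = FALSE)
}

#' Forge a parametric beta-solenoid structure
#'
#' Builds one residue per sequence position with backbone N, CA, C, O plus
#' CB and a side-chain terminal pseudo-atom, on a helical path whose
#' cross-section repeats every rung: consecutive CA atoms are 3.8 Angstrom
#' apart and residue i sits exactly `rise_per_rung` above residue i - L.
#' Inward unit positions point their side chains into the packed core;
#' injected features (charged stacks, surface hydrophobics, clashes,
#' compensating counter-charges) are realised geometrically.
#'
#' @param spec A [solenoid_spec()].
#' @return A [structure_model()] (atoms carry a `radius` column with the
#'   united-group SASA radii of the reduced representation).
#' @export
build_solenoid <- function(spec) {
  stopifnot(inherits(spec, "solenoid_spec"))
  L <- nchar(spec$sequence$unit)
  n_rungs <- spec$sequence$n_copies
  if (n_rungs < 2) stop("a solenoid needs at least 2 rungs")

  # realise injections in the sequence and orientation sets
  unit <- strsplit(spec$sequence$unit, "")[[1]]
  inward <- spec$inward_positions
  clash_pos <- integer(0)
  comp <- list()
  for (inj in spec$injections) {
    p <- inj$unit_position
    if (inj$kind == "charged_stack") {
      unit[p + 1] <- inj$residue_code
      inward <- sort(unique(c(inward, p)))
    } else if (inj$kind == "compensating_counter_charge") {
      unit[p + 1] <- inj$residue_code
      inward <- sort(unique(c(inward, p)))
      comp <- c(comp, list(inj))
    } else if (inj$kind == "surface_hydrophobic") {
      unit[p + 1] <- inj$residue_code
      inward <- setdiff(inward, p)
    } else if (inj$kind == "clash") {
      clash_pos <- c(clash_pos, p)
    }
  }

  ring <- .build_ring(L, spec$rise_per_rung, spec$n_sides, spec$core_half_width)
  xy <- ring$xy
  if (spec$handedness == "right") xy[, 2] <- -xy[, 2]
  n <- L * n_rungs
  dz <- spec$rise_per_rung / L
  idx <- seq_len(n) - 1L
  ca <- cbind(xy[(idx %% L) + 1, 1], xy[(idx %% L) + 1, 2], idx * dz)
  bb <- .place_backbone(ca)

  rows <- vector("list", n)
  tip_index <- rep(NA_integer_, n)   # row offset of the tip atom per residue
  for (i in seq_len(n)) {
    j <- (i - 1) %% L               # 0-based unit position
    res1 <- unit[j + 1]
    p2 <- xy[j + 1, ]
    core <- .core_point(p2, ring$shape)
    dirv <- core$xy - p2
    depth_avail <- sqrt(sum(dirv^2))
    d2 <- if (depth_avail > 1e-9) dirv / depth_avail else c(0, 1)
    is_in <- j %in% inward
    dir3 <- c(if (is_in) d2 else -d2, 0)
    cb <- tip <- NULL
    if (res1 != "G") cb <- ca[i, ] + 1.53 * dir3
    reach <- .SC_REACH[[res1]]
    if (!is.na(reach)) {
      ext <- 1.53 + reach
      if (is_in) ext <- min(ext, max(depth_avail - core$min_depth, 1.8))
      tip <- ca[i, ] + ext * dir3
    }
    rows[[i]] <- .residue_atoms(i, res1, ca[i, ], bb$N[i, ], bb$C[i, ],
                                bb$O[i, ], cb, tip, spec$plddt_profile[i])
    if (!is.null(tip)) tip_index[i] <- nrow(rows[[i]])
  }
  atoms <- do.call(rbind, rows)
  # absolute row of each residue's tip atom
  offs <- c(0, cumsum(vapply(rows, nrow, integer(1))))
  tip_row <- ifelse(is.na(tip_index), NA_integer_, offs[seq_len(n)] + tip_index)

  # clash injection: pull successive-rung tips of the position together
  for (p in clash_pos) {
    for (r in seq(1, n_rungs - 1, by = 2)) {
      i1 <- (r - 1) * L + p + 1; i2 <- r * L + p + 1
      r1 <- tip_row[i1]; r2 <- tip_row[i2]
      if (is.na(r1) || is.na(r2)) next
      atoms$z[r1] <- atoms$z[r1] + 1.55
      atoms$z[r2] <- atoms$z[r2] - 1.55
    }
  }
  # compensation: nudge the counter-charge tips to within reach of the
  # nearest same-rung stack member tip
  if (length(comp)) {
    stack_pos <- unlist(lapply(spec$injections, function(x)
      if (x$kind == "charged_stack") x$unit_position else NULL))
    for (inj in comp) {
      target <- inj$parameters$target_dist %||% 3.2
      for (r in seq_len(n_rungs)) {
        i_c <- (r - 1) * L + inj$unit_position + 1
        rc <- tip_row[i_c]
        if (is.na(rc) || length(stack_pos) == 0) next
        cand <- tip_row[(r - 1) * L + stack_pos + 1]
        cand <- cand[!is.na(cand)]
        if (!length(cand)) next
        pc <- as.numeric(atoms[rc, c("x", "y", "z")])
        dists <- apply(atoms[cand, c("x", "y", "z"), drop = FALSE], 1,
                       function(q) sqrt(sum((q - pc)^2)))
        q <- as.numeric(atoms[cand[which.min(dists)], c("x", "y", "z")])
        d <- sqrt(sum((q - pc)^2))
        if (d > target) {
          newp <- q + (pc - q) / d * target
          atoms$x[rc] <- newp[1]; atoms$y[rc] <- newp[2]; atoms$z[rc] <- newp[3]
        }
      }
    }
  }
  seq_full <- paste(rep(paste(unit, collapse = ""), n_rungs), collapse = "")
  structure_model(atoms, chain = "A",
                  provenance = list(forge = "solenoid", unit_length = L,
                                    n_rungs = n_rungs,
                                    sequence = seq_full,
                                    inward_positions = inward))
}

#' Forge an ideal alpha-helix decoy
#'
#' A straight ideal alpha helix: 1.5 Angstrom rise and 100 degrees rotation
#' per residue, giving consecutive CA distances of 3.8 Angstrom. Side chains
#' point radially outward.
#'
#' @param seq Residue string or [tandem()] object.
#' @param plddt_profile Per-residue pLDDT (default constant 85).
#' @return A [structure_model()].
#' @export
build_helix <- function(seq, plddt_profile = NULL) {
  full <- if (inherits(seq, "repeat_sequence")) seq$full else seq
  if (!is.character(full) || nchar(full) < 1) stop("empty sequence")
  res <- strsplit(full, "")[[1]]
  n <- length(res)
  if (is.null(plddt_profile)) plddt_profile <- rep(85, n)
  if (length(plddt_profile) != n) stop("plddt_profile length mismatch")
  rise <- 1.5; twist <- 100 * pi / 180
  r <- sqrt(.CA_STEP^2 - rise^2) / (2 * sin(twist / 2))
  i <- seq_len(n) - 1
  ca <- cbind(r * cos(i * twist), r * sin(i * twist), i * rise)
  bb <- .place_backbone(ca)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    dir3 <- c(cos((k - 1) * twist), sin((k - 1) * twist), 0)
    cb <- if (res[k] != "G") ca[k, ] + 1.53 * dir3 else NULL
    reach <- .SC_REACH[[res[k]]]
    tip <- if (!is.na(reach)) ca[k, ] + (1.53 + reach) * dir3 else NULL
    rows[[k]] <- .residue_atoms(k, res[k], ca[k, ], bb$N[k, ], bb$C[k, ],
                                bb$O[k, ], cb, tip, plddt_profile[k])
  }
  structure_model(do.call(rbind, rows), chain = "A",
                  provenance = list(forge = "helix", sequence = full))
}

#' Forge a disordered-coil decoy
#'
#' A seeded self-avoiding persistent random walk of CA atoms: step 3.8
#' Angstrom, all non-adjacent CA pairs at least `min_sep` apart.
#'
#' @param seq Residue string or [tandem()] object.
#' @param seed Integer seed (determinism: same seed, same coordinates).
#' @param plddt_profile Per-residue pLDDT (default constant 40).
#' @param min_sep Minimum non-adjacent CA distance (default 4.5).
#' @param max_tries Bounded retries per step before the build fails.
#' @return A [structure_model()].
#' @export
build_coil <- function(seq, seed = 1L, plddt_profile = NULL, min_sep = 5.2,
                       max_tries = 200L) {
  full <- if (inherits(seq, "repeat_sequence")) seq$full else seq
  if (!is.character(full) || nchar(full) < 1) stop("empty sequence")
  res <- strsplit(full, "")[[1]]
  n <- length(res)
  if (is.null(plddt_profile)) plddt_profile <- rep(40, n)
  if (length(plddt_profile) != n) stop("plddt_profile length mismatch")
  ca <- with_seed(seed, {
    m <- matrix(0, n, 3)
    dir <- c(1, 0, 0)
    ok <- TRUE
    for (i in seq(2, length.out = n - 1)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand_dir <- dir + 0.9 * stats::rnorm(3)
        cand_dir <- cand_dir / sqrt(sum(cand_dir^2))
        cand <- m[i - 1, ] + .CA_STEP * cand_dir
        if (i > 2) {
          prev <- m[seq_len(i - 2), , drop = FALSE]
          d2 <- rowSums(sweep(prev, 2, cand)^2)
          if (min(d2) < min_sep^2) next
        }
        m[i, ] <- cand; dir <- cand_dir; placed <- TRUE; break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (!ok) stop("coil placement failed after bounded retries; ",
                  "try another seed")
    m
  })
  bb <- .place_backbone(ca)
  rows <- vector("list", n)
  unit3 <- function(v) v / max(sqrt(sum(v^2)), 1e-9)
  for (k in seq_len(n)) {
    u <- if (k > 1) ca[k, ] - ca[k - 1, ] else ca[min(k + 1, n), ] - ca[k, ]
    w <- c(-u[2], u[1], 0.3)
    dir3 <- unit3(w)
    cb <- if (res[k] != "G") ca[k, ] + 1.53 * dir3 else NULL
    reach <- .SC_REACH[[res[k]]]
    tip <- if (!is.na(reach)) ca[k, ] + (1.53 + reach) * dir3 else NULL
    rows[[k]] <- .residue_atoms(k, res[k], ca[k, ], bb$N[k, ], bb$C[k, ],
                                bb$O[k, ], cb, tip, plddt_profile[k])
  }
  structure_model(do.call(rbind, rows), chain = "A",
                  provenance = list(forge = "coil", sequence = full, seed = seed))
}

#' Annotate a model with a pLDDT profile in a predictor dialect
#'
#' `residue_bfactor` (AF2-style) writes each residue's value to all of its
#' atoms. `atomic_bfactor` (AF3-style) perturbs per-atom values around the
#' residue value with seeded, mean-preserving jitter (the per-residue atom
#' mean equals the profile value exactly), emulating atomic-pLDDT files.
#'
#' @param model A [structure_model()].
#' @param profile Per-residue pLDDT values in `[0, 100]`.
#' @param dialect `"residue_bfactor"` or `"atomic_bfactor"`.
#' @param seed Seed for the atomic jitter.
#' @param jitter Half-width of the atomic perturbation (default 2).
#' @return The annotated model.
#' @export
annotate_plddt <- function(model, profile,
                           dialect = c("residue_bfactor", "atomic_bfactor"),
                           seed = 1L, jitter = 2) {
  dialect <- match.arg(dialect)
  nres <- n_residues(model)
  if (length(profile) != nres)
    stop("profile length ", length(profile), " != residue count ", nres)
  if (any(profile < 0 | profile > 100))
    stop("pLDDT values must be in [0, 100]")
  idx <- residue_atom_index(model)
  b <- model$atoms$b
  if (dialect == "residue_bfactor") {
    for (k in seq_len(nres)) b[idx[[k]]] <- profile[k]
  } else {
    b <- with_seed(seed, {
      for (k in seq_len(nres)) {
        i <- idx[[k]]
        h <- min(jitter, profile[k], 100 - profile[k])
        eps <- stats::runif(length(i), -h, h)
        eps <- eps - mean(eps)            # mean-preserving
        b[i] <- profile[k] + eps
      }
      b
    })
  }
  model$atoms$b <- b
  model$provenance$plddt_dialect <- dialect
  model
}
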