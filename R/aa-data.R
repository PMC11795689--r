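# Shared amino-acid reference data: propensity pools, Chou-Fasman propensities,
# hydropathy, charge/hydrophobicity sets, van der Waals radii, max-SASA
# references. All keyed by 1-letter residue codes.

.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Secondary-structure propensity pools
#'
#' The three residue pools used to bias random repeat units towards beta,
#' alpha or neither secondary structure. The pools are pairwise disjoint and
#' jointly cover the 20 standard amino acids (7 beta, 7 alpha, 6 neutral).
#'
#' @return Named list with character vectors `beta`, `alpha`, `neutral`.
#' @examples
#' amino_pools()$beta
#' @export
amino_pools <- function() {
  list(
    beta    = c("C", "F", "I", "T", "V", "W", "Y"),
    alpha   = c("A", "E", "K", "M", "Q", "R", "L"),
    neutral = c("G", "N", "D", "P", "H", "S")
  )
}

#' Default secondary-structure propensity table
#'
#' Chou-Fasman helix (`p_alpha`) and sheet (`p_beta`) conformational
#' propensities for the 20 standard residues. Values are dimensionless
#' (1 = indifferent). An alternative table can be loaded from TSV with
#' [read_propensity_table()].
#'
#' @return data.frame with columns `res`, `p_alpha`, `p_beta` (20 rows).
#' @export
default_propensity_table <- function() {
  data.frame(
    res = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    p_alpha = c(1.42, 0.98, 0.67, 1.01, 0.70, 1.11, 1.51, 0.57, 1.00, 1.08,
                1.21, 1.16, 1.45, 1.13, 0.57, 0.77, 0.83, 1.08, 0.69, 1.06),
    p_beta  = c(0.83, 0.93, 0.89, 0.54, 1.19, 1.10, 0.37, 0.75, 0.87, 1.60,
                1.30, 0.74, 1.05, 1.38, 0.55, 0.75, 1.19, 1.37, 1.47, 1.70),
    stringsAsFactors = FALSE
  )
}

#' Read a propensity table from TSV
#'
#' @param path TSV file with columns `res`, `p_alpha`, `p_beta`.
#' @return data.frame as [default_propensity_table()].
#' @export
read_propensity_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("res", "p_alpha", "p_beta")
  if (!all(need %in% names(tab)))
    stop("propensity table must have columns: ", paste(need, collapse = ", "))
  if (!setequal(tab$res, .AA1))
    stop("propensity table must cover exactly the 20 standard residue codes")
  if (any(tab$p_alpha <= 0) || any(tab$p_beta <= 0))
    stop("propensity values must be > 0")
  tab
}

# Kyte-Doolittle hydropathy (used by the default 3D/1D table heuristic)
.KD <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
         Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
         L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
         S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# residue groups used by the audit
.NEG_CHARGED <- c("D", "E")
.POS_CHARGED <- c("K", "R", "H")   # His configurable at call sites
.AROMATIC    <- c("F", "W", "Y", "H")
.HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "Y", "C")

#' Van der Waals radii by element
#'
#' Bondi-style radii (Angstrom) for the elements expected in predictor
#' output and forged models.
#'
#' @return Named numeric vector.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)
}

# Theoretical Gly-X-Gly maximum accessible surface areas (A^2), full-atom
# scale (Tien et al. style). Used when relative SASA is requested against the
# fixed full-atom reference rather than the representation-adaptive default.
.MAX_ASA_GXG <- c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
                  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
                  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
                  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)

# evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# global RNG stream is untouched
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
          rm(".Random.seed", envir = .GlobalEnv)
      } else assign(".Random.seed", old, envir = .GlobalEnv)
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
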