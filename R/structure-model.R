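# structure_model: ordered residues with atoms (name, element, xyz, B-factor),
# one chain, optional per-residue pLDDT cache and provenance.

#' Construct a structure model
#'
#' @param atoms data.frame with columns `resno` (1-based author numbering,
#'   non-decreasing), `res1` (1-letter residue code), `name` (atom name),
#'   `element`, `x`, `y`, `z` (Angstrom), `b` (B-factor / pLDDT).
#' @param chain Chain identifier (default "A").
#' @param provenance Optional list (e.g. `file`, `format`, `dialect`).
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(atoms, chain = "A", provenance = list()) {
  need <- c("resno", "res1", "name", "element", "x", "y", "z", "b")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty polymer: model has no atoms")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  resno <- unique(atoms$resno)
  if (any(diff(resno) <= 0))
    stop("residue numbering must be strictly increasing")
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, chain = chain, provenance = provenance),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d residues, %d atoms, chain %s\n",
              n_residues(x), nrow(x$atoms), x$chain))
  if (!is.null(x$provenance$file))
    cat("  source:", x$provenance$file, "\n")
  invisible(x)
}

#' Number of residues in a model
#' @param model structure_model.
#' @export
n_residues <- function(model) length(unique(model$atoms$resno))

#' Residue numbers (author numbering) in order
#' @param model structure_model.
#' @export
residue_numbers <- function(model) unique(model$atoms$resno)

#' Residue codes (1-letter) in residue order
#' @param model structure_model.
#' @export
residue_codes <- function(model) {
  model$atoms$res1[!duplicated(model$atoms$resno)]
}

#' Model sequence as a single string
#' @param model structure_model.
#' @export
model_sequence <- function(model) paste(residue_codes(model), collapse = "")

#' C-alpha coordinate matrix (one row per residue)
#'
#' Residues lacking a CA atom get their first atom's coordinates.
#'
#' @param model structure_model.
#' @return n x 3 numeric matrix.
#' @export
ca_xyz <- function(model) {
  a <- model$atoms
  idx <- vapply(split(seq_len(nrow(a)), factor(a$resno, levels = unique(a$resno))),
                function(i) {
                  j <- i[a$name[i] == "CA"]
                  if (length(j)) j[1] else i[1]
                }, integer(1))
  m <- as.matrix(a[idx, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

# list of per-residue atom index vectors, in residue order
residue_atom_index <- function(model) {
  a <- model$atoms
  split(seq_len(nrow(a)), factor(a$resno, levels = unique(a$resno)))
}

# apply rigid transform (rotation matrix R, translation t) to a model
transform_model <- function(model, R, t) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new <- sweep(xyz %*% t(R), 2, -t)
  model$atoms$x <- new[, 1]; model$atoms$y <- new[, 2]; model$atoms$z <- new[, 3]
  model
}
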