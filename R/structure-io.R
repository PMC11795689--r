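# PDB / mmCIF reading and writing and the pLDDT extraction conventions of the
# AlphaFold family of predictors. Reading goes through bio3d (read.pdb /
# read.cif); writers emit fixed-width PDB and canonical atom_site mmCIF with
# the pLDDT in the B-factor column.

#' Read a structure file into a [structure_model()]
#'
#' Reads the first model and (by default) the first polymer chain of a PDB or
#' mmCIF file. B-factors (pLDDT for predictor output) and insertion codes are
#' preserved. Gzip-compressed files (`.gz`) are supported.
#'
#' @param path File path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension).
#' @param chain Chain id to keep; `NULL` keeps the first chain present.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           chain = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  real <- path
  base <- path
  if (grepl("\\.gz$", path)) {
    base <- sub("\\.gz$", "", path)
    real <- tempfile(fileext = paste0(".", tools::file_ext(base)))
    on.exit(unlink(real), add = TRUE)
    writeLines(readLines(gzfile(path)), real)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(base))
    format <- switch(ext, cif = "mmcif", mmcif = "mmcif", pdb = "pdb", ent = "pdb",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass format explicitly"))
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(real, multi = FALSE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(real, verbose = FALSE)),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("empty polymer: no ATOM records in ", path)
  chains <- unique(at$chain)
  keep <- if (is.null(chain)) chains[1] else chain
  at <- at[at$chain %in% keep, , drop = FALSE]
  if (nrow(at) == 0) stop("chain '", keep, "' not present in ", path)

  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- element_from_name(at$elety[bad])
  res1 <- suppressWarnings(bio3d::aa321(at$resid))
  res1[is.na(res1)] <- "X"
  insert <- at$insert
  insert[is.na(insert)] <- ""
  # internal residue index: author numbering where strictly increasing,
  # otherwise a sequential index with author numbering kept alongside
  key <- paste(at$resno, insert)
  ridx <- cumsum(!duplicated(key) & c(TRUE, key[-1] != key[-length(key)]))
  auth <- at$resno
  resno_int <- if (all(diff(unique(auth[!duplicated(key)])) > 0) &&
                   all(insert == "")) auth else as.integer(ridx)
  atoms <- data.frame(
    resno = resno_int, res1 = res1, name = at$elety, element = toupper(elem),
    x = at$x, y = at$y, z = at$z, b = ifelse(is.na(at$b), 0, at$b),
    auth_resno = auth, insert = insert, stringsAsFactors = FALSE
  )
  structure_model(atoms, chain = keep,
                  provenance = list(file = path, format = format))
}

# infer element symbol from a PDB atom name (first alphabetic character,
# honouring two-letter elements like SE)
element_from_name <- function(name) {
  nm <- toupper(gsub("[^A-Z]", "", toupper(name)))
  vapply(nm, function(x) {
    if (startsWith(x, "SE")) "SE" else substr(x, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Write a structure model to PDB or mmCIF
#'
#' PDB output uses fixed-width ATOM records with the B-factor in columns
#' 61-66 and element in 77-78; mmCIF output writes a canonical `atom_site`
#' loop. pLDDT values stored in `b` travel in the B-factor column.
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, cif = "mmcif", mmcif = "mmcif", pdb = "pdb",
                     stop("cannot infer format from extension '.", ext, "'"))
  }
  a <- model$atoms
  res3 <- bio3d::aa123(a$res1)
  res3[is.na(res3) | res3 == "NA"] <- "UNK"
  auth <- if ("auth_resno" %in% names(a)) a$auth_resno else a$resno
  if (format == "pdb") {
    name_fmt <- ifelse(nchar(a$name) >= 4, sprintf("%-4s", a$name),
                       sprintf(" %-3s", a$name))
    lines <- sprintf(
      "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), name_fmt, res3, model$chain, auth,
      a$x, a$y, a$z, 1.00, a$b, sprintf("%2s", a$element))
    lines <- c(lines, "TER", "END")
  } else {
    fields <- c("group_PDB", "id", "type_symbol", "label_atom_id",
                "label_alt_id", "label_comp_id", "label_asym_id",
                "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                "auth_comp_id", "auth_asym_id", "auth_atom_id",
                "pdbx_PDB_model_num")
    rows <- sprintf(
      "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 %.2f ? %d %s %s %s 1",
      seq_len(nrow(a)), a$element, a$name, res3, model$chain, a$resno,
      a$x, a$y, a$z, a$b, auth, res3, model$chain, a$name)
    lines <- c("data_repeatfold", "#", "loop_",
               paste0("_atom_site.", fields), rows, "#")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Per-residue pLDDT from the B-factor column
#'
#' Two dialects are supported: `residue_bfactor` (AF2-style: every atom of a
#' residue carries the residue value; the CA atom is read, with a warned
#' fallback to the atom mean when CA is absent) and `atomic_bfactor`
#' (AF3-style: per-atom values are averaged within each residue).
#'
#' @param model A [structure_model()].
#' @param dialect `"residue_bfactor"` or `"atomic_bfactor"`.
#' @return Numeric vector, one value per residue (same scale as stored).
#' @export
residue_plddt <- function(model, dialect = c("residue_bfactor", "atomic_bfactor")) {
  dialect <- match.arg(dialect)
  a <- model$atoms
  idx <- residue_atom_index(model)
  if (dialect == "atomic_bfactor") {
    return(vapply(idx, function(i) mean(a$b[i]), numeric(1), USE.NAMES = FALSE))
  }
  missing_ca <- FALSE
  out <- vapply(idx, function(i) {
    j <- i[a$name[i] == "CA"]
    if (length(j)) a$b[j[1]] else { missing_ca <<- TRUE; mean(a$b[i]) }
  }, numeric(1), USE.NAMES = FALSE)
  if (missing_ca)
    warning("residue_bfactor dialect: CA missing in some residues; ",
            "used atom-mean fallback")
  out
}

#' Normalize pLDDT values to the 0-100 scale
#'
#' Predictors that emit pLDDT on a 0-1 scale (e.g. RoseTTAFold All-Atom) are
#' rescaled by 100; values already on 0-100 pass through unchanged. The
#' operation is idempotent.
#'
#' @param values Numeric vector of pLDDT values.
#' @return Values on the 0-100 scale.
#' @export
normalize_plddt_scale <- function(values) {
  if (any(values < 0)) stop("negative pLDDT value encountered")
  if (length(values) && max(values) <= 1.0) values * 100 else values
}

#' Mean pLDDT of a model
#'
#' Arithmetic mean of per-residue pLDDT (atom values are first averaged per
#' residue under the atomic dialect, then over residues), normalized to the
#' 0-100 scale.
#'
#' @param model A [structure_model()].
#' @param dialect Passed to [residue_plddt()].
#' @return Scalar mean pLDDT on 0-100.
#' @export
mean_plddt <- function(model, dialect = c("residue_bfactor", "atomic_bfactor")) {
  mean(normalize_plddt_scale(residue_plddt(model, dialect)))
}

#' Read a per-residue disorder-probability table
#'
#' @param path TSV with columns `residue_index`, `probability`.
#' @return Numeric vector of probabilities ordered by residue index.
#' @export
read_disorder_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("residue_index", "probability") %in% names(tab)))
    stop("disorder TSV must have columns residue_index, probability")
  p <- tab$probability[order(tab$residue_index)]
  if (any(p < 0 | p > 1)) stop("disorder probabilities must be in [0,1]")
  p
}
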