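# Sequence-design protocol: propensity-pool sampling, tandem concatenation,
# cohort designs, alanine mutants, propensity means, repeat-perfection scoring.

.SCHEMES <- c("alpha", "beta", "neutral",
              "alpha+beta", "alpha+neutral", "beta+neutral", "all")

scheme_pool <- function(scheme) {
  pools <- amino_pools()
  switch(scheme,
    alpha           = pools$alpha,
    beta            = pools$beta,
    neutral         = pools$neutral,
    "alpha+beta"    = c(pools$alpha, pools$beta),
    "alpha+neutral" = c(pools$alpha, pools$neutral),
    "beta+neutral"  = c(pools$beta, pools$neutral),
    all             = unlist(pools, use.names = FALSE),
    stop("unknown pool scheme: '", scheme, "'")
  )
}

#' Draw a random repeat unit from a propensity pool scheme
#'
#' Residues are drawn uniformly with replacement from the union of the
#' selected pools. The draw is deterministic for a given seed and leaves the
#' caller's RNG stream untouched.
#'
#' @param length Unit length (>= 1).
#' @param scheme One of `"alpha"`, `"beta"`, `"neutral"`, `"alpha+beta"`,
#'   `"alpha+neutral"`, `"beta+neutral"`, `"all"`.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Character scalar of `length` 1-letter residue codes.
#' @examples
#' make_unit(20, "beta", seed = 1)
#' @export
make_unit <- function(length, scheme, seed = NULL) {
  if (!is.numeric(length) || length(length) != 1 || is.na(length) || length < 1)
    stop("unit length must be a positive integer (got ", deparse(length), ")")
  pool <- scheme_pool(match.arg(scheme, .SCHEMES))
  draw <- with_seed(seed, sample(pool, size = as.integer(length), replace = TRUE))
  paste(draw, collapse = "")
}

#' Concatenate a repeat unit into a perfect tandem repeat
#'
#' @param unit Non-empty residue string.
#' @param n_copies Number of copies (>= 1).
#' @param scheme,seed Optional provenance carried on the result.
#' @return A `repeat_sequence` object: list with `unit`, `n_copies`, `scheme`,
#'   `seed`, and `full` (the concatenated sequence).
#' @examples
#' tandem("QTSTVIGTIASTETSSSTGI", 10)
#' @export
tandem <- function(unit, n_copies, scheme = NA_character_, seed = NULL) {
  if (!is.character(unit) || length(unit) != 1 || nchar(unit) < 1)
    stop("unit must be a non-empty residue string")
  if (!is.numeric(n_copies) || n_copies < 1)
    stop("n_copies must be >= 1")
  n_copies <- as.integer(n_copies)
  structure(
    list(unit = unit, n_copies = n_copies, scheme = scheme,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         full = paste(rep(unit, n_copies), collapse = "")),
    class = "repeat_sequence"
  )
}

#' @export
print.repeat_sequence <- function(x, ...) {
  cat(sprintf("repeat_sequence: %d-residue unit x %d = %d residues (scheme %s)\n",
              nchar(x$unit), x$n_copies, nchar(x$full), x$scheme))
  cat("  unit: ", x$unit, "\n", sep = "")
  invisible(x)
}

#' Generate the expanded repeat-sequence cohort
#'
#' One sequence per (unit length, scheme) pair; with the defaults
#' (lengths 5-30, schemes beta / alpha+beta / all, 10 copies) this yields the
#' 78-sequence cohort. Per-sequence seeds are derived deterministically as
#' `seed + index`, so the whole cohort is reproducible from one seed.
#'
#' @param lengths Integer vector of unit lengths (default `5:30`).
#' @param schemes Character vector of pool schemes.
#' @param n_copies Copies per sequence (default 10).
#' @param seed Cohort seed.
#' @return List of [tandem()] objects, named by `u<length>_<scheme>`.
#' @examples
#' length(generate_expanded_cohort(seed = 1))  # 78
#' @export
generate_expanded_cohort <- function(lengths = 5:30,
                                     schemes = c("beta", "alpha+beta", "all"),
                                     n_copies = 10, seed = 1L) {
  if (length(lengths) == 0 || length(schemes) == 0) return(list())
  grid <- expand.grid(length = as.integer(lengths), scheme = schemes,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    si <- as.integer(seed) + i
    unit <- make_unit(grid$length[i], grid$scheme[i], seed = si)
    out[[i]] <- tandem(unit, n_copies, scheme = grid$scheme[i], seed = si)
  }
  names(out) <- sprintf("u%02d_%s", grid$length, gsub("\\+", "_", grid$scheme))
  out
}

#' Enumerate the preliminary 50-entry cohort design
#'
#' The preliminary design of 20-residue units concatenated 10 times:
#' 2 alpha + 3 beta + 2 neutral + 3 of each two-pool combination + 15
#' all-pool random sequences (31 in total), plus 19 alanine-mutant slots.
#' Random entries are expanded to sequences immediately; mutant slots are
#' abstract (`kind == "mutant"`) and are realised by the caller via
#' [alanine_mutant()] with explicit (parent, unit position) pairs, since the
#' design does not fix which positions are mutated.
#'
#' @param seed Cohort seed.
#' @param unit_length Unit length for the random entries (default 20).
#' @param n_copies Copies (default 10).
#' @return A `cohort_design`: data.frame with columns `entry_id`, `kind`
#'   (`random`/`mutant`), `scheme`, `seed`, plus a `sequences` attribute
#'   holding the expanded random [tandem()] objects.
#' @export
enumerate_preliminary_design <- function(seed = 1L, unit_length = 20L,
                                         n_copies = 10L) {
  counts <- c(alpha = 2L, beta = 3L, neutral = 2L,
              "alpha+neutral" = 3L, "beta+neutral" = 3L, "alpha+beta" = 3L,
              all = 15L)
  scheme <- rep(names(counts), counts)
  n_rand <- length(scheme)            # 31
  n_mut <- 19L
  design <- data.frame(
    entry_id = c(sprintf("rand%02d", seq_len(n_rand)),
                 sprintf("mut%02d", seq_len(n_mut))),
    kind = c(rep("random", n_rand), rep("mutant", n_mut)),
    scheme = c(scheme, rep(NA_character_, n_mut)),
    seed = c(as.integer(seed) + seq_len(n_rand), rep(NA_integer_, n_mut)),
    stringsAsFactors = FALSE
  )
  seqs <- vector("list", n_rand)
  for (i in seq_len(n_rand)) {
    unit <- make_unit(unit_length, scheme[i], seed = design$seed[i])
    seqs[[i]] <- tandem(unit, n_copies, scheme = scheme[i], seed = design$seed[i])
  }
  names(seqs) <- design$entry_id[seq_len(n_rand)]
  attr(design, "sequences") <- seqs
  class(design) <- c("cohort_design", "data.frame")
  design
}

#' Alanine mutant of a repeat sequence
#'
#' Replaces an aromatic or charged residue with alanine at the same position
#' of every copy (every rung) of the repeat.
#'
#' @param seq A [tandem()] object.
#' @param unit_position 0-based position within the repeat unit.
#' @return A new `repeat_sequence` with the mutated unit.
#' @export
alanine_mutant <- function(seq, unit_position) {
  stopifnot(inherits(seq, "repeat_sequence"))
  L <- nchar(seq$unit)
  if (!is.numeric(unit_position) || unit_position < 0 || unit_position >= L)
    stop("unit_position must be in [0, ", L - 1, "]")
  pos <- as.integer(unit_position) + 1L
  res <- substr(seq$unit, pos, pos)
  eligible <- c("F", "W", "Y", "H", "D", "E", "K", "R")
  if (!res %in% eligible)
    stop("residue '", res, "' at unit position ", unit_position,
         " is not aromatic or charged; cannot mutate to alanine")
  unit <- seq$unit
  substr(unit, pos, pos) <- "A"
  tandem(unit, seq$n_copies, scheme = seq$scheme, seed = seq$seed)
}

#' Mean secondary-structure propensities of a sequence
#'
#' Arithmetic mean of per-residue helix and sheet propensities over the full
#' concatenated sequence.
#'
#' @param seq A [tandem()] object or residue string.
#' @param table Propensity table (default [default_propensity_table()]).
#' @return Named numeric vector `c(mean_alpha = , mean_beta = )`.
#' @export
propensity_means <- function(seq, table = default_propensity_table()) {
  full <- if (inherits(seq, "repeat_sequence")) seq$full else seq
  res <- strsplit(full, "")[[1]]
  miss <- setdiff(unique(res), table$res)
  if (length(miss))
    stop("residue(s) missing from propensity table: ",
         paste(miss, collapse = ", "))
  i <- match(res, table$res)
  c(mean_alpha = mean(table$p_alpha[i]), mean_beta = mean(table$p_beta[i]))
}

#' Normalize a repeat-detection score by unit length
#'
#' @param raw_score Raw repeat score.
#' @param unit_length Repeat unit length (>= 1).
#' @return `raw_score / unit_length`.
#' @seealso [is_near_perfect()]
#' @export
normalize_repeat_score <- function(raw_score, unit_length) {
  if (!is.numeric(unit_length) || unit_length < 1)
    stop("unit_length must be >= 1")
  raw_score / unit_length
}

#' Is a length-normalized repeat score in the near-perfect band?
#'
#' Near-perfect sequence repetition corresponds to a length-normalized score
#' strictly above 7.0.
#'
#' @param normalized_score Output of [normalize_repeat_score()].
#' @param threshold Cutoff (default 7.0).
#' @export
is_near_perfect <- function(normalized_score, threshold = 7.0) {
  normalized_score > threshold
}

#' Column-wise repeat perfection of a tandem sequence
#'
#' Splits the sequence into unit-length columns and scores each unit position
#' by the frequency of its most common residue across copies; the mean over
#' positions is 1 for a perfect tandem repeat.
#'
#' @param full Residue string (>= 2 unit lengths long).
#' @param unit_length Repeat unit length.
#' @return Fraction in `[1/n_copies, 1]`.
#' @export
repeat_perfection <- function(full, unit_length) {
  if (inherits(full, "repeat_sequence")) full <- full$full
  n <- nchar(full)
  if (!is.numeric(unit_length) || unit_length < 1)
    stop("unit_length must be >= 1")
  if (n < 2 * unit_length)
    stop("sequence must span at least two copies of the unit")
  res <- strsplit(full, "")[[1]]
  col <- ((seq_len(n) - 1L) %% as.integer(unit_length)) + 1L
  ident <- vapply(split(res, col), function(ch) {
    max(table(ch)) / length(ch)
  }, numeric(1))
  mean(ident)
}

#' Write a cohort of repeat sequences to FASTA
#'
#' Headers carry `id|unit_length=..|n_copies=..|scheme=..|seed=..`; lines are
#' wrapped at 60 columns.
#'
#' @param seqs List of [tandem()] objects (names become record ids).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (length(seqs) == 0) {
    file.create(path)
    return(invisible(path))
  }
  ids <- names(seqs) %||% sprintf("seq%03d", seq_along(seqs))
  if (is.null(names(seqs))) names(seqs) <- ids
  headers <- vapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    sprintf("%s|unit_length=%d|n_copies=%d|scheme=%s|seed=%s",
            ids[i], nchar(s$unit), s$n_copies, s$scheme,
            ifelse(is.na(s$seed), "NA", s$seed))
  }, character(1))
  seqinr::write.fasta(
    sequences = lapply(seqs, function(s) strsplit(s$full, "")[[1]]),
    names = headers, file.out = path, nbchar = 60
  )
  invisible(path)
}

#' Read a FASTA written by [write_fasta()] back into repeat sequences
#'
#' @param path FASTA file.
#' @return Named list of `repeat_sequence` objects (unit recovered from the
#'   header metadata when present, otherwise the full sequence as one unit).
#' @export
read_fasta_cohort <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  out <- lapply(recs, function(r) {
    header <- attr(r, "name")
    parts <- strsplit(header, "|", fixed = TRUE)[[1]]
    full <- toupper(as.character(r))
    kv <- grep("=", parts, value = TRUE)
    meta <- stats::setNames(
      sub("^[^=]*=", "", kv),
      sub("=.*$", "", kv)
    )
    ul <- suppressWarnings(as.integer(meta["unit_length"]))
    nc <- suppressWarnings(as.integer(meta["n_copies"]))
    if (!is.na(ul) && !is.na(nc) && ul * nc == nchar(full)) {
      tandem(substr(full, 1, ul), nc,
             scheme = unname(meta["scheme"]) %||% NA_character_,
             seed = suppressWarnings(as.integer(meta["seed"])))
    } else {
      tandem(full, 1L)
    }
  })
  names(out) <- vapply(recs, function(r)
    strsplit(attr(r, "name"), "|", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Cohort manifest table
#'
#' Per-sequence summary used downstream by the audit: id, unit, lengths,
#' scheme, seed, propensity means and repeat perfection.
#'
#' @param seqs Named list of [tandem()] objects.
#' @param table Propensity table.
#' @return data.frame with one row per sequence.
#' @export
cohort_manifest <- function(seqs, table = default_propensity_table()) {
  if (length(seqs) == 0)
    return(data.frame(seq_id = character(), unit = character(),
                      unit_length = integer(), n_copies = integer(),
                      scheme = character(), seed = integer(),
                      mean_alpha = numeric(), mean_beta = numeric(),
                      repeat_perfection = numeric(),
                      stringsAsFactors = FALSE))
  ids <- names(seqs) %||% sprintf("seq%03d", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    pm <- propensity_means(s, table)
    data.frame(
      seq_id = ids[i], unit = s$unit, unit_length = nchar(s$unit),
      n_copies = s$n_copies, scheme = s$scheme, seed = s$seed,
      mean_alpha = unname(pm["mean_alpha"]),
      mean_beta = unname(pm["mean_beta"]),
      repeat_perfection = if (s$n_copies >= 2)
        repeat_perfection(s$full, nchar(s$unit)) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
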