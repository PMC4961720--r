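#' @include AllClasses.R AllGenerics.R csd.R restraints.R
NULL

## run expr under an explicit seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a random peptide
#'
#' Draws a sequence of the requested length from a residue composition
#' (uniform over the canonical 20 by default).  Bit-reproducible for a
#' given seed; the caller's RNG state is left untouched.
#'
#' @param length sequence length (>= 1).
#' @param composition optional named probability vector over (a subset
#'   of) the canonical residues; must sum to 1 within 1e-9.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param id label for the generated peptide.
#'
#' @return A [PeptideSequence-class].
#' @examples
#' randomPeptide(15, seed = 7)
#' @export
randomPeptide <- function(length, composition = NULL, seed = NULL,
                          id = "synthetic") {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) pepStop("length must be >= 1")
  if (is.null(composition)) {
    letters <- AA20
    prob <- NULL
  } else {
    if (is.null(names(composition)) ||
        !all(names(composition) %in% AA20))
      pepStop("composition must be named with canonical one-letter codes")
    if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9)
      pepStop("composition probabilities must be non-negative and sum to 1")
    letters <- names(composition)
    prob <- unname(composition)
  }
  res <- .with_seed(seed,
                    sample(letters, length, replace = TRUE, prob = prob))
  peptide(res, id = id)
}

#' Generate a synthetic assigned shift table
#'
#' Inverts the chemical-shift-deviation rule as a generative model: the
#' alpha-CH shift of residue `i` is its random-coil reference value plus
#' a helical offset (`helixShift`, default -0.35 ppm, a typical helical
#' alpha-proton secondary shift, well beyond the -0.1 ppm detection
#' threshold) inside the planted segments, plus Gaussian noise of
#' standard deviation `noiseSd`.  Amide and beta protons are filled with
#' flat plausible constants (8.25 and 1.85 ppm; Gly gets no bCH record)
#' so generated tables pass the full reader validation after a
#' write/read cycle.
#'
#' @param peptide a [PeptideSequence-class] or sequence string.
#' @param helixSegments list of `c(start, end)` 1-based segments (or a
#'   two-column matrix) planted as helix.
#' @param noiseSd Gaussian noise SD, ppm (>= 0).
#' @param seed integer seed, or `NULL`.
#' @param helixShift mean helical alpha-CH offset, ppm.
#' @param ref a [RandomCoilReference-class].
#' @param solvent,temperature,reference stored table metadata.
#'
#' @return A validated [ShiftTable-class].
#' @examples
#' syntheticShiftTable("MAEAHQAVAFQFT", helixSegments = list(c(3, 10)),
#'                     noiseSd = 0.03, seed = 1)
#' @export
syntheticShiftTable <- function(peptide, helixSegments = list(),
                                noiseSd = 0, seed = NULL,
                                helixShift = -0.35,
                                ref = loadRandomCoil(),
                                solvent = "TFE_H2O_1_1",
                                temperature = 298,
                                reference = "synthetic") {
  pep <- .as_peptide(peptide)
  if (noiseSd < 0) pepStop("noiseSd must be >= 0")
  if (is.matrix(helixSegments))
    helixSegments <- split(helixSegments, row(helixSegments))
  L <- length(pep)
  mu <- rep(0, L)
  for (seg in helixSegments) {
    if (length(seg) != 2L || seg[1] < 1L || seg[2] > L || seg[1] > seg[2])
      pepStop("helix segment must be c(start, end) within 1..", L)
    mu[seg[1]:seg[2]] <- helixShift
  }
  noise <- .with_seed(seed, stats::rnorm(L, 0, noiseSd))
  res <- residues(pep)
  aCH <- scaleValues(ref)[res] + mu + noise
  recs <- data.frame(residue_index = seq_len(L), residue = res,
                     atom = "aCH", shift_ppm = unname(aCH), note = "",
                     stringsAsFactors = FALSE)
  nh <- data.frame(residue_index = seq_len(L), residue = res, atom = "NH",
                   shift_ppm = 8.25, note = "", stringsAsFactors = FALSE)
  b_idx <- which(res != "G")
  bch <- data.frame(residue_index = b_idx, residue = res[b_idx],
                    atom = "bCH", shift_ppm = 1.85, note = "",
                    stringsAsFactors = FALSE)
  records <- rbind(recs, nh, bch)
  records <- records[order(records$residue_index, records$atom), ]
  rownames(records) <- NULL
  obj <- new("ShiftTable", peptide = pep, solvent = solvent,
             temperature = temperature, reference = reference,
             records = records)
  ok <- validObject(obj, test = TRUE)
  if (!isTRUE(ok)) pepStop(ok)
  obj
}

#' Generate a restraint list with prescribed category counts
#'
#' Produces an NOE restraint list whose [restraintStats()] equal the
#' requested per-category counts exactly.  Residue pairs are drawn
#' uniformly among those achieving each gap class; atom pairs and upper
#' bounds are sampled from category-typical pools.  Infeasible requests
#' (e.g. sequential restraints for a 1-mer) are rejected.
#'
#' @param length peptide length the restraints refer to.
#' @param counts named vector `c(intra = , seq = , medium = , long = )`.
#' @param seed integer seed, or `NULL`.
#' @param peptide optional [PeptideSequence-class] supplying residue
#'   names for the UPL columns (default: `ALA` placeholders).
#'
#' @return A restraint data.frame (see [readUpl()]).
#' @examples
#' r <- syntheticRestraints(15, c(intra = 60, seq = 37, medium = 14,
#'                                long = 0), seed = 1)
#' restraintCounts(restraintStats(r))
#' @export
syntheticRestraints <- function(length, counts, seed = NULL,
                                peptide = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) pepStop("length must be >= 1")
  need <- c("intra", "seq", "medium", "long")
  if (is.null(names(counts)) || !all(need %in% names(counts)))
    pepStop("counts must be named: intra, seq, medium, long")
  counts <- vapply(counts[need], as.integer, integer(1))
  if (any(is.na(counts) | counts < 0)) pepStop("counts must be >= 0")
  if (counts["seq"] > 0L && length < 2L)
    pepStop("sequential restraints need length >= 2")
  if (counts["medium"] > 0L && length < 3L)
    pepStop("medium-range restraints need length >= 3")
  if (counts["long"] > 0L && length < 6L)
    pepStop("long-range restraints need length >= 6")
  resname <- if (is.null(peptide)) rep("ALA", length) else {
    p <- .as_peptide(peptide)
    if (base::length(p) != length)
      pepStop("peptide length does not match 'length'")
    names(AA3)[match(residues(p), AA3)]
  }
  resname <- toupper(resname)

  draw <- function(n, gaps, atoms, blo, bhi) {
    if (n == 0L)
      return(NULL)
    gaps <- gaps[gaps <= length - 1L | gaps == 0L]
    gap <- gaps[sample.int(base::length(gaps), n, replace = TRUE)]
    i <- vapply(gap, function(g) sample.int(length - g, 1L), integer(1))
    j <- i + gap
    ap <- atoms[sample.int(base::length(atoms), n, replace = TRUE)]
    ai <- sub("-.*$", "", ap); aj <- sub("^.*-", "", ap)
    data.frame(residue_i = i, resname_i = resname[i], atom_i = ai,
               residue_j = j, resname_j = resname[j], atom_j = aj,
               upper_bound = round(stats::runif(n, blo, bhi), 2),
               stringsAsFactors = FALSE)
  }
  out <- .with_seed(seed, {
    rbind(
      draw(counts["intra"], 0L, c("HA-HN", "HA-HB", "HN-HB"), 2.5, 4.5),
      draw(counts["seq"], 1L, c("HA-HN", "HN-HN", "HB-HN"), 2.5, 4.5),
      draw(counts["medium"], 2:4, c("HA-HN", "HN-HN", "HA-HB"), 3.5, 5.5),
      draw(counts["long"], 5:(max(length - 1L, 5L)),
           c("HA-HN", "HN-HN"), 4.0, 6.0))
  })
  if (is.null(out))
    out <- data.frame(residue_i = integer(0), resname_i = character(0),
                      atom_i = character(0), residue_j = integer(0),
                      resname_j = character(0), atom_j = character(0),
                      upper_bound = numeric(0))
  rownames(out) <- NULL
  out
}
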