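#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a peptide sequence
#'
#' @param x one-letter sequence string (or character vector of residues).
#' @param id short label for the peptide.
#' @param nTerminus `"free"` (default) or `"acetyl"`.
#' @param cTerminus `"free_acid"` (default) or `"amide"`.
#'
#' @return A [PeptideSequence-class] object.
#' @examples
#' peptide("MAEAHQAVAFQFT", id = "wt")
#' @export
peptide <- function(x, id = "", nTerminus = "free", cTerminus = "free_acid") {
  if (length(x) == 1L)
    x <- strsplit(x, "")[[1]]
  x <- toupper(as.character(x))
  tryCatch(new("PeptideSequence", id = as.character(id), residues = x,
               nTerminus = nTerminus, cTerminus = cTerminus),
           error = function(e) pepStop(conditionMessage(e)))
}

.as_peptide <- function(x) {
  if (is(x, "PeptideSequence")) x else peptide(x)
}

#' @describeIn peptide residues as a character vector of one-letter codes.
#' @export
setMethod("residues", "PeptideSequence", function(x) x@residues)

#' @describeIn peptide the peptide's label.
#' @export
setMethod("peptideId", "PeptideSequence", function(x) x@id)

#' @export
setMethod("length", "PeptideSequence", function(x) length(x@residues))

#' @export
setMethod("as.character", "PeptideSequence",
          function(x) paste(x@residues, collapse = ""))

setMethod("show", "PeptideSequence", function(object) {
  cat(sprintf("PeptideSequence %s (%d aa, N:%s C:%s)\n  %s\n",
              if (nzchar(object@id)) object@id else "<unnamed>",
              length(object@residues), object@nTerminus, object@cTerminus,
              paste(object@residues, collapse = "")))
})

#' Read and write peptide FASTA files
#'
#' Thin wrappers around Biostrings amino-acid FASTA input/output that
#' return validated [PeptideSequence-class] objects.  Non-canonical
#' letters are rejected.
#'
#' @param path file path.
#' @param x for the writer, a `PeptideSequence` or list of them.
#'
#' @return `readPeptideFasta` returns a named list of `PeptideSequence`;
#'   `writePeptideFasta` returns `path` invisibly.
#' @export
readPeptideFasta <- function(path) {
  if (!file.exists(path)) pepStop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) pepStop("no sequences in FASTA file: ", path)
  out <- lapply(seq_along(set), function(i) {
    peptide(as.character(set[[i]]), id = names(set)[i])
  })
  names(out) <- names(set)
  out
}

#' @rdname readPeptideFasta
#' @export
writePeptideFasta <- function(x, path) {
  if (is(x, "PeptideSequence")) x <- list(x)
  seqs <- vapply(x, function(p) paste(residues(.as_peptide(p)), collapse = ""),
                 character(1))
  ids <- vapply(x, function(p) peptideId(.as_peptide(p)), character(1))
  ids[!nzchar(ids)] <- paste0("peptide_", which(!nzchar(ids)))
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a point mutation
#'
#' Either give the three parts explicitly, or a compact string such as
#' `"V8K"` (original residue, 1-based position, replacement).
#'
#' @param position 1-based position, or a compact mutation string.
#' @param original parent residue expected at `position`.
#' @param replacement residue to substitute.
#'
#' @return A [Mutation-class] object.
#' @examples
#' mutation(8, "V", "K")
#' mutation("F12D")
#' @export
mutation <- function(position, original = NULL, replacement = NULL) {
  if (is.character(position) && is.null(original)) {
    m <- regmatches(position,
                    regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", position))[[1]]
    if (length(m) != 4L)
      pepStop("cannot parse mutation string '", position,
              "' (expected e.g. 'V8K')")
    original <- toupper(m[2]); replacement <- toupper(m[4])
    position <- as.integer(m[3])
  }
  obj <- new("Mutation", position = as.integer(position),
             original = toupper(original), replacement = toupper(replacement))
  ok <- validObject(obj, test = TRUE)
  if (!isTRUE(ok)) pepStop(ok)
  obj
}

setMethod("show", "Mutation", function(object) {
  cat(sprintf("Mutation %s%d%s\n", object@original, object@position,
              object@replacement))
})

#' Apply point mutations to a peptide
#'
#' Mutations must address distinct positions and their `original` residues
#' must match the parent sequence; the parent object is not modified.
#'
#' @param x parent [PeptideSequence-class] (or sequence string).
#' @param mutations a [Mutation-class], a list of them, or a character
#'   vector of compact strings such as `c("V8K", "F12D")`.
#' @param id label for the mutant (default: parent id plus mutation tags).
#'
#' @return The mutated [PeptideSequence-class].
#' @examples
#' applyMutations(peptide("MAEAHQAVAFQFT"), c("V8K", "F12D"))
#' @export
setMethod("applyMutations", "PeptideSequence",
          function(x, mutations, id = NULL) {
  mutations <- .as_mutation_list(mutations)
  res <- x@residues
  if (length(mutations)) {
    pos <- vapply(mutations, function(m) m@position, integer(1))
    if (anyDuplicated(pos))
      pepStop("mutations address position ", pos[duplicated(pos)][1],
              " more than once")
    if (any(pos > length(res)))
      pepStop("mutation position ", max(pos), " beyond sequence length ",
              length(res))
    for (m in mutations) {
      if (res[m@position] != m@original)
        pepStop("original mismatch at position ", m@position, ": sequence has ",
                res[m@position], ", mutation expects ", m@original)
      res[m@position] <- m@replacement
    }
  }
  if (is.null(id)) {
    tags <- vapply(mutations, function(m)
      paste0(m@original, m@position, m@replacement), character(1))
    id <- if (length(tags)) paste(c(x@id, tags)[nzchar(c(x@id, tags))],
                                  collapse = "_") else x@id
  }
  peptide(res, id = id, nTerminus = x@nTerminus, cTerminus = x@cTerminus)
})

#' @rdname applyMutations-PeptideSequence-method
#' @export
setMethod("applyMutations", "character", function(x, mutations, id = NULL) {
  applyMutations(peptide(x), mutations, id = id)
})

.as_mutation_list <- function(mutations) {
  if (is(mutations, "Mutation")) return(list(mutations))
  if (is.character(mutations)) return(lapply(mutations, mutation))
  if (is.list(mutations))
    return(lapply(mutations, function(m)
      if (is(m, "Mutation")) m else mutation(m)))
  pepStop("cannot interpret 'mutations'")
}
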