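#' @include AllClasses.R AllGenerics.R peptide.R scales.R
NULL

.norm_residue <- function(x, line = NA) {
  x1 <- toupper(x)
  if (nchar(x1) == 3L) {
    code <- AA3[paste0(substr(x1, 1, 1), tolower(substr(x1, 2, 3)))]
    if (is.na(code))
      pepStop("line ", line, ": unknown residue name '", x, "'")
    return(unname(code))
  }
  if (!x1 %in% AA20)
    pepStop("line ", line, ": unknown residue code '", x, "'")
  x1
}

.norm_atom <- function(x, line = NA) {
  x <- gsub("α", "a", gsub("β", "b", gsub("γ", "g", x)))
  if (x %in% c("NH", "aCH", "bCH", "gCH") || grepl("^other:", x)) return(x)
  pepStop("line ", line, ": atom label '", x,
          "' not one of NH, aCH, bCH, gCH, other:<text>")
}

#' Read an assigned proton shift table
#'
#' Parses the package's shift-table TSV dialect: optional `#! key=value`
#' metadata lines (`peptide_id`, `sequence`, `solvent`, `temperature_K`,
#' `reference`, `c_terminus`), then a header row
#' `residue_index residue atom shift_ppm note` and one record per line.
#' Residues may be three-letter (`Val`) or one-letter codes; Greek atom
#' labels are normalised to ASCII (`aCH`).  Records are cross-validated
#' against the peptide sequence; malformed rows, residue mismatches and
#' duplicate alpha-CH records are rejected with their line numbers.
#'
#' @param path TSV file path.
#' @param sequence optional [PeptideSequence-class] (or string) used for
#'   cross-validation; defaults to the file's `sequence` metadata.
#'
#' @return A validated [ShiftTable-class].
#' @examples
#' f <- system.file("extdata", "shifts", "mtp1_tfe.tsv", package = "pepscan")
#' readShiftTable(f)
#' @export
readShiftTable <- function(path, sequence = NULL) {
  if (!file.exists(path)) pepStop("shift table not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta <- .read_kv_header(lines)
  if (is.null(sequence)) {
    if (is.na(meta["sequence"]))
      pepStop("no sequence given and no '#! sequence=' metadata in ", path)
    sequence <- peptide(meta["sequence"],
                        id = if (!is.na(meta["peptide_id"]))
                          meta["peptide_id"] else "",
                        cTerminus = if (!is.na(meta["c_terminus"]))
                          meta["c_terminus"] else "free_acid")
  } else {
    sequence <- .as_peptide(sequence)
  }
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(body_idx)) pepStop("no records in ", path)
  header <- strsplit(lines[body_idx[1]], "\t")[[1]]
  if (!identical(header[1:4],
                 c("residue_index", "residue", "atom", "shift_ppm")))
    pepStop("unexpected header in ", path,
            " (need residue_index, residue, atom, shift_ppm[, note])")
  rec_idx <- body_idx[-1]
  recs <- lapply(rec_idx, function(i) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 4L)
      pepStop("line ", i, ": expected at least 4 tab-separated fields")
    idx <- suppressWarnings(as.integer(f[1]))
    shift <- suppressWarnings(as.numeric(f[4]))
    if (is.na(idx) || idx < 1L)
      pepStop("line ", i, ": residue_index must be an integer >= 1")
    if (is.na(shift)) pepStop("line ", i, ": shift_ppm is not numeric")
    if (shift < 0 || shift > 12)
      pepStop("line ", i, ": proton shift ", shift, " outside 0-12 ppm")
    res <- .norm_residue(f[2], i)
    if (idx > length(sequence))
      pepStop("line ", i, ": residue_index ", idx,
              " beyond sequence length ", length(sequence))
    if (res != residues(sequence)[idx])
      pepStop("line ", i, ": residue ", f[2], " at index ", idx,
              " does not match sequence residue ",
              residues(sequence)[idx])
    data.frame(residue_index = idx, residue = res,
               atom = .norm_atom(f[3], i), shift_ppm = shift,
               note = if (length(f) >= 5L) f[5] else "",
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  a <- records$residue_index[records$atom == "aCH"]
  if (anyDuplicated(a))
    pepStop("duplicate aCH record for residue ", a[duplicated(a)][1])
  obj <- new("ShiftTable", peptide = sequence,
             solvent = if (!is.na(meta["solvent"])) unname(meta["solvent"])
                       else "DMSO",
             temperature = if (!is.na(meta["temperature_K"]))
               as.numeric(meta["temperature_K"]) else NA_real_,
             reference = if (!is.na(meta["reference"]))
               unname(meta["reference"]) else "",
             records = records)
  ok <- validObject(obj, test = TRUE)
  if (!isTRUE(ok)) pepStop(ok)
  obj
}

#' @rdname readShiftTable
#' @param x a `ShiftTable` to write.
#' @export
writeShiftTable <- function(x, path) {
  stopifnot(is(x, "ShiftTable"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("#! peptide_id=", peptideId(x@peptide)),
    paste0("#! sequence=", as.character(x@peptide)),
    paste0("#! c_terminus=", x@peptide@cTerminus),
    paste0("#! solvent=", x@solvent),
    paste0("#! temperature_K=", x@temperature),
    paste0("#! reference=", x@reference),
    "residue_index\tresidue\tatom\tshift_ppm\tnote"), con)
  r <- x@records
  writeLines(paste(r$residue_index, r$residue, r$atom,
                   sub("\\.?0+$", "", sprintf("%.10f", r$shift_ppm)), r$note,
                   sep = "\t"), con)
  invisible(path)
}

setMethod("show", "ShiftTable", function(object) {
  cat(sprintf(
    "ShiftTable: %s (%d aa) in %s, %s K, ref %s; %d records (%d aCH)\n",
    peptideId(object@peptide), length(object@peptide), object@solvent,
    format(object@temperature), object@reference, nrow(object@records),
    sum(object@records$atom == "aCH")))
})
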