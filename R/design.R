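#' @include AllClasses.R AllGenerics.R scan.R
NULL

## injective assignments: ordered selections of m distinct alphabet members
.permutations <- function(n, m) {
  if (m == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  out <- matrix(seq_len(n), ncol = 1L)
  for (k in seq_len(m - 1L)) {
    out <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
      rest <- setdiff(seq_len(n), out[i, ])
      cbind(matrix(out[i, ], nrow = length(rest), ncol = k, byrow = TRUE),
            rest)
    }))
  }
  out
}

#' Enumerate and rank targeted substitution candidates
#'
#' Exhaustively enumerates candidate peptides obtained by substituting up
#' to `maxSubs` of the given positions with residues from `alphabet`, and
#' ranks them by a chosen descriptor.  Each alphabet residue is used at
#' most once per candidate (the design installs *one* of each chosen
#' chemical group, e.g. one Lys and one Asp); identity substitutions are
#' excluded.  Ranking is a stable sort on the criterion, so score ties
#' keep the deterministic generation order: fewer substitutions first,
#' then positions ascending, then alphabet residues in the order given.
#'
#' @param parent parent [PeptideSequence-class] or sequence string.
#' @param positions integer vector of candidate positions.
#' @param alphabet character vector of replacement residues, in ranking
#'   priority order (e.g. `c("K", "D")`).
#' @param maxSubs maximum number of simultaneous substitutions.
#' @param criterion `"boman_index"` (default), `"gravy"` or
#'   `"ww_interface"`; candidates are ranked by it in decreasing order.
#'
#' @return A [ScanTable-class] whose rows are the ranked candidates.
#' @examples
#' cand <- enumerateCandidates("MAEAHQAVAFQFT", positions = c(8, 12),
#'                             alphabet = c("K", "D"))
#' scanRows(cand)[1, c("sequence", "boman_index")]  # MAEAHQAKAFQDT, 2.06...
#' @export
enumerateCandidates <- function(parent, positions, alphabet,
                                maxSubs = length(positions),
                                criterion = c("boman_index", "gravy",
                                              "ww_interface")) {
  parent <- .as_peptide(parent)
  criterion <- match.arg(criterion)
  positions <- as.integer(positions)
  alphabet <- toupper(as.character(alphabet))
  if (!length(positions)) pepStop("'positions' must not be empty")
  if (!length(alphabet)) pepStop("'alphabet' must not be empty")
  if (any(positions < 1L | positions > length(parent)))
    pepStop("positions out of range for a ", length(parent), "-mer")
  if (anyDuplicated(positions)) pepStop("duplicated positions")
  bad <- setdiff(alphabet, AA20)
  if (length(bad))
    pepStop("non-canonical alphabet residue(s): ",
            paste(bad, collapse = ", "))
  maxSubs <- as.integer(maxSubs)
  if (maxSubs < 1L || maxSubs > length(positions))
    pepStop("maxSubs must lie in 1..length(positions)")
  positions <- sort(positions)

  prof <- descriptorProfile(parent)
  rows <- list()
  for (m in seq_len(min(maxSubs, length(alphabet)))) {
    subsets <- utils::combn(positions, m, simplify = FALSE)
    perms <- .permutations(length(alphabet), m)
    for (ps in subsets) {
      for (r in seq_len(nrow(perms))) {
        repl <- alphabet[perms[r, ]]
        if (any(repl == residues(parent)[ps])) next  # identity substitution
        muts <- lapply(seq_len(m), function(j)
          mutation(ps[j], residues(parent)[ps[j]], repl[j]))
        rows[[length(rows) + 1L]] <- .scan_row(parent, prof, muts)
      }
    }
  }
  if (!length(rows))
    pepStop("no non-identity candidates for the given positions/alphabet")
  rows <- do.call(rbind, rows)
  score <- rows[[criterion]]
  rows <- rows[order(-score), , drop = FALSE]  # stable: ties keep gen order
  rownames(rows) <- NULL
  new("ScanTable", parent = parent, parentProfile = prof, rows = rows)
}

.report_display <- function(rows) {
  data.frame(label = rows$label, sequence = rows$sequence,
             boman_index = truncateToZero(rows$boman_index, 2),
             hydrophobic_ratio = as.integer(rows$hydrophobic_ratio),
             net_charge = as.integer(rows$net_charge),
             gravy = truncateToZero(rows$gravy, 3),
             ww_interface = truncateToZero(rows$ww_interface, 2),
             stringsAsFactors = FALSE)
}

#' Assemble and write a design report
#'
#' Produces the descriptor panel in the layout of the published
#' glycine-scan table: the parent row first, then the scan rows in
#' position order, then any targeted candidates, with dash-notation
#' substitution labels and the display truncation convention (Boman and
#' Wimley-White at 2 decimals, GRAVY at 3, integer percent and charge).
#'
#' @param scan a [ScanTable-class] from [glycineScan()].
#' @param candidates optional [ScanTable-class] from
#'   [enumerateCandidates()]; appended after the scan rows.
#' @param file optional output path; written as TSV or JSON.
#' @param format `"tsv"` (default) or `"json"`.
#'
#' @return The report data.frame, invisibly when written to `file`.
#' @seealso [readDesignReport()] for the inverse parse.
#' @export
designReport <- function(scan, candidates = NULL, file = NULL,
                         format = c("tsv", "json")) {
  stopifnot(is(scan, "ScanTable"))
  format <- match.arg(format)
  parent <- scan@parent
  pp <- scan@parentProfile
  parent_row <- data.frame(
    label = "parent", sequence = as.character(parent),
    boman_index = truncateToZero(bomanIndex(pp), 2),
    hydrophobic_ratio = as.integer(hydrophobicRatio(pp)),
    net_charge = as.integer(netCharge(pp)),
    gravy = truncateToZero(gravy(pp), 3),
    ww_interface = truncateToZero(wwInterface(pp), 2),
    stringsAsFactors = FALSE)
  out <- rbind(parent_row, .report_display(scan@rows))
  if (!is.null(candidates)) {
    stopifnot(is(candidates, "ScanTable"))
    out <- rbind(out, .report_display(candidates@rows))
  }
  rownames(out) <- NULL
  if (is.null(file)) return(out)
  if (format == "tsv") {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(out, file, dataframe = "rows", digits = NA)
  }
  invisible(out)
}

#' Read back a design report
#'
#' Parses a TSV or JSON report written by [designReport()]; the result is
#' identical (same columns, same display-truncated values) to the
#' data.frame that was written.
#'
#' @param file path to a report written by [designReport()].
#' @param format `"tsv"` or `"json"`; guessed from the extension when
#'   missing.
#' @return The report data.frame.
#' @export
readDesignReport <- function(file, format = NULL) {
  if (!file.exists(file)) pepStop("report file not found: ", file)
  if (is.null(format))
    format <- if (grepl("\\.json$", file)) "json" else "tsv"
  if (format == "json") {
    out <- as.data.frame(jsonlite::read_json(file, simplifyVector = TRUE))
  } else {
    out <- utils::read.delim(file, stringsAsFactors = FALSE,
                             colClasses = c(label = "character",
                                            sequence = "character"))
  }
  out$hydrophobic_ratio <- as.integer(out$hydrophobic_ratio)
  out$net_charge <- as.integer(out$net_charge)
  out
}
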