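#' @include AllClasses.R AllGenerics.R descriptors.R
NULL

.dash_label <- function(L, positions, replacements) {
  lab <- rep("-", L)
  lab[positions] <- replacements
  paste(lab, collapse = "")
}

## one result row for a set of substitutions on a fixed parent
.scan_row <- function(parent, parentProfile, muts) {
  mutant <- applyMutations(parent, muts)
  p <- descriptorProfile(mutant)
  pos <- vapply(muts, function(m) m@position, integer(1))
  rep_ <- vapply(muts, function(m) m@replacement, character(1))
  data.frame(
    label = .dash_label(length(parent), pos, rep_),
    sequence = as.character(mutant),
    positions = paste(pos, collapse = ","),
    n_mut = length(muts),
    boman_index = bomanIndex(p),
    hydrophobic_ratio = as.integer(hydrophobicRatio(p)),
    net_charge = as.integer(netCharge(p)),
    gravy = gravy(p),
    ww_interface = wwInterface(p),
    d_boman = bomanIndex(p) - bomanIndex(parentProfile),
    d_gravy = gravy(p) - gravy(parentProfile),
    d_ww = wwInterface(p) - wwInterface(parentProfile),
    stringsAsFactors = FALSE)
}

#' Scanning mutagenesis of a parent peptide
#'
#' Substitutes every position in turn by a fixed residue (glycine by
#' default) and records the full descriptor panel and its change against
#' the parent.  Positions already equal to the scan residue yield rows
#' identical to the parent profile.
#'
#' @param parent parent [PeptideSequence-class] or sequence string.
#' @param replacement single scan residue, default `"G"`.
#'
#' @return A [ScanTable-class]; `scanRows()` gives one row per position,
#'   ordered by position, with columns `label` (dash notation), `sequence`,
#'   `positions`, `n_mut`, the five descriptors `boman_index`,
#'   `hydrophobic_ratio`, `net_charge`, `gravy`, `ww_interface`, and
#'   deltas `d_boman`, `d_gravy`, `d_ww` versus the parent.
#' @examples
#' scan <- glycineScan("MAEAHQAVAFQFT")
#' head(scanRows(scan))
#' @export
glycineScan <- function(parent, replacement = "G") {
  parent <- .as_peptide(parent)
  if (!replacement %in% AA20)
    pepStop("replacement must be a canonical one-letter code")
  prof <- descriptorProfile(parent)
  rows <- do.call(rbind, lapply(seq_along(residues(parent)), function(i) {
    .scan_row(parent, prof,
              list(mutation(i, residues(parent)[i], replacement)))
  }))
  rownames(rows) <- NULL
  new("ScanTable", parent = parent, parentProfile = prof, rows = rows)
}

#' @describeIn glycineScan the per-mutant rows of a scan or design table.
#' @param x a `ScanTable`.
#' @export
setMethod("scanRows", "ScanTable", function(x) x@rows)

setMethod("show", "ScanTable", function(object) {
  cat(sprintf("ScanTable: %d mutant(s) of parent %s (%s)\n",
              nrow(object@rows), peptideId(object@parent),
              as.character(object@parent)))
  df <- object@rows[, c("label", "boman_index", "hydrophobic_ratio",
                        "net_charge", "gravy", "ww_interface")]
  df$boman_index <- truncateToZero(df$boman_index, 2)
  df$gravy <- truncateToZero(df$gravy, 3)
  df$ww_interface <- truncateToZero(df$ww_interface, 2)
  print(utils::head(df, 20), row.names = FALSE)
  if (nrow(df) > 20) cat("  ...\n")
})

#' Rank scan positions by descriptor improvement
#'
#' Orders the positions of a single-substitution scan by decreasing
#' improvement of a chosen descriptor and returns the top `k`, including
#' every position tied with the k-th value.  For the Boman index
#' "improvement" means the largest increase over the parent; these are the
#' positions most reactive toward the design goal.
#'
#' @param scan a [ScanTable-class] from [glycineScan()].
#' @param k number of positions to return (ties with the k-th kept).
#' @param criterion `"boman_index"` (default), `"gravy"` or
#'   `"ww_interface"`.
#' @param decreasing if `TRUE` (default) larger deltas rank first.
#'
#' @return Integer vector of 1-based positions, best first (ties in
#'   position order).
#' @examples
#' reactivePositions(glycineScan("MAEAHQAVAFQFT"), k = 3)  # 8 10 12
#' @export
reactivePositions <- function(scan, k = 3L,
                              criterion = c("boman_index", "gravy",
                                            "ww_interface"),
                              decreasing = TRUE) {
  stopifnot(is(scan, "ScanTable"))
  criterion <- match.arg(criterion)
  if (!is.numeric(k) || k < 1) pepStop("k must be a positive integer")
  rows <- scan@rows
  if (any(rows$n_mut != 1L))
    pepStop("reactivePositions expects a single-substitution scan")
  pos <- as.integer(rows$positions)
  delta <- switch(criterion, boman_index = rows$d_boman,
                  gravy = rows$d_gravy, ww_interface = rows$d_ww)
  if (!decreasing) delta <- -delta
  k <- min(as.integer(k), length(pos))
  ord <- order(-delta, pos)
  kth <- delta[ord][k]
  pos[ord[delta[ord] >= kth - 1e-12]]
}
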