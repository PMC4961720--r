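#' @include AllClasses.R AllGenerics.R shift_table.R
NULL

.gap_category <- function(gap) {
  ifelse(gap == 0L, "intraresidue",
  ifelse(gap == 1L, "sequential",
  ifelse(gap <= 4L, "medium_range", "long_range")))
}

#' Read and write CYANA-style upper-limit restraint lists
#'
#' The UPL dialect is whitespace-delimited, seven columns per line:
#' `index_i  resname_i  atom_i  index_j  resname_j  atom_j  upper_bound`,
#' with `#` comments.  Residue names may be three- or one-letter codes;
#' bounds are in Angstrom and must be positive.
#'
#' @param path file path.
#'
#' @return `readUpl` returns a data.frame of restraints with columns
#'   `residue_i`, `resname_i`, `atom_i`, `residue_j`, `resname_j`,
#'   `atom_j`, `upper_bound`; `writeUpl` returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".upl")
#' writeLines("1 LYS HA 2 VAL HN 3.5", tf)
#' readUpl(tf)
#' @export
readUpl <- function(path) {
  if (!file.exists(path)) pepStop("UPL file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines_clean <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines_clean)))
  recs <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines_clean[i]), "[[:space:]]+")[[1]]
    if (length(f) != 7L)
      pepStop("line ", i, ": expected 7 whitespace-separated fields, got ",
              length(f))
    ri <- suppressWarnings(as.integer(f[1]))
    rj <- suppressWarnings(as.integer(f[4]))
    ub <- suppressWarnings(as.numeric(f[7]))
    if (is.na(ri) || ri < 1L || is.na(rj) || rj < 1L)
      pepStop("line ", i, ": residue indices must be integers >= 1")
    if (is.na(ub) || ub <= 0)
      pepStop("line ", i, ": upper bound must be a positive distance")
    data.frame(residue_i = ri, resname_i = toupper(f[2]), atom_i = f[3],
               residue_j = rj, resname_j = toupper(f[5]), atom_j = f[6],
               upper_bound = ub, stringsAsFactors = FALSE)
  })
  if (!length(recs))
    return(data.frame(residue_i = integer(0), resname_i = character(0),
                      atom_i = character(0), residue_j = integer(0),
                      resname_j = character(0), atom_j = character(0),
                      upper_bound = numeric(0)))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' @rdname readUpl
#' @param restraints a restraint data.frame as returned by [readUpl()].
#' @export
writeUpl <- function(restraints, path) {
  writeLines(paste(restraints$residue_i, restraints$resname_i,
                   restraints$atom_i, restraints$residue_j,
                   restraints$resname_j, restraints$atom_j,
                   formatC(restraints$upper_bound, format = "fg"),
                   sep = " "), path)
  invisible(path)
}

#' NOE restraint category accounting
#'
#' Counts distance restraints by sequence separation `|i - j|`:
#' intraresidue (0), sequential (1), medium-range (1 < gap <= 4) and
#' long-range (> 4).  The four categories always sum to the total.
#'
#' @param restraints restraint data.frame (see [readUpl()]).
#' @param torsions number of torsion-angle restraints to record alongside.
#'
#' @return A [RestraintStats-class].
#' @examples
#' r <- syntheticRestraints(15, c(intra = 60, seq = 37, medium = 14,
#'                                long = 0), seed = 1)
#' restraintStats(r)
#' @export
restraintStats <- function(restraints, torsions = 0L) {
  gap <- abs(restraints$residue_i - restraints$residue_j)
  cat_ <- .gap_category(gap)
  new("RestraintStats",
      total = length(gap),
      intraresidue = sum(cat_ == "intraresidue"),
      sequential = sum(cat_ == "sequential"),
      mediumRange = sum(cat_ == "medium_range"),
      longRange = sum(cat_ == "long_range"),
      torsionCount = as.integer(torsions))
}

#' @describeIn restraintStats counts as a named integer vector.
#' @param x a `RestraintStats`.
#' @export
setMethod("restraintCounts", "RestraintStats", function(x) {
  c(total = x@total, intraresidue = x@intraresidue,
    sequential = x@sequential, medium_range = x@mediumRange,
    long_range = x@longRange, torsion = x@torsionCount)
})

setMethod("show", "RestraintStats", function(object) {
  cat("NMR restraints\n")
  cat(sprintf("  Distance restraints          %5d\n", object@total))
  cat(sprintf("    Intraresidue               %5d\n", object@intraresidue))
  cat(sprintf("    Sequential (|i-j| = 1)     %5d\n", object@sequential))
  cat(sprintf("    Medium-range (1<|i-j|<=4)  %5d\n", object@mediumRange))
  cat(sprintf("    Long-range (|i-j| > 4)     %5d\n", object@longRange))
  cat(sprintf("  Torsion angle restraints     %5d\n", object@torsionCount))
})

#' Contact-map summary of an NOE restraint list
#'
#' Aggregates restraints per residue pair for drawing sequential/medium
#' range NOE diagrams: one row per observed `(i, j)` pair (ordered so
#' `i <= j`) with its sequence gap, category and restraint count.
#'
#' @param restraints restraint data.frame (see [readUpl()]).
#' @return data.frame with columns `i`, `j`, `gap`, `category`, `n`.
#' @export
noeContactSummary <- function(restraints) {
  if (!nrow(restraints))
    return(data.frame(i = integer(0), j = integer(0), gap = integer(0),
                      category = character(0), n = integer(0)))
  i <- pmin(restraints$residue_i, restraints$residue_j)
  j <- pmax(restraints$residue_i, restraints$residue_j)
  agg <- stats::aggregate(list(n = seq_along(i)),
                          by = list(i = i, j = j), FUN = length)
  agg <- agg[order(agg$i, agg$j), ]
  agg$gap <- agg$j - agg$i
  agg$category <- .gap_category(agg$gap)
  rownames(agg) <- NULL
  agg[, c("i", "j", "gap", "category", "n")]
}
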