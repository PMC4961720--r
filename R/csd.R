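#' @include AllClasses.R AllGenerics.R shift_table.R
NULL

#' Alpha-CH chemical-shift deviations from random coil
#'
#' For every residue with an assigned alpha-CH proton, computes the
#' secondary shift `delta(i) = observed(i) - reference[residue(i)]`.
#' Residues without an alpha-CH record stay `unassigned` with `NA` delta.
#' Sustained negative deviations indicate helix; see
#' [classifyStructure()].
#'
#' @param table a [ShiftTable-class].
#' @param ref a [RandomCoilReference-class]; defaults to the bundled
#'   aqueous table.
#'
#' @return A [CSDProfile-class] (labels all `unassigned` until
#'   classification).
#' @examples
#' f <- system.file("extdata", "shifts", "mtp1_tfe.tsv", package = "pepscan")
#' csd <- csdAlpha(readShiftTable(f))
#' @export
csdAlpha <- function(table, ref = loadRandomCoil()) {
  stopifnot(is(table, "ShiftTable"), is(ref, "RandomCoilReference"))
  res <- residues(table@peptide)
  obs <- rep(NA_real_, length(res))
  a <- table@records[table@records$atom == "aCH", ]
  obs[a$residue_index] <- a$shift_ppm
  delta <- obs - scaleValues(ref)[res]
  new("CSDProfile",
      data = data.frame(index = seq_along(res), residue = res,
                        observed_ppm = obs, delta_ppm = unname(delta),
                        label = "unassigned", stringsAsFactors = FALSE),
      helixThreshold = NA_real_, minRun = NA_integer_,
      overall = "unclassified")
}

#' @describeIn csdAlpha per-residue data of a CSD profile.
#' @param x a `CSDProfile`.
#' @export
setMethod("csdData", "CSDProfile", function(x) x@data)

setMethod("show", "CSDProfile", function(object) {
  cat(sprintf("CSDProfile: %d residues, %d assigned; overall %s\n",
              nrow(object@data), sum(!is.na(object@data$delta_ppm)),
              object@overall))
  print(object@data, row.names = FALSE, digits = 3)
})

## maximal runs of TRUE over consecutive residue indices
.runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values],
             length = r$lengths[r$values])
}

#' Helix/coil classification from secondary shifts
#'
#' Applies the standard chemical-shift-deviation rule: residues in
#' maximal runs of at least `minRun` consecutive residues whose alpha-CH
#' deviation is below `helixThreshold` (default -0.1 ppm) are labelled
#' `helical`; other assigned residues are `coil`; residues without an
#' alpha-CH assignment stay `unassigned` and break runs.  The overall
#' call is `helical` if any helical run exists, else `coil`.
#'
#' @param csd a [CSDProfile-class] from [csdAlpha()].
#' @param helixThreshold helix threshold, ppm (deviations *below* it count).
#' @param minRun minimal run length; the default of 4 residues is one
#'   helical turn.
#'
#' @return A [CSDProfile-class] with labels filled in and the `overall`
#'   call set.
#' @examples
#' prof <- csdAlpha(readShiftTable(system.file("extdata", "shifts",
#'   "mtp1_tfe.tsv", package = "pepscan")))
#' classifyStructure(prof)
#' @export
classifyStructure <- function(csd, helixThreshold = -0.1, minRun = 4L) {
  stopifnot(is(csd, "CSDProfile"))
  minRun <- as.integer(minRun)
  if (is.na(minRun) || minRun < 1L) pepStop("minRun must be >= 1")
  d <- csd@data
  assigned <- !is.na(d$delta_ppm)
  cand <- assigned & d$delta_ppm < helixThreshold
  d$label <- ifelse(assigned, "coil", "unassigned")
  runs <- .runs(cand)
  runs <- runs[runs$length >= minRun, , drop = FALSE]
  for (i in seq_len(nrow(runs)))
    d$label[runs$start[i]:runs$end[i]] <- "helical"
  new("CSDProfile", data = d, helixThreshold = helixThreshold,
      minRun = minRun,
      overall = if (any(d$label == "helical")) "helical" else "coil")
}

#' Plot-ready CSD bar data
#'
#' Convenience export of a CSD profile as a plain data.frame (optionally
#' written to CSV) for drawing per-residue deviation bar charts.
#'
#' @param csd a [CSDProfile-class].
#' @param file optional CSV output path.
#' @return The data.frame, invisibly when written.
#' @export
csdBarData <- function(csd, file = NULL) {
  stopifnot(is(csd, "CSDProfile"))
  out <- csd@data[, c("index", "residue", "delta_ppm", "label")]
  if (is.null(file)) return(out)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
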