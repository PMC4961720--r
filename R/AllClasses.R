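#' @import methods
NULL

## canonical one-letter alphabet, alphabetical by letter
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
         Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
         Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
         Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

WATER_MASS <- 18.0153
## C-terminal amide replaces the acid -OH by -NH2
AMIDE_DELTA <- -0.9847

## classed condition so the CLI can distinguish validation failures
pepStop <- function(...) {
  stop(structure(class = c("pepscan_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Validated peptide sequence
#'
#' An ordered run of one-letter codes from the 20 canonical amino acids,
#' with an identifier and terminal-state metadata.  Positions are 1-based.
#'
#' @slot id short text label.
#' @slot residues character vector of one-letter codes, one per position.
#' @slot nTerminus `"free"` or `"acetyl"`.
#' @slot cTerminus `"free_acid"` or `"amide"`.
#' @exportClass PeptideSequence
setClass("PeptideSequence",
         representation(id = "character", residues = "character",
                        nTerminus = "character", cTerminus = "character"))

setValidity("PeptideSequence", function(object) {
  if (length(object@residues) < 1L)
    return("sequence must contain at least one residue")
  bad <- setdiff(unique(object@residues), AA20)
  if (length(bad))
    return(paste0("non-canonical residue(s): ", paste(bad, collapse = ", ")))
  if (length(object@id) != 1L)
    return("'id' must be a single string")
  if (!object@nTerminus %in% c("free", "acetyl"))
    return("nTerminus must be 'free' or 'acetyl'")
  if (!object@cTerminus %in% c("free_acid", "amide"))
    return("cTerminus must be 'free_acid' or 'amide'")
  TRUE
})

#' Named per-residue numeric scale
#'
#' A complete residue-to-value map over the 20 canonical amino acids, with
#' unit, sign convention and bibliographic source.
#'
#' @slot name scale identifier.
#' @slot unit unit string (e.g. kcal/mol, Da, dimensionless).
#' @slot values named numeric vector, one value per canonical residue.
#' @slot signConvention one-line description of the sign convention.
#' @slot source citation text.
#' @exportClass ResidueScale
setClass("ResidueScale",
         representation(name = "character", unit = "character",
                        values = "numeric", signConvention = "character",
                        source = "character"))

setValidity("ResidueScale", function(object) {
  if (length(object@values) != 20L || !setequal(names(object@values), AA20))
    return("scale must map exactly the 20 canonical residues")
  if (anyNA(object@values))
    return("scale values must not be missing")
  if (length(object@unit) != 1L || !nzchar(object@unit))
    return("unit must be a non-empty string")
  TRUE
})

#' Six-descriptor physicochemical panel for one peptide
#'
#' @slot molWeight average molecular mass, Da.
#' @slot bomanIndex mean sign-inverted cyclohexane-to-water transfer free
#'   energy, kcal/mol per residue.
#' @slot hydrophobicRatio percentage of hydrophobic residues, integer
#'   percent in `[0, 100]`.
#' @slot netCharge side-chain net charge, elementary charges.
#' @slot gravy grand average of Kyte-Doolittle hydropathy, dimensionless.
#' @slot wwInterface Wimley-White whole-residue water-to-POPC-interface
#'   transfer free energy summed over the peptide, kcal/mol.
#' @exportClass DescriptorProfile
setClass("DescriptorProfile",
         representation(molWeight = "numeric", bomanIndex = "numeric",
                        hydrophobicRatio = "numeric", netCharge = "numeric",
                        gravy = "numeric", wwInterface = "numeric"))

setValidity("DescriptorProfile", function(object) {
  if (object@hydrophobicRatio < 0 || object@hydrophobicRatio > 100)
    return("hydrophobicRatio must lie in [0, 100]")
  if (object@molWeight <= 0)
    return("molWeight must be positive")
  TRUE
})

#' Point substitution on a peptide
#'
#' @slot position 1-based position in the parent sequence.
#' @slot original parent residue at that position (checked on application).
#' @slot replacement replacement residue.
#' @exportClass Mutation
setClass("Mutation",
         representation(position = "integer", original = "character",
                        replacement = "character"))

setValidity("Mutation", function(object) {
  if (length(object@position) != 1L || is.na(object@position) ||
      object@position < 1L)
    return("position must be a single index >= 1")
  if (!object@original %in% AA20 || !object@replacement %in% AA20)
    return("original and replacement must be canonical one-letter codes")
  TRUE
})

#' Scanning-mutagenesis result table
#'
#' One row per mutant: dash-notation label, mutated sequence, the five
#' sequence descriptors and their deltas against the parent.
#'
#' @slot parent parent [PeptideSequence-class].
#' @slot parentProfile parent [DescriptorProfile-class].
#' @slot rows data.frame of mutant rows (see [glycineScan()]).
#' @exportClass ScanTable
setClass("ScanTable",
         representation(parent = "PeptideSequence",
                        parentProfile = "DescriptorProfile",
                        rows = "data.frame"))

#' Assigned proton chemical-shift table
#'
#' @slot peptide the assigned [PeptideSequence-class].
#' @slot solvent `"DMSO"` or `"TFE_H2O_1_1"`.
#' @slot temperature temperature, K.
#' @slot reference chemical-shift referencing note.
#' @slot records data.frame with columns residue_index, residue (one-letter),
#'   atom (`NH`, `aCH`, `bCH`, `gCH` or `other:<text>`), shift_ppm, note.
#' @exportClass ShiftTable
setClass("ShiftTable",
         representation(peptide = "PeptideSequence", solvent = "character",
                        temperature = "numeric", reference = "character",
                        records = "data.frame"))

setValidity("ShiftTable", function(object) {
  if (!object@solvent %in% c("DMSO", "TFE_H2O_1_1"))
    return("solvent must be 'DMSO' or 'TFE_H2O_1_1'")
  rec <- object@records
  need <- c("residue_index", "residue", "atom", "shift_ppm", "note")
  if (!all(need %in% names(rec)))
    return(paste0("records must have columns ", paste(need, collapse = ", ")))
  if (nrow(rec)) {
    L <- length(object@peptide@residues)
    if (any(rec$residue_index < 1L) || any(rec$residue_index > L))
      return("record residue_index out of range")
    if (any(rec$residue != object@peptide@residues[rec$residue_index]))
      return("record residue type does not match the peptide sequence")
    if (any(rec$shift_ppm < 0 | rec$shift_ppm > 12))
      return("proton shifts must lie in 0-12 ppm")
    a <- rec$residue_index[rec$atom == "aCH"]
    if (anyDuplicated(a))
      return("at most one aCH record per residue")
  }
  TRUE
})

#' Random-coil alpha-proton reference shifts
#'
#' @slot values named numeric, alpha-CH random-coil shift (ppm) for each of
#'   the 20 canonical residues.
#' @slot source citation text.
#' @exportClass RandomCoilReference
setClass("RandomCoilReference",
         representation(values = "numeric", source = "character"))

setValidity("RandomCoilReference", function(object) {
  if (length(object@values) != 20L || !setequal(names(object@values), AA20))
    return("reference must cover exactly the 20 canonical residues")
  if (any(object@values < 3.9 | object@values > 4.9))
    return("alpha-proton random-coil values must lie in 3.9-4.9 ppm")
  TRUE
})

#' Per-residue alpha-CH chemical-shift deviation profile
#'
#' @slot data data.frame with columns index, residue, observed_ppm,
#'   delta_ppm and label (`helical`, `coil` or `unassigned`).
#' @slot helixThreshold classification threshold, ppm (NA until classified).
#' @slot minRun minimal helical run length used for classification.
#' @slot overall `"helical"`, `"coil"` or `"unclassified"`.
#' @exportClass CSDProfile
setClass("CSDProfile",
         representation(data = "data.frame", helixThreshold = "numeric",
                        minRun = "integer", overall = "character"))

setValidity("CSDProfile", function(object) {
  if (!all(object@data$label %in% c("helical", "coil", "unassigned")))
    return("labels must be helical, coil or unassigned")
  if (!object@overall %in% c("helical", "coil", "unclassified"))
    return("overall must be helical, coil or unclassified")
  TRUE
})

#' NOE distance-restraint category counts
#'
#' Counts by sequence-separation class: intraresidue (|i-j| = 0),
#' sequential (|i-j| = 1), medium-range (1 < |i-j| <= 4) and long-range
#' (|i-j| > 4), plus the number of torsion-angle restraints.
#'
#' @slot total total number of distance restraints.
#' @slot intraresidue,sequential,mediumRange,longRange category counts.
#' @slot torsionCount number of torsion-angle restraints.
#' @exportClass RestraintStats
setClass("RestraintStats",
         representation(total = "integer", intraresidue = "integer",
                        sequential = "integer", mediumRange = "integer",
                        longRange = "integer", torsionCount = "integer"))

setValidity("RestraintStats", function(object) {
  s <- object@intraresidue + object@sequential + object@mediumRange +
    object@longRange
  if (s != object@total)
    return("category counts must sum to the total")
  if (any(c(object@total, object@intraresidue, object@sequential,
            object@mediumRange, object@longRange, object@torsionCount) < 0L))
    return("counts must be non-negative")
  TRUE
})
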