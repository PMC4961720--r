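#' @include AllClasses.R AllGenerics.R scales.R peptide.R
NULL

## hydrophobic set used for the APD-style ratio; Gly deliberately excluded
HYDROPHOBIC_SET <- c("A", "C", "F", "I", "L", "M", "V", "W")

#' Truncate toward zero at a fixed number of decimals
#'
#' The display convention used for the descriptor panels: values are kept
#' at full precision internally and truncated toward zero (not rounded)
#' only for printing, e.g. 1.3254 -> 1.32 and -1.6867 -> -1.68.  A guard
#' of 1e-9 absorbs binary representation error ahead of the floor.
#'
#' @param x numeric vector.
#' @param digits decimals to keep.
#' @return `x` truncated toward zero at `digits` decimals.
#' @examples
#' truncateToZero(-1.6867, 2)
#' @export
truncateToZero <- function(x, digits) {
  sign(x) * floor(abs(x) * 10^digits + 1e-9) / 10^digits
}

.descriptor_mean <- function(seq, scale_name) {
  r <- residues(.as_peptide(seq))
  mean(scaleValues(loadScale(scale_name))[r])
}

#' Sequence descriptors
#'
#' The six whole-sequence physicochemical descriptors used to score
#' antimicrobial-peptide candidates.  All are compositional (invariant to
#' residue order):
#'
#' * `bomanIndex` — mean over residues of the sign-inverted
#'   cyclohexane-to-water transfer free energy (kcal/mol per residue);
#'   higher values indicate greater protein-binding potential.
#' * `gravy` — grand average of Kyte-Doolittle hydropathy.
#' * `wwInterface` — *sum* (not mean) of Wimley-White whole-residue
#'   water-to-POPC-interface transfer free energies (kcal/mol); negative
#'   values favour membrane-interface partitioning.
#' * `netCharge` — side-chain charge count `(#K + #R) - (#D + #E)`;
#'   His neutral, termini ignored.
#' * `hydrophobicRatio` — percentage of residues in the hydrophobic set
#'   \{A, C, F, I, L, M, V, W\}, truncated toward zero to an integer.
#' * `molecularWeight` — sum of average residue masses plus one water
#'   (free termini); `cTerminus = "amide"` subtracts 0.9847 Da.
#'
#' Methods accept either a [PeptideSequence-class] or a plain sequence
#' string.
#'
#' @param x a `PeptideSequence` or one-letter sequence string.
#' @param ... passed through to the `PeptideSequence` method.
#'
#' @return A numeric scalar (integer-valued for `netCharge` and
#'   `hydrophobicRatio`).
#' @examples
#' bomanIndex("MAEAHQAVAFQFT")   # 0.4253846
#' gravy("MAEAHQAVAFQFT")        # 0.3461538
#' wwInterface("MAEAHQAVAFQFT")  # 1.75
#' @name descriptors
NULL

#' @rdname descriptors
#' @export
setMethod("bomanIndex", "PeptideSequence",
          function(x, ...) .descriptor_mean(x, "boman"))

#' @rdname descriptors
#' @export
setMethod("bomanIndex", "character",
          function(x, ...) bomanIndex(peptide(x)))

#' @rdname descriptors
#' @export
setMethod("gravy", "PeptideSequence",
          function(x, ...) .descriptor_mean(x, "kyte_doolittle"))

#' @rdname descriptors
#' @export
setMethod("gravy", "character", function(x, ...) gravy(peptide(x)))

#' @rdname descriptors
#' @export
setMethod("wwInterface", "PeptideSequence", function(x, ...) {
  sum(scaleValues(loadScale("ww_interface"))[residues(x)])
})

#' @rdname descriptors
#' @export
setMethod("wwInterface", "character",
          function(x, ...) wwInterface(peptide(x)))

#' @rdname descriptors
#' @export
setMethod("netCharge", "PeptideSequence", function(x, ...) {
  r <- residues(x)
  sum(r %in% c("K", "R")) - sum(r %in% c("D", "E"))
})

#' @rdname descriptors
#' @export
setMethod("netCharge", "character", function(x, ...) netCharge(peptide(x)))

#' @rdname descriptors
#' @export
setMethod("hydrophobicRatio", "PeptideSequence", function(x, ...) {
  r <- residues(x)
  as.integer(floor(100 * sum(r %in% HYDROPHOBIC_SET) / length(r) + 1e-9))
})

#' @rdname descriptors
#' @export
setMethod("hydrophobicRatio", "character",
          function(x, ...) hydrophobicRatio(peptide(x)))

#' @rdname descriptors
#' @param cTerminus `"free_acid"` (the convention of the published mass
#'   panels) or `"amide"`.
#' @export
setMethod("molecularWeight", "PeptideSequence",
          function(x, cTerminus = c("free_acid", "amide"), ...) {
  cTerminus <- match.arg(cTerminus)
  m <- sum(scaleValues(loadScale("residue_mass"))[residues(x)]) + WATER_MASS
  if (cTerminus == "amide") m <- m + AMIDE_DELTA
  m
})

#' @rdname descriptors
#' @export
setMethod("molecularWeight", "character",
          function(x, cTerminus = c("free_acid", "amide"), ...)
            molecularWeight(peptide(x), cTerminus = cTerminus))

#' Full descriptor panel for one peptide
#'
#' Computes all six descriptors of [descriptors] in one pass; field-wise
#' identical to the individual calls.
#'
#' @param x a [PeptideSequence-class] or sequence string.
#' @param ... passed to [molecularWeight()] (e.g. `cTerminus`).
#'
#' @return A [DescriptorProfile-class].
#' @examples
#' descriptorProfile("MAEAHQAKAFQDT")
#' @export
setMethod("descriptorProfile", "PeptideSequence", function(x, ...) {
  new("DescriptorProfile",
      molWeight = molecularWeight(x, ...),
      bomanIndex = bomanIndex(x),
      hydrophobicRatio = as.numeric(hydrophobicRatio(x)),
      netCharge = as.numeric(netCharge(x)),
      gravy = gravy(x),
      wwInterface = wwInterface(x))
})

#' @rdname descriptorProfile-PeptideSequence-method
#' @export
setMethod("descriptorProfile", "character",
          function(x, ...) descriptorProfile(peptide(x), ...))

#' @export
setMethod("bomanIndex", "DescriptorProfile", function(x, ...) x@bomanIndex)
#' @export
setMethod("gravy", "DescriptorProfile", function(x, ...) x@gravy)
#' @export
setMethod("wwInterface", "DescriptorProfile", function(x, ...) x@wwInterface)
#' @export
setMethod("netCharge", "DescriptorProfile", function(x, ...) x@netCharge)
#' @export
setMethod("hydrophobicRatio", "DescriptorProfile",
          function(x, ...) x@hydrophobicRatio)
#' @export
setMethod("molecularWeight", "DescriptorProfile",
          function(x, ...) x@molWeight)

#' @export
setMethod("as.data.frame", "DescriptorProfile", function(x, ...) {
  data.frame(mol_weight = x@molWeight, boman_index = x@bomanIndex,
             hydrophobic_ratio = x@hydrophobicRatio, net_charge = x@netCharge,
             gravy = x@gravy, ww_interface = x@wwInterface)
})

setMethod("show", "DescriptorProfile", function(object) {
  cat("DescriptorProfile\n")
  cat(sprintf("  mol weight        %10.2f Da\n", object@molWeight))
  cat(sprintf("  Boman index       %10.2f kcal/mol  (truncated display)\n",
              truncateToZero(object@bomanIndex, 2)))
  cat(sprintf("  hydrophobic ratio %10d %%\n",
              as.integer(object@hydrophobicRatio)))
  cat(sprintf("  net charge        %+10d e\n", as.integer(object@netCharge)))
  cat(sprintf("  GRAVY             %10.3f           (truncated display)\n",
              truncateToZero(object@gravy, 3)))
  cat(sprintf("  Wimley-White      %10.2f kcal/mol\n", object@wwInterface))
})
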