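#' @include AllClasses.R AllGenerics.R
NULL

.scale_cache <- new.env(parent = emptyenv())

.read_kv_header <- function(lines) {
  hdr <- grep("^#! ", lines, value = TRUE)
  kv <- sub("^#! ", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(vals, keys)
}

.read_scale_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- .read_kv_header(lines)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  df <- utils::read.delim(text = body, header = TRUE,
                          colClasses = c("character", "numeric"))
  new("ResidueScale",
      name = unname(meta["name"]), unit = unname(meta["unit"]),
      values = stats::setNames(df$value, df$residue),
      signConvention = unname(meta["sign_convention"]),
      source = unname(meta["source"]))
}

#' Bundled residue scales
#'
#' The package ships its residue scales as versioned plain-text tables and
#' loads them at run time, so the numbers behind every descriptor are
#' inspectable and bit-identical across platforms:
#'
#' * `"boman"` — sign-inverted cyclohexane-to-water transfer free energies
#'   (kcal/mol); the per-residue terms of the Boman protein-binding index.
#' * `"kyte_doolittle"` — hydropathy index (dimensionless).
#' * `"ww_interface"` — Wimley-White whole-residue water-to-POPC-interface
#'   transfer free energies (kcal/mol), charged Asp/Glu and neutral His
#'   variants.
#' * `"residue_mass"` — average residue masses (Da).
#' * `"random_coil_alpha"` — aqueous random-coil alpha-CH shifts (ppm).
#'
#' @param name one of the identifiers above.
#'
#' @return [loadScale()] returns a [ResidueScale-class];
#'   [availableScales()] the vector of valid identifiers;
#'   [loadRandomCoil()] a [RandomCoilReference-class].
#' @examples
#' loadScale("kyte_doolittle")
#' @export
loadScale <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% availableScales())
    pepStop("unknown scale '", paste(name, collapse = ","),
            "'; available scales: ",
            paste(availableScales(), collapse = ", "))
  if (!is.null(.scale_cache[[name]])) return(.scale_cache[[name]])
  path <- system.file("extdata", "scales", paste0(name, ".tsv"),
                      package = "pepscan", mustWork = TRUE)
  sc <- .read_scale_file(path)
  validObject(sc)
  .scale_cache[[name]] <- sc
  sc
}

#' @rdname loadScale
#' @export
availableScales <- function() {
  c("boman", "kyte_doolittle", "ww_interface", "residue_mass",
    "random_coil_alpha")
}

#' @rdname loadScale
#' @export
loadRandomCoil <- function() {
  sc <- loadScale("random_coil_alpha")
  new("RandomCoilReference", values = sc@values, source = sc@source)
}

#' @describeIn loadScale the residue-to-value map of a scale.
#' @param x a `ResidueScale`.
#' @export
setMethod("scaleValues", "ResidueScale", function(x) x@values)

#' @export
setMethod("scaleValues", "RandomCoilReference", function(x) x@values)

setMethod("show", "ResidueScale", function(object) {
  cat(sprintf("ResidueScale '%s' [%s]\n  sign: %s\n  source: %s\n",
              object@name, object@unit, object@signConvention,
              object@source))
  print(round(object@values, 4))
})

setMethod("show", "RandomCoilReference", function(object) {
  cat(sprintf("RandomCoilReference (alpha-CH, ppm)\n  source: %s\n",
              object@source))
  print(object@values)
})
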