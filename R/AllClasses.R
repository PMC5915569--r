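#' Encoding configuration for m5C feature extraction
#'
#' Holds every parameter of the three window encoders: the k-mer sizes, the
#' PseDNC correlation depth \eqn{\lambda} and weight \eqn{w}, the dinucleotide
#' physicochemical property table (standardized to mean 0, sd 1 per property
#' across the 16 dinucleotides), and switches for the three feature blocks.
#'
#' @slot kValues integer vector of k-mer sizes (default 1:3, giving 84 features).
#' @slot lambda integer, maximal dinucleotide separation for the pseudo
#'   components (default 6, so PseDNC yields 16 + 6 = 22 features and the full
#'   default vector has 4L + 106 entries for an L-nt window).
#' @slot weight numeric in (0, 1], weight of the pseudo components (default 0.1).
#' @slot propertyTable numeric matrix, 16 dinucleotide rows (AA..UU) by one
#'   column per physicochemical property, standardized columns.
#' @slot includeBinary,includeKmer,includePseDNC logical block switches.
#'
#' @seealso [encodingConfig()], [encodeWindow()]
#' @export
setClass("EncodingConfig",
  representation(
    kValues = "integer",
    lambda = "integer",
    weight = "numeric",
    propertyTable = "matrix",
    includeBinary = "logical",
    includeKmer = "logical",
    includePseDNC = "logical"
  )
)

setValidity("EncodingConfig", function(object) {
  msgs <- character()
  if (length(object@lambda) != 1L || object@lambda < 1L)
    msgs <- c(msgs, "lambda must be a single integer >= 1")
  if (length(object@weight) != 1L || object@weight <= 0 || object@weight > 1)
    msgs <- c(msgs, "weight must be in (0, 1]")
  if (any(object@kValues < 1L))
    msgs <- c(msgs, "kValues must be positive")
  dinucs <- dinucleotides()
  if (!all(dinucs %in% rownames(object@propertyTable)))
    msgs <- c(msgs, "propertyTable must have all 16 dinucleotide rows AA..UU")
  if (length(msgs)) msgs else TRUE
})

#' Ensemble m5C prediction model
#'
#' The trained predictor: ten random forests (each fit on all positives plus
#' one tenth of the negatives), the selected feature subset, the window
#' geometry, and four confidence thresholds anchored at 99/95/90/85%
#' specificity on pooled out-of-fold cross-validation scores.
#'
#' @slot forests list of fitted `ranger` probability forests.
#' @slot selectedFeatures character, ordered feature names the model consumes.
#' @slot upstream,downstream integer flank lengths of the scoring window
#'   (window length L = upstream + 1 + downstream, centered on the cytosine).
#' @slot thresholds named numeric `c(VHmode=, HMode=, NMode=, LMode=)`,
#'   monotone non-increasing from VHmode to LMode.
#' @slot encoding an [EncodingConfig-class] object.
#' @slot metadata list (seed, cross-validated AUC, training set sizes, version).
#'
#' @seealso [buildEnsembleModel()], [scoreSamples()], [scanTranscripts()]
#' @export
setClass("M5CEnsemble",
  representation(
    forests = "list",
    selectedFeatures = "character",
    upstream = "integer",
    downstream = "integer",
    thresholds = "numeric",
    encoding = "EncodingConfig",
    metadata = "list"
  )
)

MODEL_MODES <- c("VHmode", "HMode", "NMode", "LMode")

setValidity("M5CEnsemble", function(object) {
  msgs <- character()
  if (length(object@forests) < 1L)
    msgs <- c(msgs, "model must contain at least one forest")
  th <- object@thresholds
  if (!all(MODEL_MODES %in% names(th)))
    msgs <- c(msgs, "thresholds must be named VHmode, HMode, NMode, LMode")
  else {
    th <- th[MODEL_MODES]
    if (any(th < 0 | th > 1)) msgs <- c(msgs, "thresholds must lie in [0, 1]")
    if (is.unsorted(rev(th))) msgs <- c(msgs, "thresholds must satisfy VH >= H >= N >= L")
  }
  if (object@upstream < 0L || object@downstream < 0L)
    msgs <- c(msgs, "window flanks must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn M5CEnsemble compact description of the fitted ensemble
#' @param object an `M5CEnsemble`
#' @export
setMethod("show", "M5CEnsemble", function(object) {
  cat("M5CEnsemble:", length(object@forests), "random forests\n")
  cat("  window: ", object@upstream, " + C + ", object@downstream,
      " (L = ", object@upstream + 1L + object@downstream, " nt)\n", sep = "")
  cat("  features:", length(object@selectedFeatures), "\n")
  th <- object@thresholds[MODEL_MODES]
  cat("  thresholds:",
      paste(sprintf("%s=%.3f", names(th), th), collapse = " "), "\n")
  if (!is.null(object@metadata$cvAUC))
    cat("  cross-validated AUC:", round(object@metadata$cvAUC, 3), "\n")
  invisible(object)
})

setMethod("show", "EncodingConfig", function(object) {
  blocks <- c("binary", "k-mer", "PseDNC")[c(object@includeBinary,
                                             object@includeKmer,
                                             object@includePseDNC)]
  cat("EncodingConfig: blocks =", paste(blocks, collapse = " + "), "\n")
  cat("  k =", paste(object@kValues, collapse = ","),
      " lambda =", object@lambda, " w =", object@weight,
      " properties =", ncol(object@propertyTable), "\n")
  invisible(object)
})

#' Accessors for fitted ensemble models
#'
#' @param object an [M5CEnsemble-class]
#' @return `thresholds()` the named threshold vector; `selectedFeatures()` the
#'   feature names; `windowGeometry()` `c(upstream=, downstream=)`;
#'   `encodingConfig()` the [EncodingConfig-class] used at training time.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("thresholds", function(object) standardGeneric("thresholds"))
#' @rdname model-accessors
#' @export
setMethod("thresholds", "M5CEnsemble", function(object) object@thresholds[MODEL_MODES])

#' @rdname model-accessors
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))
#' @rdname model-accessors
#' @export
setMethod("selectedFeatures", "M5CEnsemble", function(object) object@selectedFeatures)

#' @rdname model-accessors
#' @export
setGeneric("windowGeometry", function(object) standardGeneric("windowGeometry"))
#' @rdname model-accessors
#' @export
setMethod("windowGeometry", "M5CEnsemble", function(object)
  c(upstream = object@upstream, downstream = object@downstream))

#' @rdname model-accessors
#' @export
setGeneric("encodingConfigOf", function(object) standardGeneric("encodingConfigOf"))
#' @rdname model-accessors
#' @export
setMethod("encodingConfigOf", "M5CEnsemble", function(object) object@encoding)
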