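## The frozen CK2 linear equation: a ten-descriptor model for pIC50 of
## indeno[1,2-b]indole-type CK2 inhibitors, distributed as immutable
## constants. The left-hand side is pIC50 (the coefficient magnitudes put
## the output in the 5-8 range typical of nanomolar inhibitors).

.CK2_INTERCEPT <- 16.00545
.CK2_COEFFICIENTS <- c(
    "PEOE_VSA+1" =  0.06444,
    "Q_VSA_HYD"  = -0.03995,
    "Q_VSA_PNEG" = -0.03312,
    "SlogP_VSA7" = -0.06251,
    "SlogP_VSA8" = -0.03254,
    "SlogP_VSA9" =  0.03023,
    "SMR_VSA5"   =  0.03672,
    "weinerPath" =  0.00160,
    "vdw_vol"    = -0.01269,
    "PEOE_VSA+0" =  0.01078)

#' The frozen CK2 inhibition equation
#'
#' Returns the published ten-descriptor linear QSAR equation for CK2
#' pIC50 prediction as an immutable \linkS4class{QSAREquation}. Applied to
#' an all-zero descriptor vector it returns its intercept, 16.00545; each
#' descriptor contributes exactly its coefficient per unit.
#'
#' @return a \linkS4class{QSAREquation} with exactly ten coefficient terms.
#' @examples
#' eq <- ck2Equation()
#' predict(eq, t(setNames(numeric(10), names(modelCoefficients(eq)))))
#' @export
ck2Equation <- function() {
    QSAREquation(intercept = .CK2_INTERCEPT,
                 coefficients = .CK2_COEFFICIENTS,
                 description = "frozen ten-descriptor CK2 pIC50 equation")
}

#' Export any fitted PLS model as a frozen equation
#'
#' @param model a \linkS4class{PLSModel}.
#' @return a \linkS4class{QSAREquation} with the model's raw-scale
#'   coefficients.
#' @export
asEquation <- function(model) {
    QSAREquation(intercept = model@intercept,
                 coefficients = model@coefficients,
                 description = sprintf("exported PLS model (%d component(s))",
                                       model@ncomp))
}

#' Serialize a model to JSON
#'
#' Writes descriptor names, raw-scale coefficients, intercept, component
#' count, scaling vectors and fit statistics in a stable schema.
#'
#' @param model a \linkS4class{PLSModel} or \linkS4class{QSAREquation}.
#' @param file output path.
#' @param extra named list of additional fields (e.g. a config hash).
#' @export
writeModelJSON <- function(model, file, extra = list()) {
    body <- if (is(model, "PLSModel")) {
        list(schema = "ck2qsar-model/1", type = "pls",
             descriptors = names(model@coefficients),
             coefficients = as.list(model@coefficients),
             intercept = model@intercept, ncomp = model@ncomp,
             x_means = as.list(model@xMeans), x_scales = as.list(model@xScales),
             y_mean = model@yMean, y_scale = model@yScale,
             fit = list(r2 = model@stats@r2, rmse = model@stats@rmse,
                        q2 = model@stats@q2, n = model@stats@n))
    } else {
        list(schema = "ck2qsar-model/1", type = "equation",
             description = model@description,
             descriptors = names(model@coefficients),
             coefficients = as.list(model@coefficients),
             intercept = model@intercept)
    }
    jsonlite::write_json(c(body, extra), file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(file)
}

#' Read a model back from JSON
#'
#' @param file path written by \code{\link{writeModelJSON}}.
#' @return a \linkS4class{QSAREquation} (the linear export is what is
#'   needed for prediction).
#' @export
readModelJSON <- function(file) {
    j <- jsonlite::read_json(file, simplifyVector = TRUE)
    QSAREquation(intercept = j$intercept,
                 coefficients = unlist(j$coefficients),
                 description = if (!is.null(j$description)) j$description
                               else sprintf("model loaded from %s", basename(file)))
}
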