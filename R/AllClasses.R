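#' MolecularGraph: a 2D chemical structure as a labelled graph
#'
#' Atoms carry an element symbol, integer formal charge, an aromaticity flag
#' and an implicit hydrogen count; bonds carry the indices of their two
#' endpoints and a bond order (1, 2, 3, or 1.5 for aromatic). All descriptor
#' computations in the package start from this representation; no 3D
#' coordinates are ever used.
#'
#' @slot atoms data.frame with columns \code{element} (character),
#'   \code{charge} (integer, elementary charges), \code{aromatic} (logical)
#'   and \code{hcount} (integer, implicit hydrogens still to be expanded).
#' @slot bonds data.frame with columns \code{i}, \code{j} (1-based atom
#'   indices, \code{i < j}) and \code{order} (numeric).
#' @slot smiles the source SMILES string, if the graph came from one.
#'
#' @export
setClass("MolecularGraph",
    representation(atoms = "data.frame", bonds = "data.frame",
                   smiles = "character"),
    prototype(atoms = data.frame(element = character(), charge = integer(),
                                 aromatic = logical(), hcount = integer()),
              bonds = data.frame(i = integer(), j = integer(),
                                 order = numeric()),
              smiles = NA_character_))

setValidity("MolecularGraph", function(object) {
    a <- object@atoms; b <- object@bonds
    msgs <- character()
    need <- c("element", "charge", "aromatic", "hcount")
    if (!all(need %in% names(a)))
        return(paste("atoms must have columns", paste(need, collapse = ", ")))
    if (!all(c("i", "j", "order") %in% names(b)))
        return("bonds must have columns i, j, order")
    n <- nrow(a)
    if (nrow(b) > 0) {
        if (any(b$i < 1 | b$i > n | b$j < 1 | b$j > n))
            msgs <- c(msgs, "bond endpoints must index valid atoms")
        if (any(b$i == b$j))
            msgs <- c(msgs, "self-bonds are not allowed")
        key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
        if (anyDuplicated(key))
            msgs <- c(msgs, "duplicate bonds are not allowed")
        if (any(!b$order %in% c(1, 1.5, 2, 3)))
            msgs <- c(msgs, "bond order must be 1, 1.5, 2 or 3")
    }
    if (n > 0 && any(a$hcount < 0))
        msgs <- c(msgs, "hydrogen counts must be non-negative")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn MolecularGraph construct a graph from atom and bond tables
#' @param atoms,bonds see slots.
#' @param smiles optional source SMILES.
#' @export
MolecularGraph <- function(atoms, bonds, smiles = NA_character_) {
    atoms$element <- as.character(atoms$element)
    atoms$charge <- as.integer(atoms$charge)
    atoms$aromatic <- as.logical(atoms$aromatic)
    atoms$hcount <- as.integer(atoms$hcount)
    if (nrow(bonds)) {
        ii <- pmin(bonds$i, bonds$j); jj <- pmax(bonds$i, bonds$j)
        b2 <- data.frame(i = as.integer(ii), j = as.integer(jj),
                         order = as.numeric(bonds$order))
        if (!is.null(bonds$korder)) b2$korder <- as.numeric(bonds$korder)
        bonds <- b2
    } else {
        bonds <- data.frame(i = integer(), j = integer(), order = numeric())
        bonds$korder <- numeric()
    }
    rownames(atoms) <- NULL; rownames(bonds) <- NULL
    new("MolecularGraph", atoms = atoms, bonds = bonds, smiles = smiles)
}

#' @rdname graph-accessors
#' @export
setMethod("numAtoms", "MolecularGraph", function(x) nrow(x@atoms))

#' @rdname graph-accessors
#' @export
setMethod("numBonds", "MolecularGraph", function(x) nrow(x@bonds))

#' @rdname graph-accessors
#' @export
setMethod("atoms", "MolecularGraph", function(x) x@atoms)

#' @rdname graph-accessors
#' @export
setMethod("bonds", "MolecularGraph", function(x) x@bonds)

#' @rdname graph-accessors
#' @export
setMethod("netCharge", "MolecularGraph",
          function(x) as.integer(sum(x@atoms$charge)))

setMethod("show", "MolecularGraph", function(object) {
    nh <- sum(object@atoms$element == "H")
    cat("MolecularGraph:", nrow(object@atoms), "atoms (", nh, "explicit H ),",
        nrow(object@bonds), "bonds, net charge", sum(object@atoms$charge), "\n")
    if (!is.na(object@smiles)) cat("  SMILES:", object@smiles, "\n")
    invisible(NULL)
})

#' PLSModel: a fitted partial least squares regression model
#'
#' Fitted by NIPALS on column-autoscaled descriptors; the latent model is
#' exported as a single linear equation on the raw descriptor scale
#' (slots \code{coefficients} and \code{intercept}), which predicts
#' identically to the latent form.
#'
#' @slot ncomp number of latent components used.
#' @slot coefficients named numeric, raw-scale regression coefficients.
#' @slot intercept raw-scale intercept.
#' @slot xMeans,xScales,yMean,yScale autoscaling parameters of the fit.
#' @slot weights,loadings,yloadings NIPALS weight/loading matrices
#'   (columns = components, scaled space).
#' @slot fitted fitted training responses.
#' @slot stats a \linkS4class{FitStatistics} for the training fit.
#'
#' @export
setClass("PLSModel",
    representation(ncomp = "integer", coefficients = "numeric",
                   intercept = "numeric", xMeans = "numeric",
                   xScales = "numeric", yMean = "numeric", yScale = "numeric",
                   weights = "matrix", loadings = "matrix",
                   yloadings = "numeric", fitted = "numeric",
                   stats = "ANY"))

setValidity("PLSModel", function(object) {
    if (length(object@ncomp) != 1L || object@ncomp < 1L)
        return("ncomp must be a positive integer")
    if (is.null(names(object@coefficients)))
        return("coefficients must be named after descriptors")
    TRUE
})

#' QSAREquation: a frozen linear QSAR equation
#'
#' An immutable intercept-plus-coefficients linear model over named
#' descriptors, predicting pIC50. Used to carry the published CK2
#' equation (see \code{\link{ck2Equation}}) or any exported PLS fit.
#'
#' @slot intercept numeric scalar.
#' @slot coefficients named numeric vector.
#' @slot description free-text provenance tag.
#'
#' @export
setClass("QSAREquation",
    representation(intercept = "numeric", coefficients = "numeric",
                   description = "character"))

setValidity("QSAREquation", function(object) {
    if (length(object@intercept) != 1L) return("intercept must be scalar")
    if (length(object@coefficients) < 1L ||
        is.null(names(object@coefficients)) ||
        any(!nzchar(names(object@coefficients))))
        return("coefficients must be a non-empty named vector")
    TRUE
})

#' @describeIn QSAREquation constructor
#' @param intercept,coefficients,description see slots.
#' @export
QSAREquation <- function(intercept, coefficients,
                         description = "user-defined linear QSAR equation") {
    new("QSAREquation", intercept = as.numeric(intercept),
        coefficients = coefficients, description = description)
}

setMethod("show", "QSAREquation", function(object) {
    cat("QSAREquation:", object@description, "\n")
    cat(sprintf("  pIC50 = %.5f", object@intercept))
    cf <- object@coefficients
    for (k in seq_along(cf))
        cat(sprintf(" %s %.5f * %s", ifelse(cf[k] >= 0, "+", "-"),
                    abs(cf[k]), names(cf)[k]))
    cat("\n")
    invisible(NULL)
})

#' FitStatistics: goodness-of-fit summary for a QSAR model
#'
#' @slot r2 squared Pearson correlation of observed vs predicted.
#' @slot rmse root mean square error of prediction.
#' @slot q2 leave-one-out cross-validated determination coefficient
#'   (NA when not computed).
#' @slot n number of compounds.
#'
#' @export
setClass("FitStatistics",
    representation(r2 = "numeric", rmse = "numeric", q2 = "numeric",
                   n = "integer"))

setValidity("FitStatistics", function(object) {
    if (!is.na(object@r2) && (object@r2 < 0 || object@r2 > 1))
        return("r2 must lie in [0, 1]")
    if (!is.na(object@rmse) && object@rmse < 0)
        return("rmse must be non-negative")
    if (!is.na(object@q2) && object@q2 > 1)
        return("q2 cannot exceed 1")
    TRUE
})

FitStatistics <- function(r2, rmse, q2 = NA_real_, n) {
    new("FitStatistics", r2 = as.numeric(r2), rmse = as.numeric(rmse),
        q2 = as.numeric(q2), n = as.integer(n))
}

setMethod("show", "FitStatistics", function(object) {
    cat(sprintf("FitStatistics (n = %d): r2 = %.4f, RMSE = %.4f, q2 = %s\n",
                object@n, object@r2, object@rmse,
                ifelse(is.na(object@q2), "NA", sprintf("%.4f", object@q2))))
    invisible(NULL)
})

setMethod("show", "PLSModel", function(object) {
    cat("PLSModel:", object@ncomp, "latent component(s),",
        length(object@coefficients), "descriptors\n")
    show(object@stats)
    invisible(NULL)
})

#' Typed error helpers
#'
#' All anticipated failure modes raise classed conditions so callers can
#' distinguish e.g. a SMILES syntax error from a valence violation.
#' @param msg message text.
#' @param class condition subclass.
#' @param call. included for signature compatibility.
#' @keywords internal
ck2_error <- function(msg, class, call. = FALSE) {
    stop(structure(class = c(class, "ck2qsar_error", "error", "condition"),
                   list(message = msg, call = NULL)))
}
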