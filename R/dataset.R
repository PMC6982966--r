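## QSARDataset: compounds with activities and a descriptor matrix, carried
## as a SummarizedExperiment (rows = descriptors, columns = compounds,
## activities in colData). Readers for compound CSV, SMILES and SDF inputs.

#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' QSARDataset: compounds, activities and descriptors
#'
#' Extends \linkS4class{SummarizedExperiment}: the \code{"descriptors"}
#' assay holds the descriptor matrix (descriptors x compounds) and
#' \code{colData} the per-compound activity record (\code{ic50_nM},
#' \code{pic50}, \code{set}).
#'
#' @export
setClass("QSARDataset", contains = "SummarizedExperiment")

setValidity("QSARDataset", function(object) {
    cd <- colData(object)
    need <- c("ic50_nM", "pic50", "set")
    if (!all(need %in% names(cd)))
        return(paste("colData must contain", paste(need, collapse = ", ")))
    if (any(!is.na(cd$ic50_nM) & cd$ic50_nM <= 0))
        return("IC50 values must be positive")
    ok <- !is.na(cd$ic50_nM)
    if (any(abs(cd$pic50[ok] - (9 - log10(cd$ic50_nM[ok]))) > 1e-6))
        return("pic50 must equal 9 - log10(ic50_nM)")
    if (any(!cd$set %in% c("train", "test", "screen")))
        return("set labels must be train, test or screen")
    if (anyNA(assay(object)))
        return("descriptor matrix must not contain missing values")
    TRUE
})

#' @describeIn QSARDataset construct from a compound descriptor matrix and
#'   activity table
#' @param descriptors numeric matrix, compounds x descriptors (rownames =
#'   compound ids).
#' @param activity data.frame with columns \code{id} and \code{ic50_nM}
#'   (or \code{pic50}), optional \code{set} (default \code{"train"}).
#' @export
QSARDataset <- function(descriptors, activity) {
    descriptors <- as.matrix(descriptors)
    if (is.null(rownames(descriptors)))
        rownames(descriptors) <- activity$id
    activity <- activity[match(rownames(descriptors), activity$id), , drop = FALSE]
    if (anyNA(activity$id))
        ck2_error("activity table misses some compounds of the descriptor matrix",
                  "ck2qsar_data_error")
    if (is.null(activity$set)) activity$set <- "train"
    if (is.null(activity$pic50) && is.null(activity$ic50_nM))
        ck2_error("activity table needs ic50_nM or pic50", "ck2qsar_data_error")
    if (is.null(activity$pic50)) activity$pic50 <- toPIC50(activity$ic50_nM)
    if (is.null(activity$ic50_nM)) activity$ic50_nM <- fromPIC50(activity$pic50)
    se <- SummarizedExperiment(
        assays = list(descriptors = t(descriptors)),
        colData = DataFrame(ic50_nM = activity$ic50_nM,
                            pic50 = activity$pic50,
                            set = activity$set,
                            row.names = activity$id))
    new("QSARDataset", se)
}

#' @rdname QSARDataset
#' @param x a QSARDataset.
#' @param ... unused.
#' @export
setMethod("descriptorMatrix", "QSARDataset", function(x, ...) t(assay(x, "descriptors")))

#' @rdname QSARDataset
#' @export
setMethod("activities", "QSARDataset", function(x, ...) {
    cd <- colData(x)
    data.frame(id = rownames(cd), ic50_nM = cd$ic50_nM, pic50 = cd$pic50,
               set = cd$set, row.names = NULL)
})

#' @rdname QSARDataset
#' @export
setMethod("setLabels", "QSARDataset", function(x, ...) {
    stats::setNames(colData(x)$set, rownames(colData(x)))
})

#' Read a compound table CSV
#'
#' Expected columns \code{id,smiles,ic50[,set]}; \code{units} declares the
#' unit of the \code{ic50} column and is converted to nM internally.
#'
#' @param file CSV path.
#' @param units \code{"nM"} (default) or \code{"uM"}.
#' @return data.frame with columns \code{id}, \code{smiles},
#'   \code{ic50_nM}, \code{pic50}, \code{set}.
#' @export
readCompoundTable <- function(file, units = c("nM", "uM")) {
    units <- match.arg(units)
    df <- utils::read.csv(file, stringsAsFactors = FALSE)
    if (!all(c("id", "smiles") %in% names(df)))
        ck2_error("compound table needs columns id, smiles", "ck2qsar_data_error")
    if (nrow(df) == 0L)
        ck2_error("compound table is empty", "ck2qsar_data_error")
    if (!is.null(df$ic50)) {
        ic50 <- as.numeric(df$ic50) * ifelse(units == "uM", 1000, 1)
        df$ic50_nM <- ic50
        df$pic50 <- toPIC50(ic50)
    }
    if (is.null(df$set)) df$set <- "train"
    df
}

#' Read a SMILES file
#'
#' One molecule per line, optional whitespace-separated id; blank lines
#' and \code{#} comments are skipped.
#'
#' @param file path.
#' @return data.frame with columns \code{id}, \code{smiles}.
#' @export
readSmilesFile <- function(file) {
    lines <- trimws(readLines(file, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L)
        ck2_error("SMILES file is empty", "ck2qsar_data_error")
    parts <- strsplit(lines, "[[:space:]]+")
    data.frame(
        id = vapply(seq_along(parts), function(k)
            if (length(parts[[k]]) > 1L) parts[[k]][2L] else as.character(k),
            character(1)),
        smiles = vapply(parts, `[[`, character(1), 1L))
}

#' Read molecules from an SDF (V2000) file
#'
#' Structure input only: 2D/3D coordinates are ignored, the connection
#' table (elements, formal charges, bond orders) is converted to
#' \linkS4class{MolecularGraph} objects. Parsing is delegated to
#' ChemmineR.
#'
#' @param file SDF path.
#' @return named list of \linkS4class{MolecularGraph} objects.
#' @export
readSDFMolecules <- function(file) {
    if (!requireNamespace("ChemmineR", quietly = TRUE))
        ck2_error("SDF input requires the ChemmineR package",
                  "ck2qsar_data_error")
    sdfs <- ChemmineR::read.SDFset(file)
    out <- lapply(seq_along(sdfs), function(k) {
        sdf <- sdfs[[k]]
        ab <- ChemmineR::atomblock(sdf)
        bb <- ChemmineR::bondblock(sdf)
        el <- sub("_.*$", "", rownames(ab))
        charge <- if ("charge" %in% colnames(ab)) {
            ## V2000 charge codes: 0 none, 1:+3, 2:+2, 3:+1, 5:-1, 6:-2, 7:-3
            code <- ab[, "charge"]
            ifelse(code == 0, 0L, 4L - as.integer(code))
        } else rep(0L, nrow(ab))
        order <- as.numeric(bb[, 3])
        aromatic_bond <- order == 4
        order[aromatic_bond] <- 1.5
        aromatic <- rep(FALSE, nrow(ab))
        if (any(aromatic_bond)) {
            aa <- unique(c(bb[aromatic_bond, 1], bb[aromatic_bond, 2]))
            aromatic[aa] <- TRUE
        }
        bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                            order = order)
        bonds$korder <- ifelse(bonds$order == 1.5, 1, bonds$order)
        atom_df <- data.frame(element = el, charge = charge,
                              aromatic = aromatic, hcount = 0L)
        g <- MolecularGraph(atom_df, bonds)
        ## implicit hydrogens by standard valence on heavy atoms without
        ## explicit H (SDF files may carry either)
        has_h <- any(el == "H")
        if (!has_h) {
            ko <- if (any(aromatic_bond)) {
                k2 <- .kekulize(lapply(seq_len(nrow(atom_df)), function(v)
                    list(element = el[v], charge = charge[v],
                         aromatic = aromatic[v], hcount = NA_integer_,
                         bracket = FALSE)), bonds)
                k2
            } else bonds$order
            bonds$korder <- ko
            atoms_l <- lapply(seq_len(nrow(atom_df)), function(v)
                list(element = el[v], charge = charge[v],
                     aromatic = aromatic[v], hcount = NA_integer_,
                     bracket = FALSE))
            atom_df$hcount <- .assign_hydrogens(atoms_l, bonds, ko)
            g <- MolecularGraph(atom_df, bonds)
        }
        g
    })
    ids <- ChemmineR::sdfid(sdfs)
    names(out) <- ifelse(nzchar(ids), ids, as.character(seq_along(out)))
    out
}

#' Build a QSARDataset from a compound table
#'
#' Computes the ten model descriptors for every compound and assembles the
#' dataset; any failing compound aborts with a per-compound diagnostic.
#'
#' @param compounds data.frame from \code{\link{readCompoundTable}}.
#' @param qPolar polar-charge cutoff passed to the descriptor engine.
#' @return a \linkS4class{QSARDataset}.
#' @export
buildQSARDataset <- function(compounds, qPolar = 0.20) {
    mols <- stats::setNames(as.list(compounds$smiles), compounds$id)
    m <- descriptorTable(mols, qPolar = qPolar, onError = "stop")
    QSARDataset(m, compounds)
}
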