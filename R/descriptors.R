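## The ten 2D descriptors of the CK2 model. All VSA-family descriptors sum
## per-atom approximate accessible surface areas over atoms whose
## property (PEOE partial charge, Wildman-Crippen logP or MR contribution)
## falls in a fixed bin:
##   PEOE_VSA+k : charge in [0.05 k, 0.05 (k+1))
##   Q_VSA_HYD  : |charge| <= polar cutoff (default 0.20 e)
##   Q_VSA_PNEG : charge < -cutoff
##   SlogP_VSA7/8/9 : logP contribution in (0.25,0.30], (0.30,0.40], (0.40,Inf)
##   SMR_VSA5   : MR contribution in (0.44, 0.485]
## Hydrogens are explicit for all of these and contribute their own areas.
## weinerPath uses the hydrogen-suppressed graph; vdw_vol the full graph.

#' Names of the ten model descriptors
#' @return character vector in canonical order.
#' @export
descriptorNames <- function() {
    c("PEOE_VSA+0", "PEOE_VSA+1", "Q_VSA_HYD", "Q_VSA_PNEG",
      "SlogP_VSA7", "SlogP_VSA8", "SlogP_VSA9", "SMR_VSA5",
      "weinerPath", "vdw_vol")
}

#' Charge- and contribution-binned VSA descriptors
#'
#' @param g a \linkS4class{MolecularGraph}.
#' @param qPolar polar-charge cutoff for Q_VSA_HYD / Q_VSA_PNEG (e).
#' @param peoeBinWidth width of the PEOE charge bins (e).
#' @param full also return every populated PEOE_VSA bin (for conservation
#'   checks) instead of only the model's eight VSA descriptors.
#' @return named numeric vector of VSA sums (Angstrom^2).
#' @export
binnedVSADescriptors <- function(g, qPolar = 0.20, peoeBinWidth = 0.05,
                                 full = FALSE) {
    q <- peoeCharges(g)
    gx <- attr(q, "graph")
    vsa <- atomicVSA(gx)
    cc <- crippenContribs(gx)
    stopifnot(length(q) == length(vsa), nrow(cc) == length(vsa))
    peoe_bin <- floor(q / peoeBinWidth)      # bin k covers [k w, (k+1) w)
    out <- c(
        "PEOE_VSA+0" = sum(vsa[peoe_bin == 0]),
        "PEOE_VSA+1" = sum(vsa[peoe_bin == 1]),
        "Q_VSA_HYD"  = sum(vsa[abs(q) <= qPolar]),
        "Q_VSA_PNEG" = sum(vsa[q < -qPolar]),
        "SlogP_VSA7" = sum(vsa[cc$logp > 0.25 & cc$logp <= 0.30]),
        "SlogP_VSA8" = sum(vsa[cc$logp > 0.30 & cc$logp <= 0.40]),
        "SlogP_VSA9" = sum(vsa[cc$logp > 0.40]),
        "SMR_VSA5"   = sum(vsa[cc$mr > 0.44 & cc$mr <= 0.485]))
    if (full) {
        bins <- sort(unique(peoe_bin))
        extra <- vapply(bins, function(k) sum(vsa[peoe_bin == k]), numeric(1))
        names(extra) <- sprintf("PEOE_VSA%+d", bins)
        attr(out, "peoeBins") <- extra
        attr(out, "totalVSA") <- sum(vsa)
        attr(out, "charges") <- q
    }
    out
}

#' Compute the full ten-descriptor vector for one molecule
#'
#' @param x a \linkS4class{MolecularGraph} or a single SMILES string.
#' @param qPolar polar-charge cutoff (e) for the hydrophobic/polar split.
#' @param ... unused.
#' @return named numeric vector with exactly the ten keys of
#'   \code{\link{descriptorNames}}.
#' @examples
#' computeDescriptors("c1ccccc1")
#' @rdname computeDescriptors
#' @export
setMethod("computeDescriptors", "MolecularGraph", function(x, qPolar = 0.20, ...) {
    v <- binnedVSADescriptors(x, qPolar = qPolar)
    out <- c(v, weinerPath = as.numeric(wienerPathNumber(x)),
             vdw_vol = vdwVolume(x))
    out[descriptorNames()]
})

#' @rdname computeDescriptors
#' @export
setMethod("computeDescriptors", "character", function(x, qPolar = 0.20, ...) {
    computeDescriptors(parseSmiles(x), qPolar = qPolar, ...)
})

#' Descriptor matrix for a set of molecules
#'
#' @param molecules a character vector of SMILES or a list of
#'   \linkS4class{MolecularGraph} objects; names become row ids.
#' @param qPolar polar-charge cutoff (e).
#' @param onError \code{"stop"} aborts with a per-compound diagnostic
#'   listing (model building); \code{"skip"} drops failing compounds and
#'   records them in attribute \code{"failures"} (screening).
#' @return numeric matrix, compounds x descriptors.
#' @export
descriptorTable <- function(molecules, qPolar = 0.20,
                            onError = c("stop", "skip")) {
    onError <- match.arg(onError)
    ids <- names(molecules)
    if (is.null(ids)) ids <- as.character(seq_along(molecules))
    rows <- vector("list", length(molecules))
    errs <- character()
    for (k in seq_along(molecules)) {
        res <- tryCatch(computeDescriptors(molecules[[k]], qPolar = qPolar),
                        error = function(e) e)
        if (inherits(res, "error")) {
            errs <- c(errs, paste0(ids[k], ": ", conditionMessage(res)))
            rows[k] <- list(NULL)
        } else rows[[k]] <- res
    }
    if (length(errs) && onError == "stop")
        ck2_error(paste0("descriptor computation failed for ", length(errs),
                         " compound(s):\n  ", paste(errs, collapse = "\n  ")),
                  "ck2qsar_descriptor_error")
    ok <- !vapply(rows, is.null, logical(1))
    m <- do.call(rbind, rows[ok])
    rownames(m) <- ids[ok]
    attr(m, "failures") <- errs
    m
}

#' Write a descriptor matrix as CSV
#'
#' Emits the canonical header \code{id,PEOE_VSA+0,...,vdw_vol} with values
#' rounded to 4 decimal places.
#'
#' @param m matrix from \code{\link{descriptorTable}}.
#' @param file output path.
#' @export
writeDescriptorCSV <- function(m, file) {
    df <- data.frame(id = rownames(m),
                     round(m[, descriptorNames(), drop = FALSE], 4),
                     check.names = FALSE)
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
    invisible(file)
}
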