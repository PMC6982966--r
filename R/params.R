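## Parameter tables (vdW radii, covalent radii, ideal bond lengths, PEOE
## electronegativity coefficients, Wildman-Crippen contributions, VSA bin
## edges) ship as editable CSV files under inst/extdata/params and are
## cached per session.

.param_cache <- new.env(parent = emptyenv())

.param_file <- function(name) {
    f <- system.file("extdata", "params", name, package = "ck2qsar")
    if (!nzchar(f)) ck2_error(paste("parameter table not found:", name),
                              "ck2qsar_parameter_error")
    f
}

#' Load a shipped parameter table
#'
#' @param which one of \code{"vdw_radii"}, \code{"covalent_radii"},
#'   \code{"bond_lengths"}, \code{"peoe"}, \code{"crippen"}, \code{"vsa_bins"}.
#' @return a data.frame.
#' @examples
#' head(atomParameters("vdw_radii"))
#' @export
atomParameters <- function(which = c("vdw_radii", "covalent_radii",
                                     "bond_lengths", "peoe", "crippen",
                                     "vsa_bins")) {
    which <- match.arg(which)
    if (!is.null(.param_cache[[which]])) return(.param_cache[[which]])
    fname <- switch(which, peoe = "peoe_params.csv",
                    crippen = "crippen_params.csv",
                    paste0(which, ".csv"))
    tab <- utils::read.csv(.param_file(fname), stringsAsFactors = FALSE)
    if (which %in% c("vdw_radii", "covalent_radii") &&
        any(tab$radius <= 0))
        ck2_error("all radii must be strictly positive",
                  "ck2qsar_parameter_error")
    if (which == "bond_lengths" && any(tab$length <= 0))
        ck2_error("all bond lengths must be strictly positive",
                  "ck2qsar_parameter_error")
    .param_cache[[which]] <- tab
    tab
}

## vdW radius per element, with a typed error for unknown elements
.vdw_radius <- function(elements) {
    tab <- atomParameters("vdw_radii")
    r <- tab$radius[match(elements, tab$element)]
    if (anyNA(r))
        ck2_error(paste("no van der Waals radius for element(s):",
                        paste(unique(elements[is.na(r)]), collapse = ", ")),
                  "ck2qsar_parameter_error")
    r
}

.covalent_radius <- function(elements) {
    tab <- atomParameters("covalent_radii")
    r <- tab$radius[match(elements, tab$element)]
    if (anyNA(r))
        ck2_error(paste("no covalent radius for element(s):",
                        paste(unique(elements[is.na(r)]), collapse = ", ")),
                  "ck2qsar_parameter_error")
    r
}

## Ideal 2D bond length for an element pair and order; falls back to the sum
## of covalent radii minus 0.1 A per bond-order increment beyond single.
.ideal_bond_length <- function(e1, e2, order) {
    tab <- atomParameters("bond_lengths")
    key1 <- paste(tab$elem1, tab$elem2, tab$order)
    key2 <- paste(tab$elem2, tab$elem1, tab$order)
    q <- paste(e1, e2, order)
    idx <- match(q, key1)
    idx2 <- match(q, key2)
    idx[is.na(idx)] <- idx2[is.na(idx)]
    len <- tab$length[idx]
    miss <- is.na(len)
    if (any(miss)) {
        fallback <- .covalent_radius(e1[miss]) + .covalent_radius(e2[miss]) -
            0.1 * (order[miss] - 1)
        len[miss] <- pmax(fallback, 0.5)
    }
    len
}
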