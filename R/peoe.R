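## Gasteiger-Marsili partial equalization of orbital electronegativities
## (PEOE). Electronegativity of atom i at charge q is the quadratic
## chi_i(q) = a_i + b_i q + c_i q^2 with coefficients depending on element
## and hybridization. At iteration k every bond transfers
##   dq = (chi_high - chi_low) / chi_plus_low * f^k
## from the less to the more electronegative partner, where chi_plus_low is
## the cation electronegativity (a + b + c) of the less electronegative
## atom -- fixed at 20.02 for hydrogen -- and f = 0.5 damps the transfer.
## Formal charges seed the iteration, so the total charge is conserved
## exactly.

.peoe_lookup <- function(elements, hybrid) {
    tab <- atomParameters("peoe")
    key <- paste(tab$element, tab$hybridization)
    q <- paste(elements, hybrid)
    idx <- match(q, key)
    any_idx <- match(paste(elements, "any"), key)
    idx[is.na(idx)] <- any_idx[is.na(idx)]
    ## sp carbon-like fallback within an element: use the closest listed
    miss <- is.na(idx)
    if (any(miss))
        ck2_error(paste("no PEOE parameters for element(s):",
                        paste(unique(elements[miss]), collapse = ", ")),
                  "ck2qsar_parameter_error")
    tab[idx, c("a", "b", "c")]
}

#' Gasteiger-Marsili (PEOE) partial charges
#'
#' @param x a \linkS4class{MolecularGraph}; hydrogens are expanded
#'   automatically if still implicit.
#' @param niter number of damped iterations (default 6, the classical
#'   convergence horizon).
#' @param damping per-iteration damping factor f (default 0.5).
#' @param tol stop early when the largest per-bond transfer drops below
#'   this value.
#' @param ... unused.
#' @return numeric vector of per-atom charges (elementary charges), in the
#'   atom order of the hydrogen-expanded graph; the expanded graph is
#'   attached as attribute \code{"graph"}.
#' @examples
#' q <- peoeCharges(parseSmiles("CO"))
#' sum(q)   # neutral molecule: zero to machine precision
#' @rdname peoeCharges
#' @export
setMethod("peoeCharges", "MolecularGraph",
          function(x, niter = 6L, damping = 0.5, tol = 1e-8, ...) {
    g <- expandHydrogens(x)
    a <- g@atoms; b <- g@bonds
    hyb <- .hybridization(g)
    par <- .peoe_lookup(a$element, hyb)
    chi_plus <- ifelse(a$element == "H", 20.02, par$a + par$b + par$c)
    q <- as.numeric(a$charge)
    f <- 1
    for (k in seq_len(niter)) {
        f <- f * damping
        chi <- par$a + par$b * q + par$c * q^2
        dq <- numeric(length(q))
        maxstep <- 0
        for (e in seq_len(nrow(b))) {
            i <- b$i[e]; j <- b$j[e]
            if (chi[i] == chi[j]) next
            if (chi[i] < chi[j]) { lo <- i; hi <- j } else { lo <- j; hi <- i }
            ## electron density moves to the more electronegative atom:
            ## the donor (lo) becomes more positive
            step <- (chi[hi] - chi[lo]) / chi_plus[lo] * f
            dq[lo] <- dq[lo] + step
            dq[hi] <- dq[hi] - step
            maxstep <- max(maxstep, abs(step))
        }
        q <- q + dq
        if (maxstep < tol) break
    }
    names(q) <- a$element
    attr(q, "graph") <- g
    q
})
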