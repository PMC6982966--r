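## Approximate accessible van der Waals surface areas and volumes from the
## connection table alone (Labute-style). Each atom is a sphere of vdW
## radius R_i; every bonded neighbour j at an idealized 2D distance d_ij
## removes a spherical cap of height
##   h_ij = clamp(R_i - (d_ij^2 + R_i^2 - R_j^2) / (2 d_ij), 0, 2 R_i),
## with d_ij clamped into [|R_i - R_j|, R_i + R_j] so the cap geometry is
## always well defined. No 3D coordinates are involved.

.cap_heights <- function(g) {
    a <- g@atoms; b <- g@bonds
    R <- .vdw_radius(a$element)
    h <- vector("list", nrow(a))
    for (v in seq_len(nrow(a))) h[[v]] <- numeric(0)
    if (nrow(b)) {
        d_tab <- .ideal_bond_length(a$element[b$i], a$element[b$j], b$order)
        for (e in seq_len(nrow(b))) {
            i <- b$i[e]; j <- b$j[e]
            dij <- min(max(d_tab[e], abs(R[i] - R[j])), R[i] + R[j])
            hi <- R[i] - (dij^2 + R[i]^2 - R[j]^2) / (2 * dij)
            hj <- R[j] - (dij^2 + R[j]^2 - R[i]^2) / (2 * dij)
            h[[i]] <- c(h[[i]], min(max(hi, 0), 2 * R[i]))
            h[[j]] <- c(h[[j]], min(max(hj, 0), 2 * R[j]))
        }
    }
    list(R = R, h = h)
}

#' Per-atom approximate accessible van der Waals surface area
#'
#' @param x a \linkS4class{MolecularGraph}; hydrogens are expanded
#'   automatically.
#' @param ... unused.
#' @return numeric vector (Angstrom^2), one entry per atom of the expanded
#'   graph (attached as attribute \code{"graph"}); all entries are
#'   non-negative.
#' @examples
#' sum(atomicVSA(parseSmiles("C")))   # methane total VSA
#' @rdname atomicVSA
#' @export
setMethod("atomicVSA", "MolecularGraph", function(x, ...) {
    g <- expandHydrogens(x)
    cg <- .cap_heights(g)
    vsa <- vapply(seq_along(cg$h), function(v) {
        max(0, 4 * pi * cg$R[v]^2 - sum(2 * pi * cg$R[v] * cg$h[[v]]))
    }, numeric(1))
    attr(vsa, "graph") <- g
    vsa
})

#' Approximate van der Waals volume
#'
#' Sphere volumes minus the spherical caps removed by bonded overlaps, a
#' connection-table analogue of the 3D van der Waals volume.
#'
#' @param x a \linkS4class{MolecularGraph}; hydrogens are expanded
#'   automatically.
#' @param ... unused.
#' @return volume in Angstrom^3 (> 0 for any molecule with at least one atom).
#' @examples
#' vdwVolume(parseSmiles("C"))
#' @rdname vdwVolume
#' @export
setMethod("vdwVolume", "MolecularGraph", function(x, ...) {
    g <- expandHydrogens(x)
    if (numAtoms(g) == 0L)
        ck2_error("graph has no atoms", "ck2qsar_graph_error")
    cg <- .cap_heights(g)
    v <- vapply(seq_along(cg$h), function(vv) {
        caps <- sum(pi * cg$h[[vv]]^2 / 3 * (3 * cg$R[vv] - cg$h[[vv]]))
        max(0, 4 / 3 * pi * cg$R[vv]^3 - caps)
    }, numeric(1))
    sum(v)
})
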