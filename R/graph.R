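## Topological operations on molecular graphs. Shortest-path machinery is
## delegated to igraph; molecules are small, so exact BFS distances are
## cheap.

.as_igraph <- function(g, heavy_only = FALSE) {
    a <- g@atoms; b <- g@bonds
    keep <- if (heavy_only) which(a$element != "H") else seq_len(nrow(a))
    idx <- match(seq_len(nrow(a)), keep)
    eb <- b[b$i %in% keep & b$j %in% keep, , drop = FALSE]
    igraph::graph_from_data_frame(
        d = data.frame(from = idx[eb$i], to = idx[eb$j]),
        directed = FALSE,
        vertices = data.frame(name = seq_along(keep)))
}

#' Heavy-atom subgraph
#'
#' @param g a \linkS4class{MolecularGraph}.
#' @return the graph restricted to non-hydrogen atoms.
#' @export
heavyAtomGraph <- function(g) {
    a <- g@atoms; b <- g@bonds
    keep <- which(a$element != "H")
    idx <- match(seq_len(nrow(a)), keep)
    eb <- b[b$i %in% keep & b$j %in% keep, , drop = FALSE]
    eb$i <- idx[eb$i]; eb$j <- idx[eb$j]
    MolecularGraph(a[keep, , drop = FALSE], eb, smiles = g@smiles)
}

#' Topological distance matrix
#'
#' Shortest-path bond counts between all atom pairs (breadth-first search on
#' the unweighted molecular graph). Disconnected structures (mixtures,
#' salts) raise a typed error: fragment selection must happen upstream,
#' never silently.
#'
#' @param x a \linkS4class{MolecularGraph}.
#' @param heavy_only drop hydrogens first (default TRUE).
#' @param ... unused.
#' @return a symmetric integer matrix with zero diagonal.
#' @examples
#' distanceMatrix(parseSmiles("CCCC"))   # path graph: max entry 3
#' @rdname distanceMatrix
#' @export
setMethod("distanceMatrix", "MolecularGraph", function(x, heavy_only = TRUE, ...) {
    ig <- .as_igraph(x, heavy_only = heavy_only)
    if (igraph::vcount(ig) == 0L)
        ck2_error("graph has no atoms", "ck2qsar_graph_error")
    if (igraph::components(ig)$no > 1L)
        ck2_error("molecular graph is disconnected (mixture or salt); strip fragments upstream",
                  "ck2qsar_disconnected_error")
    d <- igraph::distances(ig)
    storage.mode(d) <- "integer"
    dimnames(d) <- NULL
    d
})

#' Wiener path number
#'
#' Half the sum of all entries of the topological distance matrix of the
#' hydrogen-suppressed molecular graph: the classical Wiener index.
#'
#' @param x a \linkS4class{MolecularGraph}.
#' @param ... passed on to \code{\link{distanceMatrix}}.
#' @return a non-negative integer (0 for a single atom).
#' @examples
#' wienerPathNumber(parseSmiles("CCCC"))   # n-butane: 10
#' @rdname wienerPathNumber
#' @export
setMethod("wienerPathNumber", "MolecularGraph", function(x, ...) {
    d <- distanceMatrix(x, heavy_only = TRUE, ...)
    as.integer(round(sum(d) / 2))
})
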