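# Shared helpers: the 20-molecule fixture panel with frozen
# reference-toolkit values (RDKit 2024.09.2), an independent BFS oracle,
# and small graph builders.

panel_charges <- function() {
    read.csv(system.file("extdata", "reference", "gasteiger_reference.csv",
                         package = "ck2qsar"), stringsAsFactors = FALSE)
}

panel_crippen <- function() {
    read.csv(system.file("extdata", "reference", "crippen_reference.csv",
                         package = "ck2qsar"), stringsAsFactors = FALSE)
}

panel_smiles <- function() {
    p <- panel_crippen()
    setNames(p$smiles, p$mol_id)
}

# Independent brute-force BFS over the heavy-atom adjacency list; used as
# the oracle for all distance/Wiener assertions.
bfs_distances <- function(g) {
    a <- atoms(g); b <- bonds(g)
    keep <- which(a$element != "H")
    idx <- match(seq_len(nrow(a)), keep)
    n <- length(keep)
    adj <- vector("list", n)
    for (k in seq_len(nrow(b))) {
        i <- idx[b$i[k]]; j <- idx[b$j[k]]
        if (!is.na(i) && !is.na(j)) {
            adj[[i]] <- c(adj[[i]], j)
            adj[[j]] <- c(adj[[j]], i)
        }
    }
    d <- matrix(Inf, n, n)
    for (s in seq_len(n)) {
        d[s, s] <- 0
        queue <- s
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            for (w in adj[[v]]) if (d[s, w] > d[s, v] + 1) {
                d[s, w] <- d[s, v] + 1
                queue <- c(queue, w)
            }
        }
    }
    d
}

bfs_wiener <- function(g) sum(bfs_distances(g)) / 2

# a bare single-atom graph (no hydrogens), for closed-form surface checks
single_atom_graph <- function(element = "C") {
    MolecularGraph(
        data.frame(element = element, charge = 0L, aromatic = FALSE,
                   hcount = 0L),
        data.frame(i = integer(), j = integer(), order = numeric()))
}
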