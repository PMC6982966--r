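## SMILES -> MolecularGraph.
##
## Covers the common organic SMILES dialect: organic-subset atoms (B, C, N,
## O, P, S, F, Cl, Br, I and aromatic b, c, n, o, p, s), bracket atoms with
## isotope/chirality/H-count/charge, branches, ring closures (including
## %nn), explicit bond symbols, and dot-separated components. Aromatic
## systems are kekulized by perfect matching so that implicit hydrogen
## counts and hybridizations follow standard valence rules. Chirality,
## isotopes and cis/trans marks are accepted and ignored: every descriptor
## in this package is 2D.

.ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")
.DEFAULT_VALENCES <- list(B = 3, C = 4, N = 3, O = 2, P = c(3, 5),
                          S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1,
                          H = 1, Si = 4)

.KNOWN_ELEMENTS <- c(
    "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
    "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn",
    "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr",
    "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
    "In", "Sn", "Sb", "Te", "I", "Xe", "Cs", "Ba", "Hf", "Ta", "W", "Re",
    "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn", "U")

.parse_error <- function(msg, pos = NA) {
    where <- if (!is.na(pos)) paste0(" (at position ", pos, ")") else ""
    ck2_error(paste0("SMILES parse error: ", msg, where), "ck2qsar_parse_error")
}

.valence_error <- function(msg) ck2_error(paste0("valence violation: ", msg),
                                          "ck2qsar_valence_error")

## Parse the contents of a bracket atom, e.g. "nH", "N+", "NH3+", "13C@@H".
.parse_bracket <- function(body, pos) {
    m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?|\\*)(@{1,2})?(H[0-9]*)?(\\+{1,3}|-{1,3}|\\+[0-9]+|-[0-9]+)?(:[0-9]+)?$",
        body))[[1]]
    if (length(m) == 0)
        .parse_error(paste0("cannot read bracket atom [", body, "]"), pos)
    sym <- m[3]
    aromatic <- sym %in% .AROMATIC_ORGANIC || sym %in% c("se", "as")
    element <- if (aromatic) {
        paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
    } else sym
    if (element == "*")
        .parse_error("wildcard atoms are not supported", pos)
    if (!element %in% .KNOWN_ELEMENTS)
        .parse_error(paste0("unknown element '", element, "'"), pos)
    htxt <- m[5]
    hcount <- if (!nzchar(htxt)) 0L
              else if (htxt == "H") 1L
              else as.integer(substring(htxt, 2))
    ctxt <- m[6]
    charge <- if (!nzchar(ctxt)) 0L
              else if (grepl("^[+-]+$", ctxt))
                  as.integer(nchar(ctxt)) * ifelse(substr(ctxt, 1, 1) == "+", 1L, -1L)
              else as.integer(ctxt)
    list(element = element, aromatic = aromatic, hcount = hcount,
         charge = charge, bracket = TRUE)
}

## Tokenize-and-build main loop.
.smiles_build <- function(text) {
    atoms <- list(); bonds <- list()
    prev <- NA_integer_            # current attachment atom
    stack <- integer()             # open branches
    pending <- NA_character_       # bond symbol awaiting its second atom
    rings <- list()                # ring-closure number -> list(atom, bond, pos)
    i <- 1L; n <- nchar(text)
    add_atom <- function(rec) {
        atoms[[length(atoms) + 1L]] <<- rec
        idx <- length(atoms)
        if (!is.na(prev)) {
            bonds[[length(bonds) + 1L]] <<-
                list(i = prev, j = idx, sym = pending, pos = i)
        } else if (!is.na(pending)) {
            .parse_error("bond symbol with no preceding atom", i)
        }
        pending <<- NA_character_
        prev <<- idx
        idx
    }
    close_ring <- function(num, pos) {
        key <- as.character(num)
        if (is.na(prev)) .parse_error("ring closure before any atom", pos)
        if (is.null(rings[[key]])) {
            rings[[key]] <<- list(atom = prev, sym = pending, pos = pos)
            pending <<- NA_character_
        } else {
            op <- rings[[key]]
            if (op$atom == prev)
                .parse_error(paste0("ring bond ", num, " closes on its own atom"), pos)
            sym <- if (!is.na(pending)) pending else op$sym
            if (!is.na(pending) && !is.na(op$sym) && pending != op$sym)
                .parse_error(paste0("conflicting bond symbols on ring closure ", num), pos)
            bonds[[length(bonds) + 1L]] <<-
                list(i = op$atom, j = prev, sym = sym, pos = pos)
            rings[[key]] <<- NULL
            pending <<- NA_character_
        }
    }
    while (i <= n) {
        ch <- substr(text, i, i)
        two <- substr(text, i, i + 1L)
        if (ch == "[") {
            end <- regexpr("]", substring(text, i), fixed = TRUE)
            if (end < 0) .parse_error("unclosed bracket atom", i)
            body <- substr(text, i + 1L, i + end - 2L)
            add_atom(.parse_bracket(body, i))
            i <- i + end
        } else if (two %in% c("Cl", "Br")) {
            add_atom(list(element = two, aromatic = FALSE, hcount = NA_integer_,
                          charge = 0L, bracket = FALSE))
            i <- i + 2L
        } else if (ch %in% .ORGANIC) {
            add_atom(list(element = ch, aromatic = FALSE, hcount = NA_integer_,
                          charge = 0L, bracket = FALSE))
            i <- i + 1L
        } else if (ch %in% .AROMATIC_ORGANIC) {
            add_atom(list(element = toupper(ch), aromatic = TRUE,
                          hcount = NA_integer_, charge = 0L, bracket = FALSE))
            i <- i + 1L
        } else if (ch %in% c("-", "=", "#", ":", "/", "\\", "$")) {
            if (!is.na(pending)) .parse_error("two bond symbols in a row", i)
            pending <- ch
            i <- i + 1L
        } else if (ch == "(") {
            if (is.na(prev)) .parse_error("branch with no preceding atom", i)
            stack <- c(stack, prev)
            i <- i + 1L
        } else if (ch == ")") {
            if (length(stack) == 0L) .parse_error("unmatched ')'", i)
            prev <- stack[length(stack)]
            stack <- stack[-length(stack)]
            i <- i + 1L
        } else if (grepl("^[0-9]$", ch)) {
            close_ring(as.integer(ch), i)
            i <- i + 1L
        } else if (ch == "%") {
            num <- substr(text, i + 1L, i + 2L)
            if (!grepl("^[0-9]{2}$", num))
                .parse_error("'%' must be followed by two digits", i)
            close_ring(as.integer(num), i)
            i <- i + 3L
        } else if (ch == ".") {
            if (!is.na(pending)) .parse_error("bond symbol before '.'", i)
            prev <- NA_integer_
            i <- i + 1L
        } else {
            .parse_error(paste0("unexpected character '", ch, "'"), i)
        }
    }
    if (length(stack) > 0L) .parse_error("unclosed branch", n)
    if (length(rings) > 0L)
        .parse_error(paste0("unclosed ring bond(s): ",
                            paste(names(rings), collapse = ", ")), n)
    if (!is.na(pending)) .parse_error("dangling bond symbol", n)
    if (length(atoms) == 0L) .parse_error("no atoms", 1)
    list(atoms = atoms, bonds = bonds)
}

## Resolve bond symbols to orders. Directional marks are single bonds; an
## unadorned bond between two aromatic atoms is aromatic (order 1.5).
.resolve_orders <- function(atoms, bonds) {
    vapply(bonds, function(b) {
        sym <- b$sym
        if (is.na(sym) || sym %in% c("/", "\\")) {
            if (is.na(sym) && atoms[[b$i]]$aromatic && atoms[[b$j]]$aromatic)
                1.5 else 1
        } else switch(sym, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5, "$" = 4)
    }, numeric(1))
}

## Kekulize the aromatic subsystem by perfect matching: every aromatic atom
## that is short one bond of its target valence must receive exactly one
## double bond along an aromatic bond. Returns the vector of kekulized bond
## orders (aromatic bonds become 1 or 2).
.kekulize <- function(atoms, bond_df) {
    nA <- length(atoms)
    arom <- vapply(atoms, `[[`, logical(1), "aromatic")
    if (!any(arom)) return(bond_df$order)
    deg_extra <- numeric(nA)       # order beyond single from explicit bonds
    nsig <- integer(nA)
    for (k in seq_len(nrow(bond_df))) {
        o <- bond_df$order[k]
        for (v in c(bond_df$i[k], bond_df$j[k])) {
            nsig[v] <- nsig[v] + 1L
            if (o %in% c(2, 3)) deg_extra[v] <- deg_extra[v] + (o - 1)
        }
    }
    needs <- rep(FALSE, nA)
    for (v in which(arom)) {
        a <- atoms[[v]]
        el <- a$element
        target <- switch(el, C = 4, N = 3 + max(a$charge, 0),
                         P = 3 + max(a$charge, 0), O = 2, S = 2, B = 3,
                         Se = 2, As = 3, 4)
        h <- if (is.na(a$hcount)) 0L else a$hcount
        d <- target - (nsig[v] + deg_extra[v] + h)
        if (is.na(a$hcount) && el == "C") {
            ## organic-subset aromatic carbon: one double bond plus implicit H
            needs[v] <- d >= 1
        } else {
            needs[v] <- d >= 1
        }
    }
    ## candidate bonds: aromatic bonds joining two needy atoms
    cand <- which(bond_df$order == 1.5 & needs[bond_df$i] & needs[bond_df$j])
    needy <- which(needs)
    if (length(needy) %% 2L != 0L)
        .valence_error("cannot kekulize aromatic system (odd number of sp2 centres)")
    ## backtracking perfect matching
    adj <- lapply(seq_len(nA), function(v)
        cand[bond_df$i[cand] == v | bond_df$j[cand] == v])
    matched <- rep(NA_integer_, nA)
    match_rec <- function(todo) {
        todo <- todo[is.na(matched[todo])]
        if (length(todo) == 0L) return(TRUE)
        v <- todo[1L]
        for (bk in adj[[v]]) {
            u <- if (bond_df$i[bk] == v) bond_df$j[bk] else bond_df$i[bk]
            if (!is.na(matched[u])) next
            matched[v] <<- bk; matched[u] <<- bk
            if (match_rec(todo[-1L])) return(TRUE)
            matched[v] <<- NA_integer_; matched[u] <<- NA_integer_
        }
        FALSE
    }
    if (!match_rec(needy))
        .valence_error("cannot kekulize aromatic system (no valid alternating pattern)")
    korder <- bond_df$order
    dbl <- unique(matched[!is.na(matched)])
    korder[bond_df$order == 1.5] <- 1
    korder[dbl] <- 2
    korder
}

## Implicit hydrogen counts by smallest standard valence that accommodates
## the kekulized bond-order sum; strict valence checking for organic-subset
## atoms.
.assign_hydrogens <- function(atoms, bond_df, korder) {
    nA <- length(atoms)
    bsum <- numeric(nA)
    for (k in seq_along(korder)) {
        bsum[bond_df$i[k]] <- bsum[bond_df$i[k]] + korder[k]
        bsum[bond_df$j[k]] <- bsum[bond_df$j[k]] + korder[k]
    }
    hcount <- integer(nA)
    for (v in seq_len(nA)) {
        a <- atoms[[v]]
        if (a$bracket) {
            hcount[v] <- a$hcount
            next
        }
        vals <- .DEFAULT_VALENCES[[a$element]]
        if (is.null(vals))
            .valence_error(paste("no standard valence for", a$element))
        ok <- vals[vals >= bsum[v]]
        if (length(ok) == 0L)
            .valence_error(sprintf("atom %d (%s) has bond-order sum %g exceeding valence %g",
                                   v, a$element, bsum[v], max(vals)))
        hcount[v] <- as.integer(ok[1L] - bsum[v])
    }
    hcount
}

#' Parse a SMILES string into a molecular graph
#'
#' Aromatic perception follows the SMILES notation (lowercase atoms and
#' \code{:} bonds); aromatic systems are kekulized internally so that
#' implicit hydrogen counts and hybridizations obey standard valence rules.
#' Malformed input (unbalanced branches or ring bonds, unknown tokens,
#' valence violations) raises a typed condition
#' (\code{ck2qsar_parse_error} / \code{ck2qsar_valence_error}) naming the
#' offending position.
#'
#' @param text a single SMILES string.
#' @return a \linkS4class{MolecularGraph} with implicit hydrogen counts
#'   assigned. Bonds carry the input order (1.5 for aromatic) in
#'   \code{order} and the kekulized order in \code{korder}.
#' @examples
#' g <- parseSmiles("c1ccccc1")   # benzene: 6 aromatic C, 6 implicit H
#' numAtoms(g)
#' @export
parseSmiles <- function(text) {
    if (!is.character(text) || length(text) != 1L || is.na(text) ||
        !nzchar(trimws(text)))
        .parse_error("input must be a single non-empty string")
    text <- trimws(text)
    if (grepl("[[:space:]]", text))
        .parse_error("embedded whitespace (supply the bare SMILES)")
    built <- .smiles_build(text)
    atoms <- built$atoms
    if (length(built$bonds)) {
        bond_df <- data.frame(
            i = vapply(built$bonds, `[[`, integer(1), "i"),
            j = vapply(built$bonds, `[[`, integer(1), "j"),
            order = .resolve_orders(atoms, built$bonds))
    } else {
        bond_df <- data.frame(i = integer(), j = integer(), order = numeric())
    }
    key <- paste(pmin(bond_df$i, bond_df$j), pmax(bond_df$i, bond_df$j))
    if (anyDuplicated(key))
        .parse_error("duplicate bond between the same atom pair")
    ## normalize bracket flag/hcount bookkeeping
    atoms <- lapply(atoms, function(a) {
        if (is.null(a$bracket)) a$bracket <- FALSE
        a
    })
    korder <- .kekulize(atoms, bond_df)
    hcount <- .assign_hydrogens(atoms, bond_df, korder)
    atom_df <- data.frame(
        element = vapply(atoms, `[[`, character(1), "element"),
        charge = vapply(atoms, `[[`, integer(1), "charge"),
        aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
        hcount = hcount)
    bond_df$korder <- korder
    MolecularGraph(atom_df, bond_df, smiles = text)
}

#' Make implicit hydrogens explicit
#'
#' Appends one explicit H atom (single bond) per implicit hydrogen, in heavy
#' atom order; the heavy-atom subgraph is unchanged and the operation is
#' idempotent.
#'
#' @param x a \linkS4class{MolecularGraph}.
#' @param ... unused.
#' @return a \linkS4class{MolecularGraph} with \code{hcount} all zero.
#' @examples
#' numAtoms(expandHydrogens(parseSmiles("C")))  # methane: 5 atoms
#' @rdname expandHydrogens
#' @export
setMethod("expandHydrogens", "MolecularGraph", function(x, ...) {
    a <- x@atoms; b <- x@bonds
    nh <- sum(a$hcount)
    if (nh == 0L) return(x)
    heavy_n <- nrow(a)
    new_atoms <- data.frame(element = rep("H", nh), charge = 0L,
                            aromatic = FALSE, hcount = 0L)
    owner <- rep(seq_len(heavy_n), a$hcount)
    new_bonds <- data.frame(i = owner, j = heavy_n + seq_len(nh), order = 1)
    if ("korder" %in% names(b)) new_bonds$korder <- 1
    a$hcount <- 0L
    ## keep any extra atom columns consistent
    for (col in setdiff(names(a), names(new_atoms))) new_atoms[[col]] <- NA
    MolecularGraph(rbind(a, new_atoms[names(a)]), rbind(b, new_bonds[names(b)]),
                   smiles = x@smiles)
})

## Hybridization per atom from kekulized bond orders: sp for a triple bond
## or two or more double bonds, sp2 for one double bond or an aromatic
## flag, else sp3.
.hybridization <- function(g) {
    a <- g@atoms; b <- g@bonds
    ko <- if ("korder" %in% names(b)) b$korder else b$order
    ndouble <- integer(nrow(a)); ntriple <- integer(nrow(a))
    for (k in seq_along(ko)) {
        if (ko[k] == 2) {
            ndouble[b$i[k]] <- ndouble[b$i[k]] + 1L
            ndouble[b$j[k]] <- ndouble[b$j[k]] + 1L
        } else if (ko[k] == 3) {
            ntriple[b$i[k]] <- ntriple[b$i[k]] + 1L
            ntriple[b$j[k]] <- ntriple[b$j[k]] + 1L
        }
    }
    hyb <- ifelse(ntriple > 0 | ndouble >= 2, "sp",
                  ifelse(ndouble == 1 | a$aromatic, "sp2", "sp3"))
    ## lone-pair conjugation: a singly-bonded N or O attached to an
    ## aromatic ring or to a multiply-bonded atom is effectively sp2
    unsat <- a$aromatic | ndouble > 0 | ntriple > 0
    for (k in seq_along(ko)) {
        for (vv in list(c(b$i[k], b$j[k]), c(b$j[k], b$i[k]))) {
            v <- vv[1]; w <- vv[2]
            if (hyb[v] == "sp3" && a$element[v] %in% c("N", "O") && unsat[w])
                hyb[v] <- "sp2"
        }
    }
    hyb
}
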