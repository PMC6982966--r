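## Packaged reference tables: the published tested/predicted pIC50 pairs
## of the CK2 training and test sets, the screening-prediction table, the
## in-vitro confirmation results, and name-derived SMILES for the
## compounds whose systematic names are public. These are numeric
## fixtures: the report layer operates on them directly, independent of
## the descriptor engine.

.table_file <- function(name)
    system.file("extdata", "tables", name, package = "ck2qsar")

#' Published CK2 training-set pairs
#'
#' Tested and predicted IC50/pIC50 values for the 20 training-set
#' indeno[1,2-b]indoles.
#' @return data.frame with columns \code{id}, \code{tested_ic50_nM},
#'   \code{tested_pic50}, \code{predicted_ic50_nM}, \code{predicted_pic50}.
#' @export
ck2TrainingPairs <- function() {
    utils::read.csv(.table_file("training_pairs.csv"),
                    stringsAsFactors = FALSE)
}

#' Published CK2 test-set pairs
#' @return data.frame, same shape as \code{\link{ck2TrainingPairs}} for
#'   the 10 external-set compounds.
#' @export
ck2TestPairs <- function() {
    utils::read.csv(.table_file("test_pairs.csv"), stringsAsFactors = FALSE)
}

#' Published screening predictions for the naphthofurandione candidates
#' @return data.frame with the 25 ZINC candidates' predicted IC50/pIC50
#'   and docking scores.
#' @export
ck2ScreenPredictions <- function() {
    utils::read.csv(.table_file("screen_predictions.csv"),
                    colClasses = c(zinc_code = "character"),
                    stringsAsFactors = FALSE)
}

#' In-vitro confirmation results for the four tested candidates
#' @return data.frame with measured inhibition and IC50 values.
#' @export
ck2InvitroResults <- function() {
    utils::read.csv(.table_file("invitro_results.csv"),
                    colClasses = c(zinc_code = "character"),
                    stringsAsFactors = FALSE)
}

#' Replicate IC50 determinations for the confirmed hit
#'
#' The three independent biological replicates (uM) of the most active
#' confirmed naphthofurandione; their mean is the reported IC50 of
#' 2.33 uM.
#' @return numeric vector of length 3 (uM).
#' @export
ck2ReplicateIC50 <- function() c(2.046, 2.527, 2.423)

#' Name-derived structures of the publicly named compounds
#'
#' SMILES reconstructed from systematic IUPAC names (the two most active
#' training inhibitors and the four tested naphthofurandiones). These are
#' synthetic stand-ins: original structure files are not deposited.
#' @return data.frame with columns \code{id}, \code{smiles}.
#' @export
ck2NamedStructures <- function() {
    f <- system.file("extdata", "structures", "named_structures.smi",
                     package = "ck2qsar")
    df <- readSmilesFile(f)
    df[, c("id", "smiles")]
}
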