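## Activity transforms. IC50 values are held in nM internally;
## pIC50 = -log10(IC50 in mol/L) = 9 - log10(IC50 in nM).

#' Convert IC50 (nM) to pIC50
#'
#' @param ic50 numeric vector of IC50 values in nM; must be positive.
#' @return pIC50 = 9 - log10(ic50).
#' @examples
#' toPIC50(1400)   # 5.8539
#' @export
toPIC50 <- function(ic50) {
    if (!is.numeric(ic50) || any(!is.finite(ic50)) || any(ic50 <= 0))
        ck2_error("IC50 values must be positive and finite",
                  "ck2qsar_activity_error")
    9 - log10(ic50)
}

#' Convert pIC50 back to IC50 (nM)
#'
#' Exact inverse of \code{\link{toPIC50}}.
#' @param pic50 numeric vector.
#' @return IC50 in nM.
#' @export
fromPIC50 <- function(pic50) 10^(9 - pic50)

#' Average replicate IC50 determinations
#'
#' Arithmetic mean and standard deviation of independent biological
#' replicates, reported at 2 decimal places in the replicates' unit.
#'
#' @param replicates numeric vector of positive IC50 values (any single
#'   unit, conventionally uM for replicate reporting).
#' @return list with \code{mean}, \code{sd} (both rounded to 2 d.p.),
#'   \code{n} and the raw \code{values}.
#' @examples
#' meanIC50(c(2.046, 2.527, 2.423))$mean   # 2.33
#' @export
meanIC50 <- function(replicates) {
    if (length(replicates) < 1L)
        ck2_error("at least one replicate is required", "ck2qsar_activity_error")
    if (any(!is.finite(replicates)) || any(replicates <= 0))
        ck2_error("replicate IC50 values must be positive and finite",
                  "ck2qsar_activity_error")
    list(mean = round(mean(replicates), 2),
         sd = if (length(replicates) > 1L) round(stats::sd(replicates), 2)
              else NA_real_,
         n = length(replicates), values = replicates)
}
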