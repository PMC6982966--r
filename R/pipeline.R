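## End-to-end workflow: ingest -> descriptors -> fit -> validate ->
## predict -> report, with deterministic outputs. Every output file is
## stamped with the package version and a hash of the run configuration,
## so identical configurations produce identical files.

.pkg_version <- function() as.character(utils::packageVersion("ck2qsar"))

#' Hash a run configuration
#'
#' Canonical-JSON md5 of a configuration list; stamped into every output.
#' Output locations (\code{outDir}) are excluded so that the hash
#' identifies the computation, not where its results land.
#' @param config a list.
#' @return md5 string.
#' @export
configHash <- function(config) {
    config <- config[setdiff(names(config), "outDir")]
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(config[order(names(config))], tmp, auto_unbox = TRUE,
                         digits = NA)
    unname(tools::md5sum(tmp))
}

.stamp_csv <- function(df, file, hash) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(sprintf("# ck2qsar %s config %s", .pkg_version(), hash), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    invisible(file)
}

#' Range-matched random train/test split
#'
#' Records are sorted by pIC50 and partitioned into contiguous activity
#' strata; within each stratum members are assigned to the test set at the
#' requested fraction by a seeded draw. Both sets therefore span the full
#' activity range; the extreme strata always keep at least one training
#' member, and the external set must end up with at least 5 compounds.
#'
#' @param records data.frame with a \code{pic50} column.
#' @param fractionTest test proportion in (0, 0.5].
#' @param seed integer seed for the within-stratum draws.
#' @param strata number of activity strata (default 5).
#' @return the input data.frame with a \code{set} column
#'   (\code{"train"}/\code{"test"}).
#' @export
splitRangeMatched <- function(records, fractionTest = 1 / 3, seed = 1L,
                              strata = 5L) {
    if (nrow(records) < 5L)
        ck2_error("need at least 5 records to split", "ck2qsar_split_error")
    if (fractionTest <= 0 || fractionTest > 0.5)
        ck2_error("fractionTest must lie in (0, 0.5]", "ck2qsar_split_error")
    ord <- order(records$pic50)
    groups <- split(ord, cut(seq_along(ord), breaks = strata, labels = FALSE))
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    test_idx <- integer()
    for (g in groups) {
        k <- round(length(g) * fractionTest)
        k <- min(k, length(g) - 1L)           # extreme strata keep a trainer
        if (k > 0L) test_idx <- c(test_idx, sample(g, k))
    }
    if (length(test_idx) < 5L)
        ck2_error(paste0("external set would have ", length(test_idx),
                         " compounds; at least 5 are required"),
                  "ck2qsar_split_error")
    records$set <- "train"
    records$set[test_idx] <- "test"
    records
}

.default_config <- function(config) {
    defaults <- list(units = "nM", split = "given", testFraction = 1 / 3,
                     seed = 1L, components = "auto", qPolar = 0.20,
                     strata = 5L)
    for (nm in names(defaults))
        if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    config
}

#' Run the training workflow
#'
#' Reads a compound table, computes descriptors, splits into train/test
#' (honouring given labels or drawing a range-matched random split), fits
#' a PLS model with internal (LOO q2) validation, predicts the external
#' set, and writes: \code{model.json}, \code{statistics.csv},
#' \code{predictions.csv} (id, set, tested and predicted pIC50 -- the
#' plot-ready actual-vs-predicted scatter data). Any compound failing
#' descriptor computation aborts the run with a per-compound listing.
#'
#' @param config list with \code{input} (compound CSV) and \code{outDir},
#'   plus optional \code{units} ("nM"/"uM"), \code{split} ("given"/
#'   "random"), \code{testFraction}, \code{seed}, \code{components}
#'   ("auto" or integer), \code{qPolar}, \code{strata}.
#' @return invisibly, a list with the fitted model, per-split statistics
#'   and the prediction table.
#' @export
runTraining <- function(config) {
    config <- .default_config(config)
    if (is.null(config$input) || is.null(config$outDir))
        ck2_error("config needs input and outDir", "ck2qsar_config_error")
    hash <- configHash(config)
    compounds <- readCompoundTable(config$input, units = config$units)
    if (identical(config$split, "random"))
        compounds <- splitRangeMatched(compounds, config$testFraction,
                                       config$seed, config$strata)
    ds <- buildQSARDataset(compounds, qPolar = config$qPolar)
    lab <- setLabels(ds)
    X <- descriptorMatrix(ds)
    act <- activities(ds)
    tr <- lab == "train"; te <- lab == "test"
    if (sum(tr) < 3L)
        ck2_error("training set too small", "ck2qsar_model_error")
    model <- fitPLS(X[tr, , drop = FALSE], act$pic50[tr],
                    ncomp = config$components)
    pred <- predictActivity(model, X)$pic50
    stats_rows <- list(data.frame(
        set = "train", n = sum(tr),
        r2 = rSquared(act$pic50[tr], pred[tr]),
        rmse = rmse(act$pic50[tr], pred[tr]),
        q2 = model@stats@q2))
    if (sum(te) >= 3L)
        stats_rows <- c(stats_rows, list(data.frame(
            set = "test", n = sum(te),
            r2 = rSquared(act$pic50[te], pred[te]),
            rmse = rmse(act$pic50[te], pred[te]), q2 = NA_real_)))
    stats_df <- do.call(rbind, stats_rows)
    preds_df <- data.frame(id = act$id, set = lab,
                           tested_pic50 = round(act$pic50, 4),
                           predicted_pic50 = round(pred, 4))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    writeModelJSON(model, file.path(config$outDir, "model.json"),
                   extra = list(config_hash = hash,
                                package_version = .pkg_version(),
                                seed = config$seed))
    .stamp_csv(stats_df, file.path(config$outDir, "statistics.csv"), hash)
    .stamp_csv(preds_df, file.path(config$outDir, "predictions.csv"), hash)
    invisible(list(model = model, statistics = stats_df,
                   predictions = preds_df, config_hash = hash))
}

#' Screen a compound list with a model
#'
#' Computes descriptors for every parsable entry, predicts pIC50 and IC50
#' (nM) and returns the ranking (descending pIC50). Unparsable or failing
#' entries are collected and reported, never fatal: screening is
#' permissive where model building is strict. A compound whose ten
#' descriptors are all zero is flagged as an out-of-range extrapolation.
#'
#' @param config list with \code{input} (SMILES file) and optional
#'   \code{outDir}, \code{qPolar}, \code{seed}.
#' @param model a \linkS4class{PLSModel} or \linkS4class{QSAREquation}
#'   (default: the frozen CK2 equation).
#' @return data.frame (id, predicted pIC50, predicted IC50 nM, flag),
#'   sorted by decreasing predicted pIC50; failures in attribute
#'   \code{"failures"}.
#' @export
runScreen <- function(config, model = ck2Equation()) {
    config <- .default_config(config)
    hash <- configHash(config)
    smi <- readSmilesFile(config$input)
    mols <- stats::setNames(as.list(smi$smiles), smi$id)
    m <- descriptorTable(mols, qPolar = config$qPolar, onError = "skip")
    fails <- attr(m, "failures")
    pr <- predictActivity(model, m)
    out <- data.frame(id = rownames(m),
                      predicted_pic50 = round(pr$pic50, 4),
                      predicted_ic50_nM = round(pr$ic50_nM, 4),
                      flag = ifelse(rowSums(abs(m[, names(modelCoefficients(model)),
                                                  drop = FALSE])) == 0,
                                    "extrapolation", ""))
    out <- out[order(-out$predicted_pic50), , drop = FALSE]
    rownames(out) <- NULL
    if (!is.null(config$outDir)) {
        dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
        .stamp_csv(out, file.path(config$outDir, "screen.csv"), hash)
        if (length(fails))
            writeLines(fails, file.path(config$outDir, "screen_failures.txt"))
    }
    attr(out, "failures") <- fails
    out
}

#' Validate a frozen model against a labelled compound table
#'
#' Computes descriptors for every compound, predicts with the supplied
#' model and reports external-validation statistics against the measured
#' activities.
#'
#' @param config list with \code{input} (compound CSV with an ic50 column)
#'   and optional \code{units}, \code{qPolar}, \code{outDir}.
#' @param model a \linkS4class{PLSModel} or \linkS4class{QSAREquation}.
#' @return list with \code{r2}, \code{rmse}, \code{n} and the per-compound
#'   prediction table.
#' @export
runValidation <- function(config, model = ck2Equation()) {
    config <- .default_config(config)
    hash <- configHash(config)
    compounds <- readCompoundTable(config$input, units = config$units)
    ds <- buildQSARDataset(compounds, qPolar = config$qPolar)
    act <- activities(ds)
    pred <- predictActivity(model, descriptorMatrix(ds))$pic50
    tab <- data.frame(id = act$id, tested_pic50 = round(act$pic50, 4),
                      predicted_pic50 = round(pred, 4))
    out <- list(r2 = rSquared(act$pic50, pred), rmse = rmse(act$pic50, pred),
                n = nrow(tab), predictions = tab)
    if (!is.null(config$outDir)) {
        dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
        .stamp_csv(tab, file.path(config$outDir, "validation.csv"), hash)
    }
    out
}

#' Report fit statistics from an actual-vs-predicted pairs table
#'
#' The pure-table path of the pipeline: computes r2 and RMSE directly from
#' printed or exported (tested, predicted) pIC50 pairs without touching
#' the descriptor engine.
#'
#' @param pairs data.frame with columns \code{tested_pic50},
#'   \code{predicted_pic50} (or a path to such a CSV).
#' @return list with \code{r2}, \code{rmse}, \code{n}.
#' @examples
#' reportPairs(ck2TrainingPairs())$r2   # 0.94 at 2 d.p.
#' @export
reportPairs <- function(pairs) {
    if (is.character(pairs))
        pairs <- utils::read.csv(pairs, comment.char = "#",
                                 stringsAsFactors = FALSE)
    if (!all(c("tested_pic50", "predicted_pic50") %in% names(pairs)))
        ck2_error("pairs need columns tested_pic50, predicted_pic50",
                  "ck2qsar_data_error")
    list(r2 = rSquared(pairs$tested_pic50, pairs$predicted_pic50),
         rmse = rmse(pairs$tested_pic50, pairs$predicted_pic50),
         n = nrow(pairs))
}
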