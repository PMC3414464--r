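# Interchange: measurement CSV (canonical dialect plus a best-effort
# ImageJ-Results mapping), reference-model JSON and summary JSON. The
# canonical CSV always uses comma delimiter and period decimal separator,
# independent of locale.

.CANONICAL <- c("nucleus_id", "image_id", "Area", "Aspect", "AreaBox",
                "RadRatio", "Roundness")

#' Read a measurement table
#'
#' The \code{nma} dialect expects the canonical header (nucleus_id,
#' image_id, Area, Aspect, AreaBox, RadRatio, Roundness; optional NII,
#' Class; extra columns are preserved). The \code{imagej} dialect maps an
#' ImageJ-Results-style table: a leading unnamed index column becomes
#' nucleus_id and \code{AR} maps to Aspect. Note that ImageJ's built-in
#' \code{Round} is 4 area / (pi major^2) — not the isoperimetric roundness
#' used here — so the AreaBox/RadRatio/Roundness columns must come from an
#' NMA-equivalent plugin export; the reader fails loudly when they are
#' absent rather than silently miscomputing NII.
#'
#' @param path CSV file path.
#' @param dialect "nma" or "imagej".
#' @return measurement data.frame.
#' @export
readMeasurements <- function(path, dialect = c("nma", "imagej")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (dialect == "imagej") {
        nm <- names(df)
        if (nm[1] %in% c("", "X", " ")) nm[1] <- "nucleus_id"
        nm[nm == "AR"] <- "Aspect"
        if ("Round" %in% nm)
            warning(paste("ImageJ's built-in 'Round' (4 area / (pi major^2))",
                          "is not the NMA roundness; the column is kept but",
                          "ignored for NII"))
        names(df) <- nm
        if (!"image_id" %in% nm) df$image_id <- "imagej"
    }
    miss <- setdiff(.CANONICAL, names(df))
    if (length(miss))
        stop("missing required column(s): ", paste(miss, collapse = ", "))
    num <- setdiff(.CANONICAL, c("nucleus_id", "image_id"))
    for (cn in c(num, intersect("NII", names(df)))) {
        v <- suppressWarnings(as.numeric(df[[cn]]))
        bad <- which(!is.finite(v) & !is.na(df[[cn]]) & df[[cn]] != "")
        badNA <- which(is.na(v))
        if (length(badNA))
            stop(sprintf("non-numeric value in column %s, row %d", cn,
                         badNA[1]))
        df[[cn]] <- v
    }
    df
}

#' Write a measurement table
#'
#' Canonical CSV dialect: comma delimiter, period decimal separator,
#' numbers at full double precision (15 significant digits). Deterministic:
#' identical tables produce byte-identical files.
#'
#' @param table measurement data.frame.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeMeasurements <- function(table, path) {
    df <- table
    for (cn in names(df))
        if (is.numeric(df[[cn]]) && !is.integer(df[[cn]]))
            df[[cn]] <- formatC(df[[cn]], digits = 15, format = "g")
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Serialize / restore a reference model as JSON
#'
#' The JSON carries every model field plus provenance (source description
#' and reference n), so a calibration can be reused across sessions and
#' conditions.
#'
#' @param model a \linkS4class{ReferenceModel}.
#' @param path JSON file path.
#' @param source free-text provenance of the calibration data.
#' @return \code{writeReferenceModel} invisibly returns \code{path};
#'   \code{readReferenceModel} returns the model.
#' @export
writeReferenceModel <- function(model, path, source = "") {
    validObject(model)
    obj <- list(mean_area = model@meanArea, sd_area = model@sdArea,
                mean_nii = model@meanNII, sd_nii = model@sdNII,
                k_area = model@kArea, k_nii = model@kNII,
                k_nii_si = model@kNIISi, n_reference = model@nReference,
                source = source)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeReferenceModel
#' @export
readReferenceModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("ReferenceModel", meanArea = obj$mean_area, sdArea = obj$sd_area,
        meanNII = obj$mean_nii, sdNII = obj$sd_nii, kArea = obj$k_area,
        kNII = obj$k_nii, kNIISi = obj$k_nii_si,
        nReference = as.integer(obj$n_reference))
}

#' Write classified table and population summary
#'
#' Writes the classified measurement CSV (input columns plus NII and Class)
#' and a summary JSON holding the per-class counts, percentages (full
#' precision) and means, the model parameters and thresholds, and the total
#' n. Both outputs are deterministic.
#'
#' @param table classified measurement data.frame.
#' @param model the \linkS4class{ReferenceModel} used.
#' @param csvPath,jsonPath output paths (NULL skips the respective file).
#' @return invisibly, the summary list written to JSON.
#' @export
writeOutputs <- function(table, model, csvPath = NULL, jsonPath = NULL) {
    if (!"Class" %in% names(table)) stop("table is not classified")
    summ <- summarizePopulations(table)
    th <- nmaThresholds(model)
    out <- list(
        n = attr(summ, "n"),
        classes = summ,
        model = list(mean_area = model@meanArea, sd_area = model@sdArea,
                     mean_nii = model@meanNII, sd_nii = model@sdNII,
                     k_area = model@kArea, k_nii = model@kNII,
                     k_nii_si = model@kNIISi,
                     n_reference = model@nReference),
        thresholds = as.list(th))
    if (!is.null(csvPath)) writeMeasurements(table, csvPath)
    if (!is.null(jsonPath))
        jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA,
                             dataframe = "columns")
    invisible(out)
}

#' Read a run configuration
#'
#' YAML key-value file mirroring the pipeline parameters; missing keys fall
#' back to the documented defaults.
#'
#' @param path YAML file (NULL for pure defaults).
#' @return named list of configuration values.
#' @export
readRunConfig <- function(path = NULL) {
    defaults <- list(
        calibration = 1, smoothing_sigma = 1, threshold_method = "otsu",
        threshold_value = NA_real_, min_area = 50, max_area = NA_real_,
        exclude_border = TRUE, split_touching = FALSE, connectivity = 8,
        k_area = 2, k_nii = 2, k_nii_si = 4, seed = 1,
        frame = c(2048L, 2048L), snr = 20, n_per_class = 50,
        area_mean = 2000, verbose = TRUE)
    if (is.null(path)) return(defaults)
    cfg <- yaml::read_yaml(path)
    unknown <- setdiff(names(cfg), names(defaults))
    if (length(unknown))
        warning("ignoring unknown config key(s): ",
                paste(unknown, collapse = ", "))
    utils::modifyList(defaults, cfg[intersect(names(cfg), names(defaults))])
}

#' Run the full synthetic pipeline
#'
#' simulate -> segment -> measure -> calibrate (on the normal-phenotype
#' nuclei) -> classify -> summarize, entirely driven by a configuration
#' list and its seed. The reference is fit on the measured nuclei whose
#' ground truth is the normal phenotype, mirroring the curated-control
#' calibration of real workflows.
#'
#' @param config list as returned by \code{\link{readRunConfig}}.
#' @return list with elements scene, mask, table (classified, with
#'   phenotype ground truth), model and summary.
#' @export
runPipeline <- function(config = readRunConfig()) {
    scene <- generatePopulation(
        presetPhenotypes(areaMean = config$area_mean,
                         n = config$n_per_class),
        frameSize = as.integer(config$frame), snr = config$snr,
        seed = config$seed)
    params <- segmentationParams(
        smoothingSigma = config$smoothing_sigma,
        thresholdMethod = config$threshold_method,
        thresholdValue = config$threshold_value,
        minArea = config$min_area, maxArea = config$max_area,
        excludeBorder = config$exclude_border,
        splitTouching = config$split_touching,
        connectivity = config$connectivity)
    mask <- segmentNuclei(scene@image, params)
    tab <- measureNuclei(extractShapes(mask, config$calibration))
    tab <- computeNII(tab)
    tab <- matchTruth(tab, scene)
    model <- suppressWarnings(fitReference(
        tab[tab$phenotype == "normal", ],
        kArea = config$k_area, kNII = config$k_nii,
        kNIISi = config$k_nii_si))
    tab <- classifyNuclei(tab, model)
    summ <- summarizePopulations(tab)
    if (isTRUE(config$verbose)) {
        th <- nmaThresholds(model)
        message(sprintf(
            "n=%d nuclei; thresholds area [%.1f, %.1f], NII %.3f / %.3f",
            attr(summ, "n"), th["areaLow"], th["areaHigh"], th["niiIrr"],
            th["niiSi"]))
        message(paste(sprintf("%s: %d (%.1f%%)", summ$class, summ$count,
                              summ$percent), collapse = "  "))
    }
    list(scene = scene, mask = mask, table = tab, model = model,
         summary = summ)
}
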