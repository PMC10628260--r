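# Slide manifest I/O. Labels are encoded as strings in files and validated
# against the fixed vocabulary on read; MSI is the positive class throughout.

#' Construct a slide manifest
#'
#' @param slide_id,patient_id,label,scanner_id,block_id,path character
#'   vectors of equal length; `label` must be `"MSI"`, `"non-MSI"` or
#'   `"unknown"` (`unknown` only for prediction-only slides).
#' @return a [SlideManifest-class]
#' @examples
#' SlideManifest(slide_id = c("s1", "s2"), patient_id = c("p1", "p2"),
#'               label = c("MSI", "non-MSI"))
#' @export
SlideManifest <- function(slide_id, patient_id, label,
                          scanner_id = "scanner01", block_id = "A",
                          path = "") {
    df <- S4Vectors::DataFrame(
        slide_id = as.character(slide_id),
        patient_id = as.character(patient_id),
        label = as.character(label),
        scanner_id = rep_len(as.character(scanner_id), length(slide_id)),
        block_id = rep_len(as.character(block_id), length(slide_id)),
        path = rep_len(as.character(path), length(slide_id)))
    new("SlideManifest", df)
}

#' Read a slide manifest from CSV
#'
#' The CSV must contain the columns
#' `slide_id,patient_id,label,scanner_id,block_id,path` (`path` may be
#' empty). Duplicate slide ids and unknown label tokens are rejected.
#'
#' @param path CSV file.
#' @return a [SlideManifest-class]
#' @export
readManifest <- function(path) {
    if (!file.exists(path)) stop("manifest file not found: ", path,
                                 call. = FALSE)
    df <- utils::read.csv(path, colClasses = "character")
    miss <- setdiff(setdiff(MANIFEST_COLUMNS, "path"), colnames(df))
    if (length(miss))
        stop("manifest schema error, missing column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    if (!"path" %in% colnames(df)) df$path <- ""
    m <- new("SlideManifest", S4Vectors::DataFrame(df[, MANIFEST_COLUMNS]))
    validObject(m)
    m
}

#' Write a slide manifest to CSV
#'
#' @param manifest a [SlideManifest-class]
#' @param path output CSV file.
#' @export
writeManifest <- function(manifest, path) {
    stopifnot(is(manifest, "SlideManifest"))
    validObject(manifest)
    utils::write.csv(as.data.frame(manifest), path, row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}

setMethod("show", "SlideManifest", function(object) {
    lab <- table(factor(object$label, LABEL_LEVELS))
    cat(sprintf("SlideManifest: %d slides, %d patients (MSI %d / non-MSI %d / unknown %d)\n",
                nrow(object), length(unique(object$patient_id)),
                lab[["MSI"]], lab[["non-MSI"]], lab[["unknown"]]))
    callNextMethod()
})
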