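#' @importFrom utils read.delim write.table
NULL

.readTable <- function(path) {
    if (!file.exists(path))
        stop(sprintf("file not found: '%s'", path), call. = FALSE)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    read.delim(path, sep = sep, check.names = FALSE,
               stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Read a raw intensity matrix
#'
#' Reads a CSV/TSV table of raw median fluorescence intensities. In the
#' default orientation samples are in rows (first column = sample ids, header
#' = antigen ids), as exported by most bead-array readers; set
#' \code{orientation = "antigens_in_rows"} for the transposed dialect. The
#' result always stores antigens in rows, following the
#' \code{SummarizedExperiment} convention.
#'
#' @param path path to a CSV or TSV file.
#' @param orientation layout of the file on disk.
#' @return A \linkS4class{SeroExperiment} with the \code{"MFI"} assay.
#'   Non-numeric, missing, negative or non-finite cells and duplicated ids
#'   are rejected with an error naming the offending coordinates.
#' @seealso [writeIntensityMatrix()]
#' @export
readIntensityMatrix <- function(path,
                                orientation = c("samples_in_rows",
                                                "antigens_in_rows")) {
    orientation <- match.arg(orientation)
    df <- .readTable(path)
    ids <- as.character(df[[1L]])
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop(sprintf("duplicate id in first column: '%s'", dup[1L]),
             call. = FALSE)
    other <- colnames(df)[-1L]
    dup <- unique(other[duplicated(other)])
    if (length(dup))
        stop(sprintf("duplicate id in header: '%s'", dup[1L]), call. = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "double")
    bad <- which(!is.finite(m) | m < 0)
    if (length(bad)) {
        rc <- arrayInd(bad[1L], dim(m))
        stop(sprintf(
            "invalid intensity (missing, non-numeric, negative or non-finite) at row '%s', column '%s'",
            ids[rc[1L]], other[rc[2L]]), call. = FALSE)
    }
    rownames(m) <- ids
    if (orientation == "samples_in_rows") m <- t(m)
    SeroExperiment(m)
}

#' Write a raw intensity matrix
#'
#' @param x a \linkS4class{SeroExperiment} or an antigens-x-samples matrix.
#' @param path output file; ".csv" writes comma-separated, anything else
#'   tab-separated.
#' @param orientation layout on disk (default samples in rows).
#' @return \code{path}, invisibly.
#' @export
writeIntensityMatrix <- function(x, path,
                                 orientation = c("samples_in_rows",
                                                 "antigens_in_rows")) {
    orientation <- match.arg(orientation)
    m <- if (is(x, "SeroExperiment")) mfi(x) else as.matrix(x)
    if (orientation == "samples_in_rows") m <- t(m)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    colnames(df)[1L] <- ""
    write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    invisible(path)
}

.validateEnum <- function(x, levels, field, strict) {
    x <- as.character(x)
    x[is.na(x)] <- "unknown"
    bad <- setdiff(unique(x), levels)
    if (length(bad)) {
        if (strict)
            stop(sprintf("invalid %s value '%s'; allowed: %s", field, bad[1L],
                         paste(levels, collapse = ", ")), call. = FALSE)
        warning(sprintf("%s: %d value(s) outside {%s} mapped to 'unknown'",
                        field, sum(x %in% bad), paste(levels, collapse = ", ")),
                call. = FALSE)
        x[x %in% bad] <- "unknown"
    }
    factor(x, levels = levels)
}

#' Read per-sample clinical metadata
#'
#' Reads a CSV/TSV with one row per serum sample. Required columns:
#' \code{sample_id}, \code{group} (AAV, GCA, PMR or HC). Recognized optional
#' columns: \code{subject_id}, \code{site}, \code{timepoint},
#' \code{anca_serotype}, \code{phenotype}, \code{sex}, \code{age},
#' \code{on_treatment}, \code{bvas}, \code{organ_involvement}
#' (semicolon-separated subset of kidney;ENT;respiratory). Structural fields
#' (\code{group}, \code{site}, \code{timepoint}) reject unknown categories
#' with an error listing the allowed values; \code{anca_serotype},
#' \code{phenotype} and \code{sex} map unrecognized values to
#' \code{"unknown"} with a warning. Missing values are kept as explicit
#' missing markers, never dropped.
#'
#' @param path path to the metadata file.
#' @return A [S4Vectors::DataFrame] keyed by \code{sample_id}, suitable as
#'   \code{colData} for [SeroExperiment()].
#' @export
readSampleMetadata <- function(path) {
    df <- .readTable(path)
    if (!"sample_id" %in% colnames(df))
        stop("metadata must contain a 'sample_id' column", call. = FALSE)
    if (!"group" %in% colnames(df))
        stop("metadata must contain a 'group' column", call. = FALSE)
    n <- nrow(df)
    get <- function(col, default) if (col %in% colnames(df)) df[[col]] else
        rep(default, length.out = n)
    out <- DataFrame(
        sample_id = as.character(df$sample_id),
        subject_id = as.character(get("subject_id", df$sample_id)),
        group = .validateEnum(df$group, .GROUP_LEVELS, "group", strict = TRUE),
        site = .validateEnum(get("site", "SYNTH"), .SITE_LEVELS, "site",
                             strict = TRUE),
        timepoint = .validateEnum(get("timepoint", "single"),
                                  .TIMEPOINT_LEVELS, "timepoint",
                                  strict = TRUE),
        anca_serotype = .validateEnum(get("anca_serotype", "unknown"),
                                      .ANCA_LEVELS, "anca_serotype", FALSE),
        phenotype = .validateEnum(get("phenotype", "unknown"),
                                  .PHENOTYPE_LEVELS, "phenotype", FALSE),
        sex = .validateEnum(get("sex", "unknown"), .SEX_LEVELS, "sex", FALSE),
        age = suppressWarnings(as.numeric(get("age", NA))),
        on_treatment = as.logical(get("on_treatment", NA)),
        bvas = suppressWarnings(as.integer(get("bvas", NA))),
        organ_involvement = {
            oi <- as.character(get("organ_involvement", ""))
            oi[is.na(oi)] <- ""
            oi
        }
    )
    if (anyNA(out$group))
        stop("missing values in 'group'", call. = FALSE)
    nonAAV <- out$group != "AAV"
    if (any(nonAAV & out$timepoint != "single"))
        stop("non-AAV samples must have timepoint 'single'", call. = FALSE)
    out$phenotype[nonAAV] <- "not_applicable"
    key <- paste(out$subject_id, out$timepoint)
    dup <- unique(key[duplicated(key)])
    if (length(dup))
        stop(sprintf("duplicate (subject_id, timepoint): '%s'", dup[1L]),
             call. = FALSE)
    org <- strsplit(out$organ_involvement, ";", fixed = TRUE)
    bad <- setdiff(unlist(org), c(.ORGAN_LEVELS, ""))
    if (length(bad))
        stop(sprintf("invalid organ_involvement value '%s'; allowed: %s",
                     bad[1L], paste(.ORGAN_LEVELS, collapse = ", ")),
             call. = FALSE)
    for (o in .ORGAN_LEVELS)
        out[[paste0("organ_", o)]] <- vapply(org, function(v) o %in% v, NA)
    rownames(out) <- out$sample_id
    out
}

#' Read antigen fragment annotation
#'
#' Reads a CSV/TSV with columns \code{antigen_id}, \code{gene_symbol},
#' \code{uniprot_id}, \code{aa_start}, \code{aa_end} and optional
#' \code{family_tag}. Fragment coordinates are 1-based inclusive; lengths
#' outside the typical 40-100 amino-acid range of fragment antigens raise a
#' warning (not an error).
#'
#' @param path path to the annotation file.
#' @return A [S4Vectors::DataFrame] keyed by \code{antigen_id}.
#' @export
readAntigenAnnotation <- function(path) {
    df <- .readTable(path)
    req <- c("antigen_id", "gene_symbol", "uniprot_id", "aa_start", "aa_end")
    miss <- setdiff(req, colnames(df))
    if (length(miss))
        stop(sprintf("annotation is missing column(s): %s",
                     paste(miss, collapse = ", ")), call. = FALSE)
    out <- DataFrame(
        antigen_id = as.character(df$antigen_id),
        gene_symbol = as.character(df$gene_symbol),
        uniprot_id = as.character(df$uniprot_id),
        aa_start = as.integer(df$aa_start),
        aa_end = as.integer(df$aa_end),
        family_tag = if ("family_tag" %in% colnames(df))
            as.character(df$family_tag) else NA_character_
    )
    if (any(out$aa_start < 1L | out$aa_end < out$aa_start))
        stop("fragment coordinates must satisfy 1 <= aa_start <= aa_end",
             call. = FALSE)
    len <- out$aa_end - out$aa_start + 1L
    n_out <- sum(len < 40L | len > 100L)
    if (n_out)
        warning(sprintf("%d fragment(s) outside the typical 40-100 aa range",
                        n_out), call. = FALSE)
    rownames(out) <- out$antigen_id
    out
}

#' Sample-level quality filter
#'
#' Removes samples whose fraction of valid antigen measurements (strictly
#' positive intensities) falls below \code{minValidFraction}. Every exclusion
#' is recorded, with the observed valid fraction, in
#' \code{metadata(x)$qc_exclusions} (see [qcExclusions()]); the rule is a
#' deterministic, auditable stand-in for ad-hoc technical exclusions.
#' Idempotent: filtering a filtered object changes nothing.
#'
#' @param x a \linkS4class{SeroExperiment}.
#' @param minValidFraction minimum fraction of valid measurements required to
#'   keep a sample, in (0, 1\]; default 0.9.
#' @return The filtered \linkS4class{SeroExperiment}; errors if every sample
#'   would be excluded.
#' @export
qcFilter <- function(x, minValidFraction = 0.9) {
    stopifnot(is(x, "SeroExperiment"),
              minValidFraction > 0, minValidFraction <= 1)
    frac <- colMeans(mfi(x) > 0)
    drop <- frac < minValidFraction
    if (all(drop))
        stop("qcFilter would exclude every sample", call. = FALSE)
    new_ex <- data.frame(sample_id = colnames(x)[drop],
                         valid_fraction = unname(frac[drop]),
                         reason = sprintf("valid fraction %.3f < %.3f",
                                          frac[drop], minValidFraction))
    out <- x[, !drop]
    metadata(out)$qc_exclusions <- rbind(qcExclusions(x), new_ex)
    out
}

#' Write the QC exclusion report as JSON lines
#'
#' @param x a filtered \linkS4class{SeroExperiment}.
#' @param path output file; one JSON object per excluded sample.
#' @return \code{path}, invisibly.
#' @export
writeExclusionReport <- function(x, path) {
    ex <- qcExclusions(x)
    lines <- vapply(seq_len(nrow(ex)), function(i)
        jsonlite::toJSON(as.list(ex[i, ]), auto_unbox = TRUE), character(1L))
    writeLines(lines, path)
    invisible(path)
}
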