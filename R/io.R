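## Tabular I/O.  Dialect: UTF-8, tab-delimited, '.' decimal separator,
## first column always the identifier.  Expression-table headers encode one
## array per column as "<cellLine>|<condition>|<replicate>".

#' Write a ResponseExperiment as a tab-delimited table
#'
#' One row per probe set; column headers encode each array as
#' \code{cellLine|condition|replicate}.  Missing values are written as
#' \code{NA}.  A scale comment line (\code{# scale: linear|log2}) is placed
#' before the header so round trips preserve the scale flag.
#'
#' @param x a [ResponseExperiment-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso [readExpressionTable()]
#' @export
writeExpressionTable <- function(x, path) {
    stopifnot(is(x, "ResponseExperiment"))
    cd <- colData(x)
    hdr <- paste(cd$cellLine, cd$condition, cd$replicate, sep = "|")
    m <- assay(x, "fluorescence")
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("# scale: ", expressionScale(x)), con)
    writeLines(paste(c("probe_set", hdr), collapse = "\t"), con)
    body <- cbind(rownames(m),
                  matrix(format(m, trim = TRUE, digits = 15), nrow = nrow(m)))
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
    invisible(path)
}

#' Read a tab-delimited ligand-response expression table
#'
#' Expects the dialect written by [writeExpressionTable()]: an optional
#' \code{# scale:} comment, a header row whose array columns are labeled
#' \code{cellLine|condition|replicate}, and one probe set per row (first
#' column).  Values must be non-negative on the linear scale; empty cells
#' and \code{NA} are treated as missing and the affected probe sets are
#' later excluded from fold-change calling.
#'
#' @param path input file.
#' @param scale override the scale flag (\code{"linear"} or \code{"log2"});
#'   default uses the file's comment, falling back to linear.
#' @return a [ResponseExperiment-class].
#' @export
readExpressionTable <- function(path, scale = NULL) {
    lines <- readLines(path, encoding = "UTF-8")
    fileScale <- "linear"
    scaleLn <- grep("^#\\s*scale:", lines)
    if (length(scaleLn))
        fileScale <- trimws(sub("^#\\s*scale:", "", lines[scaleLn[1]]))
    lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    if (length(lines) < 1L) stop("no data rows in '", path, "'")
    hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(hdr) < 2L) stop("header must name at least one array column")
    parts <- strsplit(hdr[-1], "|", fixed = TRUE)
    bad <- which(lengths(parts) != 3L)
    if (length(bad))
        stop("malformed header field(s) (need cellLine|condition|replicate): ",
             paste(hdr[-1][bad], collapse = ", "))
    lab <- do.call(rbind, parts)
    if (length(lines) < 2L) stop("no data rows in '", path, "'")
    rows <- strsplit(lines[-1], "\t", fixed = TRUE)
    nc <- length(hdr)
    rows <- lapply(rows, function(r) { length(r) <- nc; r })
    ids <- vapply(rows, `[`, character(1), 1L)
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate probe-set identifier(s): ",
             paste(dup, collapse = ", "))
    vals <- vapply(rows, function(r) {
        v <- r[-1]
        v[!nzchar(v) | is.na(v) | v == "NA"] <- NA_character_
        as.numeric(v)
    }, numeric(nc - 1L))
    m <- matrix(t(vals), nrow = length(ids), ncol = nc - 1L,
                dimnames = list(ids, NULL))
    if (!is.null(scale)) fileScale <- scale
    if (identical(fileScale, "linear") && any(m < 0, na.rm = TRUE))
        stop("negative fluorescence value(s) in linear-scale table")
    ResponseExperiment(m, cellLine = lab[, 1], condition = lab[, 2],
                       replicate = as.integer(lab[, 3]), scale = fileScale)
}

#' Read a probe-set to gene-symbol annotation map
#'
#' Two-column tab-delimited file (\code{probe_set}, \code{gene}); a header
#' row with those names is skipped if present.  A probe set listed several
#' times with the same gene is collapsed; conflicting genes for one probe
#' set are an error (the map must be a function).  An empty file is a valid
#' empty map: all probe sets are then unannotated.
#'
#' @param path input file.
#' @return named character vector, probe set -> gene symbol.
#' @export
readAnnotation <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
    if (!length(lines)) return(stats::setNames(character(), character()))
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) < 2L))
        stop("annotation rows must have two tab-separated columns")
    ps <- vapply(f, `[`, character(1), 1L)
    gn <- vapply(f, `[`, character(1), 2L)
    if (identical(tolower(ps[1]), "probe_set")) {
        ps <- ps[-1]; gn <- gn[-1]
        if (!length(ps)) return(stats::setNames(character(), character()))
    }
    tab <- unique(data.frame(ps, gn, stringsAsFactors = FALSE))
    conf <- unique(tab$ps[duplicated(tab$ps)])
    if (length(conf))
        stop("probe set(s) mapped to conflicting genes: ",
             paste(conf, collapse = ", "))
    stats::setNames(tab$gn, tab$ps)
}

#' @rdname readAnnotation
#' @param annotation named character vector to write.
#' @export
writeAnnotation <- function(annotation, path) {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines("probe_set\tgene", con)
    if (length(annotation))
        writeLines(paste(names(annotation), annotation, sep = "\t"), con)
    invisible(path)
}

#' Read / write a receptor design matrix
#'
#' Tab-delimited: first column \code{receptor}, remaining columns one per
#' cell line, entries 0/1.
#'
#' @param path input (or output) file.
#' @return [ReceptorDesign-class] for the reader; \code{path} invisibly for
#'   the writer.
#' @export
readReceptorDesign <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("design needs a receptor column and >= 1 line")
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    ReceptorDesign(m)
}

#' @rdname readReceptorDesign
#' @param design a [ReceptorDesign-class] to write.
#' @export
writeReceptorDesign <- function(design, path) {
    stopifnot(is(design, "ReceptorDesign"))
    m <- presenceMatrix(design)
    tab <- data.frame(receptor = rownames(m), (m * 1L),
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a GEO Series Matrix file into a ResponseExperiment
#'
#' Parses the plain-text Series Matrix format: \code{!}-prefixed metadata
#' lines followed by the sample table delimited by
#' \code{!series_matrix_table_begin} / \code{!series_matrix_table_end}.
#' Sample titles (from \code{!Sample_title}) are translated into
#' \code{(cellLine, condition, replicate)} via \code{sampleMap}; a title
#' absent from the map is an error.  Deposited values may be linear or
#' log2-scaled; with \code{scale = "auto"} the loader scans the
#' \code{!Sample_data_processing} / \code{!Series_summary} metadata for a
#' log2 mention and records the result, which downstream fold-change
#' computation honours (\code{fold = 2^(mean log2 treated - mean log2
#' control)}).
#'
#' @param path Series Matrix text file.
#' @param sampleMap \code{data.frame} with columns \code{title},
#'   \code{cellLine}, \code{condition}, \code{replicate}.
#' @param scale \code{"auto"} (default), \code{"linear"} or \code{"log2"}.
#' @return a [ResponseExperiment-class].
#' @export
readGEOSeriesMatrix <- function(path, sampleMap,
                                scale = c("auto", "linear", "log2")) {
    scale <- match.arg(scale)
    stopifnot(is.data.frame(sampleMap),
              all(c("title", "cellLine", "condition", "replicate") %in%
                  colnames(sampleMap)))
    lines <- readLines(path, encoding = "UTF-8")
    meta <- lines[startsWith(lines, "!")]
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1L)
        stop("malformed Series Matrix: table-begin marker not found")
    if (length(end) != 1L || end <= begin)
        stop("malformed Series Matrix: table-end marker not found")
    titleLn <- grep("^!Sample_title\\b", meta, value = TRUE)
    if (!length(titleLn)) stop("no !Sample_title metadata line")
    unquote <- function(x) gsub('^"|"$', "", x)
    titles <- unquote(strsplit(titleLn[1], "\t", fixed = TRUE)[[1]][-1])

    block <- lines[(begin + 1L):(end - 1L)]
    if (length(block) < 2L) stop("malformed Series Matrix: empty table block")
    cells <- lapply(strsplit(block, "\t", fixed = TRUE), unquote)
    nc <- length(cells[[1]])
    if (any(lengths(cells) != nc))
        stop("malformed Series Matrix: ragged table block")
    ids <- vapply(cells[-1], `[`, character(1), 1L)
    m <- vapply(cells[-1], function(r) suppressWarnings(as.numeric(r[-1])),
                numeric(nc - 1L))
    m <- matrix(t(m), nrow = length(ids), dimnames = list(ids, NULL))
    if (length(titles) != ncol(m))
        stop("sample-title count does not match table columns")

    hit <- match(titles, sampleMap$title)
    if (anyNA(hit))
        stop("sample title(s) not in sampleMap: ",
             paste(titles[is.na(hit)], collapse = ", "))
    if (scale == "auto") {
        procLn <- grep("^!(Sample_data_processing|Series_summary)", meta,
                       value = TRUE)
        scale <- if (any(grepl("log2|log-2|log 2", procLn,
                               ignore.case = TRUE))) "log2" else "linear"
    }
    ResponseExperiment(m, cellLine = sampleMap$cellLine[hit],
                       condition = sampleMap$condition[hit],
                       replicate = as.integer(sampleMap$replicate[hit]),
                       scale = scale)
}

#' Read / write sample-level cohort and intervention tables
#'
#' Plain tab-delimited tables with a header row; [readInterventionTable()]
#' checks for the \code{animal_id}, \code{group} and \code{measurement}
#' columns and positive measurements.
#'
#' @param path file path.
#' @return \code{data.frame}.
#' @export
readCohortTable <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (!nrow(tab)) stop("no data rows in '", path, "'")
    tab
}

#' @rdname readCohortTable
#' @export
readInterventionTable <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    need <- c("animal_id", "group", "measurement")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("intervention table is missing column(s): ",
             paste(miss, collapse = ", "))
    if (any(tab$measurement <= 0))
        stop("measurements must be strictly positive")
    if (anyDuplicated(tab$animal_id))
        stop("each animal must appear exactly once")
    tab
}

#' @rdname readCohortTable
#' @param x \code{data.frame} to write.
#' @export
writeSampleTable <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
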