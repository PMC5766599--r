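#' @include AllClasses.R
NULL

## Single on-disk dialect: tab-delimited, UTF-8, '.' decimal, header row.
.readTsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty file: ", path)
  read.delim(path, header = TRUE, sep = "\t", quote = "",
             check.names = FALSE, stringsAsFactors = FALSE, ...)
}

.writeTsv <- function(df, path, rowNames = FALSE) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = rowNames, col.names = TRUE)
  invisible(path)
}

.requireColumns <- function(df, cols, what) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "))
}

#' Read and write count matrices
#'
#' `readCounts()` parses a tab-delimited count file (first column feature
#' ids, header row of sample ids) into a validated integer matrix;
#' `writeCounts()` writes one back in the identical dialect, so the two are
#' exact inverses. Non-integer, negative or missing cells and duplicated
#' identifiers are hard errors with the offending coordinates named; no
#' silent coercion.
#'
#' @param path file path
#' @param counts integer matrix with feature rownames and sample colnames,
#'   or a [LncCountExperiment-class]
#' @return `readCounts()` returns an integer matrix; `writeCounts()` the
#'   path, invisibly.
#' @examples
#' m <- matrix(1:6, 2, 3,
#'             dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
#' tf <- tempfile(fileext = ".tsv")
#' writeCounts(m, tf)
#' stopifnot(identical(readCounts(tf), m))
#' @export
readCounts <- function(path) {
  df <- .readTsv(path, colClasses = "character")
  if (ncol(df) < 2L) stop("count file needs a feature-id column and at least one sample column: ", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  cnt <- matrix(NA_integer_, nrow(df), length(samples),
                dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    raw <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) | num < 0 | num != round(num))
    if (length(bad))
      stop(sprintf("invalid count '%s' at feature '%s', sample '%s' (row %d, column %d)",
                   raw[bad[1]], ids[bad[1]], samples[j], bad[1], j + 1L))
    cnt[, j] <- as.integer(num)
  }
  cnt
}

#' @rdname readCounts
#' @export
writeCounts <- function(counts, path) {
  if (is(counts, "LncCountExperiment")) counts <- countsMatrix(counts)
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE)
  .writeTsv(df, path)
}

#' Read sample sheets, annotations, gene sets and id lists
#'
#' Readers for the pipeline's tabular inputs. All are strict: unknown
#' condition or stage tokens, missing columns and inconsistent identifiers
#' raise structured errors rather than coercing. `readSampleSheet()` can
#' cross-check the sheet against a count matrix and, in paired mode,
#' enforce exactly one tumor and one normal sample per patient.
#' `readGeneSets()` drops duplicated (feature, set) rows with a warning.
#' `readIdList()` reads one id per line, ignoring blank lines and `#`
#' comments.
#'
#' @param path file path
#' @param counts optional count matrix to cross-check sample ids against
#' @param paired enforce the one tumor + one normal per patient invariant?
#' @return `readSampleSheet()`, `readAnnotation()` return `data.frame`s;
#'   `readGeneSets()` a named list of character vectors (one per set);
#'   `readIdList()` a character vector.
#' @name readers
#' @examples
#' tf <- tempfile()
#' writeLines(c("# known ids", "CCAT1", "MEG3"), tf)
#' readIdList(tf)
NULL

#' @rdname readers
#' @export
readSampleSheet <- function(path, counts = NULL, paired = FALSE) {
  df <- .readTsv(path, colClasses = "character")
  .requireColumns(df, c("sample_id", "patient_id", "condition", "stage"),
                  "sample sheet")
  df$stage[df$stage %in% c("NA", "")] <- NA_character_
  badCond <- setdiff(unique(df$condition), .CONDITIONS)
  if (length(badCond))
    stop("unknown condition token(s): ", paste(badCond, collapse = ", "))
  badStage <- setdiff(unique(df$stage[!is.na(df$stage)]), .STAGES)
  if (length(badStage))
    stop("unknown stage token(s): ", paste(badStage, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s) in sample sheet")
  if (!is.null(counts)) {
    miss <- setdiff(colnames(counts), df$sample_id)
    if (length(miss))
      stop("sample(s) in counts missing from sheet: ",
           paste(miss, collapse = ", "))
  }
  if (paired) validatePairing(df)
  df[, c("sample_id", "patient_id", "condition", "stage")]
}

#' Validate a paired tumor/normal design
#'
#' Checks that every patient contributes exactly one tumor and one normal
#' sample, the invariant the paired GLM design requires.
#'
#' @param sheet a sample-sheet `data.frame`
#' @return The sheet, invisibly; errors name the offending patients.
#' @export
validatePairing <- function(sheet) {
  tab <- table(sheet$patient_id, factor(sheet$condition,
                                        levels = .CONDITIONS))
  bad <- rownames(tab)[tab[, "tumor"] != 1L | tab[, "normal"] != 1L]
  if (length(bad))
    stop("paired mode requires exactly one tumor and one normal sample per patient; violated by: ",
         paste(bad, collapse = ", "))
  invisible(sheet)
}

#' @rdname readers
#' @export
readAnnotation <- function(path) {
  df <- .readTsv(path, colClasses = "character")
  .requireColumns(df, c("feature_id", "symbol", "biotype", "is_lncRNA"),
                  "annotation")
  if (anyDuplicated(df$feature_id)) stop("duplicate feature id(s) in annotation")
  badBio <- setdiff(unique(df$biotype), .BIOTYPES)
  if (length(badBio))
    stop("unknown biotype token(s): ", paste(badBio, collapse = ", "))
  df$is_lncRNA <- df$is_lncRNA %in% c("TRUE", "True", "true", "1")
  df[, c("feature_id", "symbol", "biotype", "is_lncRNA")]
}

#' @rdname readers
#' @export
readGeneSets <- function(path) {
  df <- .readTsv(path, colClasses = "character")
  .requireColumns(df, c("feature_id", "set_id"), "gene-set table")
  dup <- duplicated(df[, c("feature_id", "set_id")])
  if (any(dup)) {
    warning(sum(dup), " duplicated (feature, set) row(s) removed")
    df <- df[!dup, , drop = FALSE]
  }
  split(df$feature_id, df$set_id)
}

#' @rdname readers
#' @export
readIdList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

#' Write the simulator's tabular outputs
#'
#' Writers for sample sheets, feature annotations, gene-set membership
#' tables, truth tables and differential-expression result tables, all in
#' the package's single tab-delimited dialect. Each writer round-trips with
#' its reader.
#'
#' @param sheet,annotation,truth,results a `data.frame`
#' @param sets a named list of character vectors (set id -> feature ids)
#' @param path file path
#' @return The path, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
writeSampleSheet <- function(sheet, path) {
  sheet$stage[is.na(sheet$stage)] <- "NA"
  .writeTsv(sheet, path)
}

#' @rdname writers
#' @export
writeAnnotation <- function(annotation, path) .writeTsv(annotation, path)

#' @rdname writers
#' @export
writeGeneSets <- function(sets, path) {
  df <- data.frame(feature_id = unlist(sets, use.names = FALSE),
                   set_id = rep(names(sets), lengths(sets)))
  .writeTsv(df, path)
}

#' @rdname writers
#' @export
writeTruth <- function(truth, path) .writeTsv(truth, path)

#' @rdname writers
#' @export
writeDEResults <- function(results, path) {
  if (is(results, "DEResultSet")) results <- deResults(results)
  .writeTsv(results, path)
}

#' Read a differential-expression result table
#'
#' Parses a DE result table with possibly censored significance columns:
#' printed values of the form `<x` (for example `<0.001`) are read as `x/2`,
#' the midpoint of the censoring interval `[0, x)`. The rule only matters
#' for display; any censored value below a threshold passes that threshold
#' regardless of the midpoint convention.
#'
#' @param path file path
#' @param numericCols columns to decensor and convert
#' @return A `data.frame` with the named columns numeric.
#' @examples
#' t2 <- system.file("extdata", "table2.tsv", package = "lncDiscoveR")
#' head(readDETable(t2))
#' @export
readDETable <- function(path,
                        numericCols = intersect(c("logFC", "log2FC",
                                                  "p_value", "fdr",
                                                  "fdr_confirm"),
                                                colnames(.readTsv(path)))) {
  df <- .readTsv(path, colClasses = "character")
  for (col in intersect(numericCols, colnames(df)))
    df[[col]] <- .decensor(df[[col]], col)
  df
}

.decensor <- function(x, col) {
  cens <- grepl("^<", x)
  out <- suppressWarnings(as.numeric(x))
  out[cens] <- suppressWarnings(as.numeric(sub("^<", "", x[cens]))) / 2
  if (anyNA(out))
    stop("non-numeric value(s) in column '", col, "': ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}
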