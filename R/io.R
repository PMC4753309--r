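# Plain-text I/O: CSV/TSV with '#'-prefixed metadata comments, Newick trees
# and JSON reports. Writers are deterministic (stable column order, numbers
# at 10 significant digits) so outputs diff cleanly.

.fmt_num <- function(x) sprintf("%.10g", x)

.read_commented <- function(path, sep = ",") {
  lines <- readLines(path)
  is_comment <- startsWith(trimws(lines), "#")
  meta <- list()
  for (ln in lines[is_comment]) {
    kv <- sub("^\\s*#\\s*", "", ln)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- sub("=.*$", "", kv)
      meta[[trimws(key)]] <- trimws(sub("^[^=]*=", "", kv))
    }
  }
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (!length(body_idx)) stop("no data rows in ", path)
  df <- utils::read.table(text = lines[body_idx], sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "meta") <- meta
  attr(df, "line_numbers") <- body_idx[-1]   # data rows (after header)
  df
}

.check_numeric_col <- function(df, col, path) {
  v <- df[[col]]
  if (is.numeric(v)) return(as.numeric(v))
  suppress <- suppressWarnings(as.numeric(v))
  if (anyNA(suppress) && !all(is.na(v))) {
    bad <- which(is.na(suppress) & !is.na(v) & v != "NA")
    lines <- attr(df, "line_numbers")[bad]
    stop("non-numeric value(s) in column '", col, "' of ", path,
         " at line(s) ", paste(lines, collapse = ", "))
  }
  suppress
}

#' Read / write an accretion series CSV
#'
#' Columns `t_days,x,censored` with metadata comment lines `# units=` and
#' `# what=`. Round-trips an [AccretionSeries-class] losslessly (values at
#' 10 significant digits).
#'
#' @param path file path.
#' @return [AccretionSeries-class] for the reader; the path, invisibly, for
#'   the writer.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeSeries(genAccretionSeries(siteConfig("osp")), f)
#' readSeries(f)
#' @export
readSeries <- function(path) {
  df <- .read_commented(path)
  need <- setdiff(c("t_days", "x"), names(df))
  if (length(need))
    stop(path, " is missing required column(s): ",
         paste(need, collapse = ", "))
  meta <- attr(df, "meta")
  accretionSeries(
    .check_numeric_col(df, "t_days", path),
    .check_numeric_col(df, "x", path),
    censored = if ("censored" %in% names(df)) as.logical(df$censored)
               else rep(FALSE, nrow(df)),
    units = meta$units %||% "", what = meta$what %||% "Fe")
}

#' @rdname readSeries
#' @param series an [AccretionSeries-class].
#' @export
writeSeries <- function(series, path) {
  stopifnot(is(series, "AccretionSeries"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("# units=", series@units),
               paste0("# what=", series@what),
               "t_days,x,censored",
               paste(.fmt_num(obsTimes(series)), .fmt_num(obsValues(series)),
                     isCensored(series), sep = ",")), con)
  invisible(path)
}

#' Read / write an oxygen microprofile CSV
#'
#' Columns `z_um,c_uM` with metadata comments `# c_bulk_uM=` and
#' `# temperature_c=`.
#'
#' @param path file path.
#' @return [Microprofile-class] for the reader; the path, invisibly, for the
#'   writer.
#' @export
readProfile <- function(path) {
  df <- .read_commented(path)
  need <- setdiff(c("z_um", "c_uM"), names(df))
  if (length(need))
    stop(path, " is missing required column(s): ",
         paste(need, collapse = ", "))
  meta <- attr(df, "meta")
  if (is.null(meta$c_bulk_uM))
    stop(path, " is missing the '# c_bulk_uM=' metadata comment")
  microprofile(.check_numeric_col(df, "z_um", path),
               .check_numeric_col(df, "c_uM", path),
               C_bulk = as.numeric(meta$c_bulk_uM),
               temperature = as.numeric(meta$temperature_c %||% NA))
}

#' @rdname readProfile
#' @param profile a [Microprofile-class].
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "Microprofile"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("# c_bulk_uM=", .fmt_num(bulkConc(profile))),
               if (!is.na(profile@temperature))
                 paste0("# temperature_c=", .fmt_num(profile@temperature)),
               "z_um,c_uM",
               paste(.fmt_num(profileDepths(profile)),
                     .fmt_num(profileConc(profile)), sep = ",")), con)
  invisible(path)
}

#' Read / write a taxon-by-sample abundance TSV
#'
#' First column `taxon`, remaining columns sample IDs (e.g. `osp_day04`).
#' Metadata comments carry the assay mode, per-taxon copy numbers and
#' per-sample site/day/depth-zone annotations:
#' `# mode=`, `# copy_numbers=taxon:cn;...`, `# site=`, `# day=`,
#' `# depth_zone=` (comma-separated, aligned with the sample columns).
#'
#' @param path file path.
#' @return [MatCommunity-class] for the reader; the path, invisibly, for the
#'   writer.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeAbundance(genCommunityTable(siteConfig("osp")), f)
#' readAbundance(f)
#' @export
readAbundance <- function(path) {
  df <- .read_commented(path, sep = "\t")
  if (names(df)[1] != "taxon")
    stop(path, ": first column must be 'taxon'")
  dup <- names(df)[-1][duplicated(names(df)[-1])]
  if (length(dup))
    stop(path, ": duplicate sample column(s): ",
         paste(unique(dup), collapse = ", "))
  meta <- attr(df, "meta")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    for (col in names(df)[-1]) .check_numeric_col(df, col, path)
    m <- apply(m, 2, as.numeric)
  }
  rownames(m) <- df$taxon
  cn <- rep(1, nrow(m))
  if (!is.null(meta$copy_numbers)) {
    pairs <- strsplit(strsplit(meta$copy_numbers, ";")[[1]], ":")
    cn_map <- stats::setNames(as.numeric(vapply(pairs, `[`, "", 2)),
                              vapply(pairs, `[`, "", 1))
    cn <- unname(cn_map[rownames(m)])
    cn[is.na(cn)] <- 1
  }
  split_meta <- function(key, default, cast = identity) {
    if (is.null(meta[[key]])) return(rep(default, ncol(m)))
    v <- strsplit(meta[[key]], ",")[[1]]
    v[v == "NA"] <- NA
    cast(v)
  }
  MatCommunity(m, copy_number = cn,
               site = split_meta("site", "unknown"),
               day = split_meta("day", NA_real_, as.numeric),
               depth_zone = split_meta("depth_zone", "none"),
               mode = meta$mode %||% "counts")
}

#' @rdname readAbundance
#' @param x a [MatCommunity-class].
#' @export
writeAbundance <- function(x, path) {
  stopifnot(is(x, "MatCommunity"))
  a <- abundances(x)
  cd <- SummarizedExperiment::colData(x)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste0("# mode=", abundanceMode(x)),
    paste0("# copy_numbers=",
           paste(rownames(a), .fmt_num(copyNumbers(x)), sep = ":",
                 collapse = ";")),
    paste0("# site=", paste(cd$site, collapse = ",")),
    paste0("# day=", paste(cd$day, collapse = ",")),
    paste0("# depth_zone=", paste(cd$depth_zone, collapse = ",")),
    paste(c("taxon", colnames(a)), collapse = "\t"),
    vapply(seq_len(nrow(a)), function(i)
      paste(c(rownames(a)[i], .fmt_num(a[i, ])), collapse = "\t"), "")), con)
  invisible(path)
}

#' Read a long-format ICP extraction CSV
#'
#' Columns `t_days,element,mg_per_L`; metadata comments
#' `# extraction_volume_L=`, `# slide_area_cm2=`, `# site=` override the
#' defaults.
#'
#' @param path file path.
#' @param extraction_volume,slide_area defaults when the file carries no
#'   metadata comments.
#' @return An [ExtractionSet-class].
#' @export
readIcp <- function(path, extraction_volume = 0.05, slide_area = 18.75) {
  df <- .read_commented(path)
  need <- setdiff(c("t_days", "element", "mg_per_L"), names(df))
  if (length(need))
    stop(path, " is missing required column(s): ",
         paste(need, collapse = ", "))
  meta <- attr(df, "meta")
  extractionSet(
    data.frame(t_days = .check_numeric_col(df, "t_days", path),
               element = as.character(df$element),
               mg_per_L = .check_numeric_col(df, "mg_per_L", path)),
    extraction_volume = as.numeric(meta$extraction_volume_L %||%
                                     extraction_volume),
    slide_area = as.numeric(meta$slide_area_cm2 %||% slide_area),
    site = meta$site %||% "unknown")
}

#' @rdname readIcp
#' @param record an [ExtractionSet-class].
#' @export
writeIcp <- function(record, path) {
  stopifnot(is(record, "ExtractionSet"))
  con <- file(path, "w"); on.exit(close(con))
  d <- record@data
  writeLines(c(
    paste0("# extraction_volume_L=", .fmt_num(record@extraction_volume)),
    paste0("# slide_area_cm2=", .fmt_num(record@slide_area)),
    paste0("# site=", record@site),
    "t_days,element,mg_per_L",
    paste(.fmt_num(d$t_days), d$element, .fmt_num(d$mg_per_L), sep = ",")),
    con)
  invisible(path)
}

#' Serialise a dendrogram as Newick
#'
#' Converts an `hclust` tree to `phylo` and writes Newick with branch
#' lengths; labels containing whitespace are single-quoted.
#'
#' @param tree an `hclust` (e.g. from [clusterDendrogram()]) or `phylo`.
#' @param path file path.
#' @return The path, invisibly.
#' @export
writeNewick <- function(tree, path) {
  if (inherits(tree, "hclust")) tree <- ape::as.phylo(tree)
  stopifnot(inherits(tree, "phylo"))
  ws <- grepl("\\s", tree$tip.label)
  tree$tip.label[ws] <- paste0("'", tree$tip.label[ws], "'")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' Scalar values are unboxed and numbers written at full precision, so
#' reports are both human-readable and machine-comparable.
#'
#' @param x a named list of results.
#' @param path file path.
#' @return The path, invisibly.
#' @export
writeJsonReport <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
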