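#' Construct an abundance table
#'
#' The package's central container: a taxa x samples (or KO x samples)
#' non-negative numeric matrix with unique row and column identifiers and a
#' `kind` tag distinguishing raw counts from relative abundances (columns
#' summing to 1).
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   dimnames.
#' @param kind `"counts"`, `"relative"`, or `"abundance"` (raw non-negative
#'   values that are neither integer counts nor closed compositions, e.g.
#'   normalized KO depths). If `NULL`, inferred: an integer-valued matrix is
#'   treated as counts, otherwise as relative abundances (which are then
#'   validated to close to 1).
#' @return an `abundance_table` object.
#' @export
abundance_table <- function(values, kind = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance table needs taxon (row) and sample (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyNA(values)) stop("abundance table contains missing values")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative abundance at taxon '%s', sample '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
  if (is.null(kind))
    kind <- if (all(values == round(values))) "counts" else "relative"
  kind <- match.arg(kind, c("counts", "relative", "abundance"))
  if (kind == "relative") {
    cs <- colSums(values)
    bad <- colnames(values)[abs(cs - 1) > 1e-9]
    if (length(bad))
      stop("relative table columns do not sum to 1: ",
           paste(bad, collapse = ", "))
  }
  structure(list(values = values, kind = kind), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Abundance table (%s): %d taxa x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Taxon and sample identifiers of an abundance table
#' @param x an `abundance_table`.
#' @return character vector of ids.
#' @export
taxon_ids <- function(x) rownames(x$values)

#' @rdname taxon_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an abundance table by taxa and/or samples
#' @param x an `abundance_table`.
#' @param taxa,samples character or index vectors (default: keep all).
#' @return an `abundance_table`. Subsetting a relative table re-validates
#'   closure only when all taxa are kept; otherwise the result is returned
#'   as-is with kind `"relative"` dropped to `"counts"`-agnostic raw values
#'   is avoided by re-closing via [to_relative()] when `reclose = TRUE`.
#' @param reclose re-normalize columns after a taxon subset (default FALSE).
#' @export
subset_table <- function(x, taxa = NULL, samples = NULL, reclose = FALSE) {
  v <- x$values
  if (!is.null(taxa)) v <- v[taxa, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  kind <- x$kind
  if (!is.null(taxa) && kind == "relative" && !reclose) {
    # partial compositions no longer close to 1; keep values, mark counts-free
    out <- structure(list(values = v, kind = "relative"),
                     class = "abundance_table")
    return(out)
  }
  out <- structure(list(values = v, kind = kind), class = "abundance_table")
  if (reclose) out <- to_relative(out, force = TRUE)
  out
}

read_id_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2) stop("expected '#ID' column plus at least one sample: ",
                         path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, TRUE))[1]
    stop(sprintf("non-numeric entries in column '%s' of %s",
                 names(df)[-1][bad], path))
  }
  rownames(m) <- ids
  m
}

#' Read / write abundance tables
#'
#' Tables are TSV, UTF-8, first header cell `#ID`, first column the feature
#' ids, remaining columns one per sample.
#'
#' @param path file path.
#' @param kind forced kind, or `NULL` to infer (integer-valued => counts).
#' @return [read_abundance_table()]: an `abundance_table`.
#' @export
read_abundance_table <- function(path, kind = NULL) {
  abundance_table(read_id_matrix(path), kind = kind)
}

#' @rdname read_abundance_table
#' @param x an `abundance_table` to write.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "abundance_table"))
  df <- data.frame("#ID" = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a KO abundance table
#'
#' Same format as [read_abundance_table()]; returned object is an
#' `abundance_table` whose rows are KO identifiers. Unlike genus tables,
#' non-integer KO profiles are normalized depths rather than closed
#' compositions, so inference maps them to kind `"abundance"` (not
#' `"relative"`).
#' @inheritParams read_abundance_table
#' @export
read_ko_table <- function(path, kind = NULL) {
  m <- read_id_matrix(path)
  if (is.null(kind))
    kind <- if (all(m == round(m))) "counts" else "abundance"
  abundance_table(m, kind = kind)
}

#' Read / write sample metadata
#'
#' Metadata is TSV with columns `sample_id`, `subject_id`, `group`,
#' `age_days` (integer days, >= 0).
#'
#' @param path file path.
#' @return a `data.frame` with the four columns above.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  req <- c("sample_id", "subject_id", "group", "age_days")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("metadata lacks required columns: ", paste(missing, collapse = ", "))
  df <- df[req]
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$age_days <- as.integer(df$age_days)
  if (anyNA(df$age_days) || any(df$age_days < 0))
    stop("age_days must be non-negative integers")
  df
}

#' @rdname read_sample_metadata
#' @param metadata data.frame to write.
#' @export
write_sample_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that metadata covers a table's samples
#'
#' @param table an `abundance_table`.
#' @param metadata a metadata data.frame.
#' @return invisibly `TRUE`; errors if any table sample lacks metadata.
#' @export
validate_pairing <- function(table, metadata) {
  missing <- setdiff(sample_ids(table), metadata$sample_id)
  if (length(missing))
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Read a pathway -> KO membership map
#'
#' TSV with columns `pathway_id` and `ko_id`, one pair per row. Duplicate
#' pairs are de-duplicated; an empty member set is an error.
#'
#' @param path file path.
#' @return named list of character vectors (class `pathway_map`), one
#'   element per pathway.
#' @export
read_pathway_map <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!all(c("pathway_id", "ko_id") %in% names(df)))
    stop("pathway map needs columns 'pathway_id' and 'ko_id'")
  df$pathway_id <- as.character(df$pathway_id)
  df$ko_id <- as.character(df$ko_id)
  if (any(!nzchar(df$ko_id)) || anyNA(df$ko_id))
    stop("pathway map contains empty KO ids")
  pm <- lapply(split(df$ko_id, df$pathway_id), function(k) sort(unique(k)))
  empty <- names(pm)[lengths(pm) == 0]
  if (length(empty))
    stop("pathways with no member KOs: ", paste(empty, collapse = ", "))
  structure(pm, class = "pathway_map")
}

#' @rdname read_pathway_map
#' @param map a `pathway_map` (or named list of KO id vectors) to write.
#' @export
write_pathway_map <- function(map, path) {
  df <- data.frame(
    pathway_id = rep(names(map), lengths(map)),
    ko_id = unlist(map, use.names = FALSE), stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides every sample column by its sum. Already-relative tables are
#' returned unchanged (idempotent).
#'
#' @param table an `abundance_table`.
#' @param force re-normalize even if `kind == "relative"` (used after taxon
#'   subsets).
#' @return an `abundance_table` with `kind = "relative"`.
#' @export
to_relative <- function(table, force = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$kind == "relative" && !force) return(table)
  cs <- colSums(table$values)
  zero <- colnames(table$values)[cs == 0]
  if (length(zero))
    stop("all-zero sample(s) cannot be normalized: ",
         paste(zero, collapse = ", "))
  structure(list(values = sweep(table$values, 2, cs, "/"),
                 kind = "relative"),
            class = "abundance_table")
}

#' Rarefy a count table to fixed depth
#'
#' Subsamples every sample's counts without replacement (multivariate
#' hypergeometric) to exactly `depth` reads, the standard normalization for
#' uneven sequencing effort. Samples below the target depth are an error by
#' default; `drop_shallow = TRUE` removes them instead (with a message).
#'
#' @param table an `abundance_table` of counts.
#' @param depth target reads per sample (default 2490).
#' @param seed optional integer seed.
#' @param drop_shallow drop samples with total < depth instead of erroring.
#' @return an `abundance_table` of counts; every column sums to `depth`.
#' @export
rarefy <- function(table, depth = 2490, seed = NULL, drop_shallow = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$kind != "counts") stop("rarefaction requires a count table")
  depth <- as.integer(depth)
  if (depth < 1) stop("depth must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  totals <- colSums(table$values)
  shallow <- colnames(table$values)[totals < depth]
  if (length(shallow)) {
    if (!drop_shallow)
      stop("samples below rarefaction depth ", depth, ": ",
           paste(shallow, collapse = ", "))
    message("dropping ", length(shallow), " shallow sample(s): ",
            paste(shallow, collapse = ", "))
  }
  keep <- setdiff(colnames(table$values), shallow)
  if (length(keep) == 0)
    stop("no samples reach rarefaction depth ", depth)
  v <- table$values[, keep, drop = FALSE]
  out <- v
  for (j in seq_len(ncol(v))) {
    cnt <- v[, j]
    tot <- sum(cnt)
    if (tot == depth) { out[, j] <- cnt; next }
    # draw `depth` reads without replacement from the expanded read pool
    picked <- sample.int(tot, depth)
    breaks <- c(0, cumsum(cnt))
    out[, j] <- tabulate(findInterval(picked, breaks, left.open = TRUE),
                         nbins = nrow(v))
  }
  abundance_table(out, kind = "counts")
}
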