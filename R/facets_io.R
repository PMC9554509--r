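#' Canonical FACETS cncf column names
#'
#' The 14 columns of a FACETS `*_cncf` segment table, in canonical (dotted)
#' order. Dotted and underscored spellings are accepted on input,
#' case-insensitively.
#'
#' @return Character vector of 14 column names.
#' @export
cncf_columns <- function() {
  c("chrom", "seg", "num.mark", "nhet", "cnlr.median", "segclust",
    "cnlr.median.clust", "start", "end", "mafR", "mafR.clust",
    "cf.em", "tcn.em", "lcn.em")
}

# internal (underscored) field names, parallel to cncf_columns()
.cncf_fields <- function() gsub(".", "_", cncf_columns(), fixed = TRUE)

# normalize a header name for dialect-insensitive matching
.canon_key <- function(x) tolower(gsub("[._]", "_", x))

#' Default LOH feature set
#'
#' The nine segment-level features used by default to describe an LOH
#' instance: heterozygous-SNP count, median copy-number log-ratio, the
#' mafR log-odds summary (segment and cluster level), genomic start/end,
#' and the EM estimates of cell fraction, total and lesser copy number.
#'
#' @return Character vector of 9 feature names (underscored spelling).
#' @export
miln_features <- function() {
  c("nhet", "cnlr_median", "mafR", "mafR_clust", "start", "end",
    "cf_em", "tcn_em", "lcn_em")
}

#' Read a FACETS cncf segment table
#'
#' Reads a tab-separated FACETS `*_cncf` file into a segment data frame with
#' underscored column names. Chromosomes "X" and "Y" are encoded as 23 and 24;
#' a leading "chr" prefix is dropped. Empty cells and "NA" become `NA`.
#'
#' @param path Path to a TSV file with a header row naming at least the 14
#'   canonical columns (any order; dotted or underscored; case-insensitive).
#' @param sample_id Optional sample identifier stored as an attribute.
#' @return A `data.frame` of class `cncf_segments`, one row per segment, with
#'   columns `chrom, seg, num_mark, nhet, cnlr_median, segclust,
#'   cnlr_median_clust, start, end, mafR, mafR_clust, cf_em, tcn_em, lcn_em`.
#' @export
read_cncf <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""), strip.white = TRUE)
  keys <- .canon_key(names(raw))
  fields <- .cncf_fields()
  fkeys <- .canon_key(fields)
  idx <- match(fkeys, keys)
  if (anyNA(idx)) {
    missing <- cncf_columns()[is.na(idx)]
    stop("cncf format error: missing column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- raw[, idx, drop = FALSE]
  names(out) <- fields
  # chromosome codes: X -> 23, Y -> 24, strip "chr"
  chr <- sub("^chr", "", out$chrom, ignore.case = TRUE)
  chr[toupper(chr) == "X"] <- "23"
  chr[toupper(chr) == "Y"] <- "24"
  out$chrom <- chr
  for (f in fields) {
    v <- out[[f]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      stop("cncf parse error: non-numeric value ", dQuote(v[bad[1]]),
           " in column '", f, "', row ", bad[1])
    }
    out[[f]] <- num
  }
  bad <- which(!is.na(out$start) & !is.na(out$end) & out$start > out$end)
  if (length(bad)) {
    warning("segment(s) with start > end at row(s): ",
            paste(utils::head(bad, 5), collapse = ", "))
  }
  attr(out, "sample_id") <- sample_id
  class(out) <- c("cncf_segments", "data.frame")
  out
}

#' Write a FACETS-dialect cncf segment table
#'
#' Inverse of [read_cncf()]: writes a tab-separated table with the canonical
#' dotted headers. Missing values are written as "NA".
#'
#' @param segments A `cncf_segments` data frame (or any data frame with the
#'   14 underscored columns).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cncf <- function(segments, path) {
  fields <- .cncf_fields()
  if (!all(fields %in% names(segments))) {
    stop("segments must contain the 14 cncf columns")
  }
  out <- as.data.frame(segments)[, fields, drop = FALSE]
  names(out) <- cncf_columns()
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Extract per-segment feature vectors
#'
#' Projects segment records onto an ordered feature list. Segments with a
#' missing value in a requested feature are imputed with 0 and flagged; the
#' `imputed` attribute records which cells were filled and `n_imputed` the
#' total count.
#'
#' @param segments A `cncf_segments` data frame from [read_cncf()].
#' @param feature_names Ordered character vector of feature (column) names;
#'   defaults to the nine-feature set of [miln_features()].
#' @return Numeric matrix, one row per segment, columns in the requested
#'   order, with attributes `imputed` (logical matrix) and `n_imputed`.
#' @export
extract_features <- function(segments, feature_names = miln_features()) {
  unknown <- setdiff(feature_names, names(segments))
  if (length(unknown)) {
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  }
  x <- as.matrix(as.data.frame(segments)[, feature_names, drop = FALSE])
  storage.mode(x) <- "double"
  imp <- is.na(x)
  x[imp] <- 0
  attr(x, "imputed") <- imp
  attr(x, "n_imputed") <- sum(imp)
  x
}

#' Fit per-feature min-max normalization bounds
#'
#' @param x Numeric matrix of feature vectors (rows = instances), or a list
#'   of such matrices which are stacked first.
#' @return An object of class `miln_bounds` with named `min` and `max`
#'   vectors.
#' @export
fit_minmax <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("cannot fit bounds on an empty feature set")
  b <- list(min = apply(x, 2, min), max = apply(x, 2, max))
  stopifnot(all(b$min <= b$max))
  class(b) <- "miln_bounds"
  b
}

#' Apply min-max normalization
#'
#' Maps each value to `(x - min) / (max - min)`. Values outside the fitted
#' bounds are clipped to `[0, 1]`; features constant at fit time map to 0.
#'
#' @param x Numeric matrix of feature vectors (rows = instances).
#' @param bounds A `miln_bounds` object from [fit_minmax()].
#' @return Matrix of the same shape with all values in `[0, 1]`.
#' @export
apply_minmax <- function(x, bounds) {
  x <- as.matrix(x)
  if (ncol(x) != length(bounds$min)) {
    stop("feature dimension mismatch: data has ", ncol(x),
         " columns, bounds have ", length(bounds$min))
  }
  rng <- bounds$max - bounds$min
  out <- sweep(x, 2, bounds$min, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  dimnames(out) <- dimnames(x)
  out
}

#' Construct a bag of LOH instances
#'
#' A bag is one tumor sample: its identifier, an optional HRD label in
#' `{+1, -1}` (only bags are labeled, never individual segments), and a
#' matrix of instance feature vectors, one row per LOH segment.
#'
#' @param sample_id Sample identifier.
#' @param instances Numeric matrix with >= 1 row.
#' @param label `+1`, `-1`, or `NULL` (unlabeled).
#' @return A `miln_bag` object.
#' @export
miln_bag <- function(sample_id, instances, label = NULL) {
  instances <- as.matrix(instances)
  storage.mode(instances) <- "double"
  if (nrow(instances) < 1L) {
    stop("bag '", sample_id, "' must contain at least one instance")
  }
  if (anyNA(instances)) stop("bag '", sample_id, "' has missing values")
  if (!is.null(label)) {
    if (!(length(label) == 1L && label %in% c(-1, 1))) {
      stop("label must be +1 or -1")
    }
    label <- as.integer(label)
  }
  structure(list(sample_id = as.character(sample_id),
                 label = label, instances = instances),
            class = "miln_bag")
}

#' @export
print.miln_bag <- function(x, ...) {
  cat(sprintf("<miln_bag> %s: %d instances x %d features, label %s\n",
              x$sample_id, nrow(x$instances), ncol(x$instances),
              if (is.null(x$label)) "<none>" else sprintf("%+d", x$label)))
  invisible(x)
}

.coerce_label <- function(v) {
  if (is.character(v)) {
    v <- tolower(v)
    v[v %in% c("pos", "positive", "+1", "1")] <- "1"
    v[v %in% c("neg", "negative", "-1")] <- "-1"
    v <- as.numeric(v)
  }
  if (any(!v %in% c(-1, 1))) stop("labels must be in {1, -1} (or pos/neg)")
  as.integer(v)
}

#' Assemble bags from per-sample feature matrices
#'
#' @param per_sample_vectors Named list mapping sample id to a feature matrix
#'   (one row per LOH segment).
#' @param labels Optional named vector of labels in `{1, -1}` (also accepts
#'   `"pos"`/`"neg"`); every named sample must be present.
#' @return List of [miln_bag()] objects, one per sample, in input order.
#' @export
assemble_bags <- function(per_sample_vectors, labels = NULL) {
  ids <- names(per_sample_vectors)
  if (is.null(ids)) stop("per_sample_vectors must be a named list")
  if (!is.null(labels)) {
    missing <- setdiff(names(labels), ids)
    if (length(missing)) {
      stop("labeled sample(s) missing from data: ",
           paste(missing, collapse = ", "))
    }
    labels <- stats::setNames(.coerce_label(labels), names(labels))
  }
  lapply(ids, function(id) {
    x <- per_sample_vectors[[id]]
    if (is.null(dim(x))) {
      if (length(x) == 0L) stop("sample '", id, "' has zero segments")
      x <- matrix(x, nrow = 1L)  # bare vector = one instance
    }
    if (nrow(x) == 0L) stop("sample '", id, "' has zero segments")
    lab <- if (!is.null(labels) && id %in% names(labels)) labels[[id]]
    miln_bag(id, x, lab)
  })
}

#' Read a sample label file
#'
#' Two-column TSV `sample_id<TAB>label`, label in `{1, -1}` or
#' `pos`/`neg`. A header row is detected and skipped if its second field is
#' not a recognized label.
#'
#' @param path Path to the labels TSV.
#' @return Named integer vector of `+1`/`-1` labels.
#' @export
read_labels <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = FALSE,
                         colClasses = "character", strip.white = TRUE)
  if (ncol(d) < 2L) stop("labels file must have two tab-separated columns")
  ok1 <- tolower(d[1, 2]) %in% c("1", "-1", "+1", "pos", "neg",
                                 "positive", "negative")
  if (!ok1) d <- d[-1, , drop = FALSE]
  stats::setNames(.coerce_label(d[[2]]), d[[1]])
}

#' Write a sample label file
#'
#' @param labels Named vector of `+1`/`-1` labels.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(sample_id = names(labels),
                                label = as.integer(labels)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# stack instances of all bags; returns matrix plus bag index
.stack_bags <- function(bags) {
  X <- do.call(rbind, lapply(bags, `[[`, "instances"))
  list(X = X, bag = rep.int(seq_along(bags),
                            vapply(bags, function(b) nrow(b$instances), 1L)))
}

.bag_labels <- function(bags) {
  vapply(bags, function(b) {
    if (is.null(b$label)) stop("bag '", b$sample_id, "' is unlabeled")
    b$label
  }, 1L)
}

# normalize every bag's instances with the given bounds
.normalize_bags <- function(bags, bounds) {
  lapply(bags, function(b) {
    b$instances <- apply_minmax(b$instances, bounds)
    b
  })
}
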