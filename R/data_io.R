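#' Construct an expression dataset
#'
#' Bundles a normalized expression matrix (genes in rows, samples in columns)
#' with an optional two-level condition annotation. This is the central input
#' container of the package: differential co-expression is always computed
#' between the two condition groups of an `ExpressionDataset`.
#'
#' @param values Numeric matrix, genes x samples, with unique non-empty
#'   rownames (gene ids) and colnames (sample ids). All entries must be finite:
#'   the method defines no imputation, so missing values are rejected.
#' @param conditions Optional named character vector (or factor) mapping every
#'   sample id to exactly one of two condition labels.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values` (the matrix) and `conditions` (named factor with two levels, or
#'   `NULL` when not yet annotated).
#'
#' @details Fewer than 10 samples in either condition triggers a warning:
#'   around 10 samples per condition is the recommended minimum for stable
#'   association estimates; fewer than 2 per condition is an error.
#'
#' @examples
#' m <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- expression_dataset(m, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
#' ds
#' @export
expression_dataset <- function(values, conditions = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid) || any(!nzchar(gid)) || any(!nzchar(sid)))
    stop("`values` must have non-empty rownames (genes) and colnames (samples)")
  dup_g <- unique(gid[duplicated(gid)])
  if (length(dup_g))
    stop("duplicate gene identifiers: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(sid[duplicated(sid)])
  if (length(dup_s))
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite expression value at gene '", gid[bad[1]], "', sample '",
         sid[bad[2]], "'; missing values are not supported")
  }
  ds <- structure(list(values = values, conditions = NULL),
                  class = "ExpressionDataset")
  if (!is.null(conditions)) ds <- set_conditions(ds, conditions)
  ds
}

#' Attach a two-level condition annotation to a dataset
#'
#' @param dataset An `ExpressionDataset`.
#' @param conditions Named character vector or factor, one entry per sample of
#'   `dataset`, with exactly two distinct labels and at least two samples per
#'   label.
#' @return The dataset with `conditions` populated (named factor, two levels).
#' @export
set_conditions <- function(dataset, conditions) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  sid <- colnames(dataset$values)
  cn <- as.character(conditions)
  names(cn) <- names(conditions)
  if (is.null(names(cn))) stop("`conditions` must be named by sample id")
  missing_ds <- setdiff(names(cn), sid)
  if (length(missing_ds))
    stop("condition table contains unknown samples: ",
         paste(missing_ds, collapse = ", "))
  missing_cond <- setdiff(sid, names(cn))
  if (length(missing_cond))
    stop("samples without condition assignment: ",
         paste(missing_cond, collapse = ", "))
  cn <- cn[sid]
  lv <- sort(unique(cn))
  if (length(lv) != 2)
    stop("expected exactly two conditions, found ", length(lv), ": ",
         paste(lv, collapse = ", "))
  tab <- table(cn)
  if (any(tab < 2))
    stop("each condition needs at least 2 samples (got ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")")
  if (any(tab < 10))
    warning("fewer than 10 samples in condition(s) ",
            paste(names(tab)[tab < 10], collapse = ", "),
            "; around 10 samples per condition are recommended")
  dataset$conditions <- factor(cn, levels = lv)
  names(dataset$conditions) <- sid
  dataset
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  if (is.null(x$conditions)) {
    cat("  conditions: <none>\n")
  } else {
    tab <- table(x$conditions)
    cat("  conditions:", paste(sprintf("%s (n=%d)", names(tab), tab),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

.detect_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (grepl("\t", hdr)) "\t" else ","
}

#' Read an expression matrix from delimited text
#'
#' Reads a TSV/CSV table with one header row and one identifier column, and
#' stores it genes x samples regardless of on-disk orientation. The delimiter
#' (tab or comma) is auto-detected from the header line.
#'
#' @param path Path to the file.
#' @param orientation `"genes_in_rows"` (default; first column = gene ids,
#'   header = sample ids) or `"samples_in_rows"` (transposed layout).
#' @return An `ExpressionDataset` without condition annotation.
#' @seealso [read_conditions()] to attach the condition table.
#' @export
read_expression <- function(path, orientation = c("genes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2) stop("expected an identifier column plus at least one data column")
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate identifiers in '", path, "': ", paste(dup, collapse = ", "))
  raw <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric or missing value in '", path, "' at row '", ids[bad[1]],
         "', column '", colnames(raw)[bad[2]], "'")
  }
  dimnames(num) <- list(ids, colnames(raw))
  if (orientation == "samples_in_rows") num <- t(num)
  expression_dataset(num)
}

#' Read a sample-to-condition table and attach it to a dataset
#'
#' Expects a two-column delimited table (columns `sample`, `condition`; extra
#' columns are ignored). Every dataset sample must be assigned to exactly one
#' of two condition labels.
#'
#' @param path Path to the table.
#' @param dataset An `ExpressionDataset` (typically from [read_expression()]).
#' @return The dataset with conditions populated.
#' @export
read_conditions <- function(path, dataset) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2) stop("condition table needs columns `sample` and `condition`")
  smp <- if ("sample" %in% names(df)) df[["sample"]] else df[[1]]
  cnd <- if ("condition" %in% names(df)) df[["condition"]] else df[[2]]
  set_conditions(dataset, stats::setNames(cnd, smp))
}

.canonical_pairs <- function(src, tgt) {
  a <- pmin(src, tgt)
  b <- pmax(src, tgt)
  data.frame(source = a, target = b, stringsAsFactors = FALSE)
}

.edge_key <- function(edges, directed) {
  if (!directed) edges <- .canonical_pairs(edges$source, edges$target)
  paste(edges$source, edges$target, sep = "\r")
}

#' Build the candidate edge set to be tested
#'
#' In mode 1 (no prior network) every unordered gene pair is a candidate and
#' the result is undirected; pairs are stored in canonical lexicographic
#' (min, max) order so output is reproducible. In mode 2 a regulator-target
#' edge list restricts testing to those directed pairs (pathway-level
#' analysis).
#'
#' @param dataset An `ExpressionDataset`.
#' @param grn Optional data frame with regulator/target columns (first two
#'   columns are used). When supplied, mode 2 is selected.
#' @return A `CandidateEdgeSet`: data frame with columns `source`, `target`
#'   and attributes `mode` (1 or 2) and `directed`.
#' @export
candidate_edges <- function(dataset, grn = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  genes <- rownames(dataset$values)
  if (is.null(grn)) {
    if (length(genes) < 2) stop("need at least two genes for mode 1")
    cmb <- utils::combn(sort(genes), 2)
    edges <- data.frame(source = cmb[1, ], target = cmb[2, ],
                        stringsAsFactors = FALSE)
    return(structure(edges, mode = 1L, directed = FALSE,
                     class = c("CandidateEdgeSet", "data.frame")))
  }
  if (ncol(grn) < 2) stop("GRN edge list needs two columns (regulator, target)")
  src <- as.character(grn[[1]])
  tgt <- as.character(grn[[2]])
  n_in <- length(src)
  keep <- src %in% genes & tgt %in% genes & src != tgt
  src <- src[keep]; tgt <- tgt[keep]
  key <- paste(src, tgt, sep = "\r")
  first <- !duplicated(key)
  edges <- data.frame(source = src[first], target = tgt[first],
                      stringsAsFactors = FALSE)
  n_drop <- n_in - nrow(edges)
  if (nrow(edges) == 0)
    stop("no GRN edges remain after filtering to dataset genes")
  if (n_drop > 0)
    message(sprintf("candidate edges: kept %d of %d GRN edges (%d dropped: unknown genes, self-loops or duplicates)",
                    nrow(edges), n_in, n_drop))
  structure(edges, mode = 2L, directed = TRUE,
            class = c("CandidateEdgeSet", "data.frame"))
}

#' Read a regulator-target edge list and restrict it to a dataset
#'
#' Reads a two-column TF/TG table (TRRUST-like layout; extra columns are
#' ignored), drops self-loops, duplicates and edges with genes absent from the
#' dataset, and returns the surviving directed candidate edges (mode 2).
#'
#' @param path Path to the edge list.
#' @param dataset An `ExpressionDataset`.
#' @return A `CandidateEdgeSet` (mode 2, directed).
#' @export
read_grn <- function(path, dataset) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  candidate_edges(dataset, grn = df)
}

#' Write a differential network to delimited text
#'
#' One row per tested edge in input edge order, tab-separated, with columns
#' `source`, `target`, `r_a`, `r_b`, `r_ab`, `delta_r`, `s`, `p_delta_r`,
#' `p_s`, `padj_delta_r`, `padj_s`, `sig_delta_r`, `sig_s`, `degenerate`.
#' Numeric columns are printed at full double precision so the file
#' round-trips exactly.
#'
#' @param network A `dcnet_result` (from [run_dcnet()]) or its `edges` data
#'   frame.
#' @param path Output path.
#' @param significant_only If `TRUE`, write only the edges passing the
#'   network's significance rule (a header-only file when none do).
#' @return Invisibly, the data frame written.
#' @export
write_network <- function(network, path, significant_only = FALSE) {
  edges <- if (inherits(network, "dcnet_result")) network$edges else network
  if (significant_only) {
    rule <- if (inherits(network, "dcnet_result")) network$rule else "either"
    edges <- edges[.apply_rule(edges, rule), , drop = FALSE]
  }
  out <- edges
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edges)
}

#' Read back a differential network table
#'
#' @param path Path to a file produced by [write_network()].
#' @return Data frame with the same columns and types.
#' @export
read_network <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (cl in c("sig_delta_r", "sig_s", "degenerate"))
    if (cl %in% names(df)) df[[cl]] <- as.logical(df[[cl]])
  df
}
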