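# Pairwise metafeature expansion: every unordered feature pair combined under
# ratio, sum, difference and product operators, with canonical a-before-b
# orientation taken from the matrix's feature order.

.metafeature_ops <- c(ratio = "/", sum = "+", diff = "-", prod = "*")

#' Number of pairwise metafeatures
#'
#' For `n` features and a set of operators, each unordered pair contributes
#' one metafeature per operator: `|ops| * n * (n - 1) / 2`.
#'
#' @param n_features Number of base features (at least 2).
#' @param ops Character vector drawn from `c("ratio", "sum", "diff", "prod")`.
#' @return The metafeature count as a double (counts exceed integer range for
#'   large signatures).
#' @examples
#' count_metafeatures(1372, c("ratio", "sum", "diff", "prod")) # 3762024
#' @export
count_metafeatures <- function(n_features, ops = names(.metafeature_ops)) {
  ops <- match.arg(ops, names(.metafeature_ops), several.ok = TRUE)
  if (length(ops) == 0L) stop("ops must be nonempty")
  if (n_features < 2L) stop("need at least 2 features")
  length(unique(ops)) * n_features * (n_features - 1) / 2
}

#' Combine two expression vectors under one operator
#'
#' @param x_a,x_b Numeric vectors of equal length; `x_a` is the canonical
#'   first operand.
#' @param op One of "ratio", "sum", "diff", "prod".
#' @return Elementwise `x_a / x_b`, `x_a + x_b`, `x_a - x_b` or `x_a * x_b`.
#' @export
compute_metafeature <- function(x_a, x_b, op) {
  op <- match.arg(op, names(.metafeature_ops))
  if (length(x_a) != length(x_b)) stop("operand length mismatch")
  if (op == "ratio" && any(x_b == 0)) {
    i <- which(x_b == 0)[1L]
    nm <- if (!is.null(names(x_b))) names(x_b)[i] else as.character(i)
    stop("zero denominator in ratio at sample ", nm)
  }
  switch(op,
         ratio = x_a / x_b,
         sum = x_a + x_b,
         diff = x_a - x_b,
         prod = x_a * x_b)
}

#' Serialized metafeature identifiers for one operator
#'
#' @param feature_ids Base feature ids in matrix order.
#' @param op Operator name.
#' @param pairs Optional 2-row index matrix of (a, b) pairs; defaults to all
#'   pairs with a before b.
#' @return Character vector like `"A/B"`, `"A+B"`, `"A-B"`, `"A*B"`.
#' @export
metafeature_ids <- function(feature_ids, op, pairs = utils::combn(length(feature_ids), 2L)) {
  op <- match.arg(op, names(.metafeature_ops))
  paste0(feature_ids[pairs[1L, ]], .metafeature_ops[[op]], feature_ids[pairs[2L, ]])
}

#' Generate all pairwise metafeatures of an expression matrix
#'
#' Rows are emitted operator-major (in the order the operators are given),
#' then in pair order (a before b in matrix feature order), so two runs yield
#' identical matrices. Generation proceeds in blocks of at most `block_size`
#' metafeature rows; supply `callback` to stream blocks instead of
#' materializing the full matrix.
#'
#' @param X Expression matrix (features x samples); strictly positive when
#'   "ratio" is among the operators.
#' @param ops Operators to apply.
#' @param block_size Maximum rows per generated block.
#' @param callback Optional `function(block_matrix)` invoked once per block in
#'   order. When given, the function returns the total row count invisibly and
#'   builds no full matrix.
#' @return The metafeature matrix (or, with a callback, the row count).
#' @export
generate_metafeatures <- function(X, ops = names(.metafeature_ops),
                                  block_size = 100000L, callback = NULL) {
  ops <- match.arg(ops, names(.metafeature_ops), several.ok = TRUE)
  validate_expression(X, require_positive = "ratio" %in% ops)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 features")
  if (block_size < 1L) stop("block_size must be positive")
  pairs <- utils::combn(n, 2L)
  n_pairs <- ncol(pairs)
  streaming <- !is.null(callback)
  out <- if (!streaming) vector("list", length(ops) * ceiling(n_pairs / block_size))
  chunk_i <- 0L
  total <- 0
  for (op in ops) {
    start <- 1L
    while (start <= n_pairs) {
      end <- min(start + block_size - 1L, n_pairs)
      idx <- pairs[, start:end, drop = FALSE]
      a <- X[idx[1L, ], , drop = FALSE]
      b <- X[idx[2L, ], , drop = FALSE]
      block <- switch(op, ratio = a / b, sum = a + b, diff = a - b, prod = a * b)
      rownames(block) <- metafeature_ids(rownames(X), op, idx)
      total <- total + nrow(block)
      if (streaming) {
        callback(block)
      } else {
        chunk_i <- chunk_i + 1L
        out[[chunk_i]] <- block
      }
      start <- end + 1L
    }
  }
  if (streaming) return(invisible(total))
  res <- do.call(rbind, out[seq_len(chunk_i)])
  colnames(res) <- colnames(X)
  res
}

#' Stack original features, metafeatures and progression-marker rows
#'
#' Produces the analysis matrix that the clustering sees: original features,
#' then metafeatures, then one row per progression marker named
#' `"MARKER:<name>"`, so markers participate in the graph as ordinary nodes.
#'
#' @param X Original expression matrix.
#' @param meta Metafeature matrix over the same samples (may have 0 rows).
#' @param markers A data.frame or named list of per-sample marker vectors, or
#'   a matrix with marker rows; sample ids must match `X`'s columns.
#' @return A single features x samples matrix.
#' @export
assemble_analysis_matrix <- function(X, meta = NULL, markers = NULL) {
  validate_expression(X)
  parts <- list(X)
  if (!is.null(meta) && nrow(meta) > 0L) {
    if (!identical(colnames(meta), colnames(X))) stop("sample ids of metafeatures do not match")
    parts <- c(parts, list(meta))
  }
  if (!is.null(markers)) {
    if (is.data.frame(markers) || (is.list(markers) && !is.matrix(markers))) {
      mm <- do.call(rbind, lapply(markers, as.numeric))
      rownames(mm) <- names(markers)
      colnames(mm) <- if (is.data.frame(markers)) rownames(markers)
                      else names(markers[[1L]]) %||% colnames(X)[seq_len(ncol(mm))]
      markers <- mm
    }
    if (!all(colnames(X) %in% colnames(markers))) {
      stop("marker table is missing sample(s): ",
           paste(setdiff(colnames(X), colnames(markers)), collapse = ", "))
    }
    markers <- markers[, colnames(X), drop = FALSE]
    if (anyNA(markers)) stop("marker table contains missing values")
    rownames(markers) <- paste0("MARKER:", rownames(markers))
    parts <- c(parts, list(markers))
  }
  res <- do.call(rbind, parts)
  if (anyDuplicated(rownames(res))) stop("duplicate feature ids after assembly")
  res
}

#' Decompose a (meta)feature identifier into its constituent probe ids
#'
#' Metafeature ids carry exactly one operator glyph (`/`, `+`, `-`, `*`)
#' between the two probe ids; plain feature ids carry none. The decomposition
#' is operator-blind: `"A-B"` and `"A+B"` map to the same probe set.
#'
#' @param id A feature or metafeature identifier.
#' @return Character vector of 1 or 2 probe ids.
#' @export
constituent_probes <- function(id) {
  stopifnot(length(id) == 1L, is.character(id))
  hits <- gregexpr("[/*+-]", id)[[1L]]
  if (identical(as.integer(hits[1L]), -1L)) return(id)
  if (length(hits) != 1L) stop("malformed metafeature id: ", id)
  parts <- c(substr(id, 1L, hits - 1L), substr(id, hits + 1L, nchar(id)))
  if (any(!nzchar(parts))) stop("malformed metafeature id: ", id)
  parts
}
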