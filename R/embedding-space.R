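#' Embedding spaces
#'
#' An `embedding_space` holds one modality's vector representations: a
#' numeric matrix with one row per item, row names giving the item ids, and
#' a modality label (`"vision"` or `"language"` in the standard workflow).
#' All similarity computation in the package runs over these objects.
#'
#' Vectors are stored as given; cosine similarity supplies the
#' normalisation, so no re-scaling is applied at construction. Zero-norm
#' vectors are admitted to the container (a catalog may carry items that are
#' later filtered out) but rejected at similarity time.
#'
#' @param vectors numeric matrix, one row per item, `d >= 1` columns.
#' @param item_ids character vector of unique item identifiers, one per row.
#'   Defaults to the matrix row names.
#' @param modality label for the modality the vectors represent.
#'
#' @return An object of class `embedding_space`: the vector matrix with item
#'   ids as row names and a `modality` attribute.
#' @examples
#' sp <- embedding_space(rbind(a = c(1, 0), b = c(0, 1)), modality = "vision")
#' cosine(sp["a", ], sp["b", ])
#' @export
embedding_space <- function(vectors, item_ids = rownames(vectors),
                            modality = "vision") {
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (nrow(vectors) < 1L || ncol(vectors) < 1L) {
    stop_drm("drm_precondition_error",
             "an embedding space needs at least one item and one dimension")
  }
  if (is.null(item_ids)) {
    stop_drm("drm_precondition_error", "item_ids are required (or set rownames)")
  }
  item_ids <- as.character(item_ids)
  if (length(item_ids) != nrow(vectors)) {
    stop_drm("drm_precondition_error",
             "got %d item ids for %d vector rows", length(item_ids), nrow(vectors))
  }
  if (anyDuplicated(item_ids)) {
    stop_drm("drm_input_error", "duplicate item id: '%s'",
             item_ids[duplicated(item_ids)][1L])
  }
  if (!all(is.finite(vectors))) {
    stop_drm("drm_input_error", "non-finite value in vectors for item '%s'",
             item_ids[which(!apply(is.finite(vectors), 1L, all))[1L]])
  }
  rownames(vectors) <- item_ids
  structure(vectors, modality = modality, class = c("embedding_space", "matrix", "array"))
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("<embedding_space '%s': %d items x %d dims>\n",
              attr(x, "modality"), nrow(x), ncol(x)))
  invisible(x)
}

#' @rdname embedding_space
#' @param x object to test.
#' @export
is_embedding_space <- function(x) inherits(x, "embedding_space")

space_vector <- function(space, id) {
  if (!id %in% rownames(space)) {
    stop_drm("drm_lookup_error", "item '%s' not found in %s space",
             id, attr(space, "modality") %||% "the")
  }
  space[id, , drop = TRUE]
}

#' Read and write word2vec-style text vector tables
#'
#' The `.vec` dialect: line 1 is `"N D"`; each of the next `N` lines is an
#' item id followed by `D` numbers, single-space delimited, UTF-8, `.` as
#' decimal separator. Values are written with 8 significant digits, which
#' round-trips losslessly at every tolerance used in the package.
#'
#' @param path path of the file to read or write.
#' @param modality modality label attached to the returned space.
#' @return `read_vec_table()` returns an [embedding_space()];
#'   `write_vec_table()` invisibly returns `path`.
#' @examples
#' sp <- embedding_space(rbind(a = c(1, 2), b = c(3, 4)))
#' f <- tempfile(fileext = ".vec")
#' write_vec_table(sp, f)
#' read_vec_table(f)
#' @export
read_vec_table <- function(path, modality = "vision") {
  if (!file.exists(path)) {
    stop_drm("drm_io_error", "vector table not found: %s", path)
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L) stop_drm("drm_input_error", "empty vector table: %s", path)
  header <- strsplit(trimws(lines[1L]), " ", fixed = TRUE)[[1L]]
  n <- suppressWarnings(as.integer(header[1L]))
  d <- suppressWarnings(as.integer(header[2L]))
  if (length(header) != 2L || is.na(n) || is.na(d) || n < 1L || d < 1L) {
    stop_drm("drm_input_error", "malformed header (line 1): '%s'", lines[1L])
  }
  if (length(lines) < n + 1L) {
    stop_drm("drm_input_error", "header promises %d rows but file has %d",
             n, length(lines) - 1L)
  }
  ids <- character(n)
  vectors <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[i + 1L], " ", fixed = TRUE)[[1L]]
    if (length(fields) != d + 1L) {
      stop_drm("drm_input_error",
               "line %d: expected id + %d values, got %d fields",
               i + 1L, d, length(fields))
    }
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(vals)) {
      stop_drm("drm_input_error", "line %d: non-numeric vector value", i + 1L)
    }
    ids[i] <- fields[1L]
    vectors[i, ] <- vals
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop_drm("drm_input_error", "line %d: duplicate item id '%s'",
             which(ids == dup)[2L] + 1L, dup)
  }
  embedding_space(vectors, ids, modality = modality)
}

#' @rdname read_vec_table
#' @param space an [embedding_space()].
#' @export
write_vec_table <- function(space, path) {
  if (!is_embedding_space(space)) {
    stop_drm("drm_precondition_error", "`space` must be an embedding_space")
  }
  if (nrow(space) < 1L) {
    stop_drm("drm_precondition_error", "refusing to write an empty space")
  }
  body <- vapply(seq_len(nrow(space)), function(i) {
    paste(c(rownames(space)[i], formatC(space[i, ], format = "g", digits = 8)),
          collapse = " ")
  }, character(1L))
  out <- c(sprintf("%d %d", nrow(space), ncol(space)), body)
  ok <- tryCatch({
    writeLines(out, path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_drm("drm_io_error", "cannot write vector table to %s", path)
  invisible(path)
}

#' Category prototype as the exemplar centroid
#'
#' A category's prototype vector is the element-wise arithmetic mean of the
#' embedding vectors of its exemplars (e.g. many images of the same
#' category), abstracting shared features away from exemplar idiosyncrasies.
#'
#' @param exemplars numeric matrix of exemplar vectors, one row each
#'   (`n_exemplars x d`, `n_exemplars >= 1`).
#' @return numeric vector of length `d`.
#' @examples
#' build_prototype(rbind(c(0, 0), c(2, 2)))  # c(1, 1)
#' @export
build_prototype <- function(exemplars) {
  exemplars <- as.matrix(exemplars)
  if (nrow(exemplars) < 1L || ncol(exemplars) < 1L) {
    stop_drm("drm_precondition_error", "exemplar set is empty")
  }
  if (!all(is.finite(exemplars))) {
    stop_drm("drm_input_error", "non-finite exemplar value")
  }
  colMeans(exemplars)
}

#' Cosine similarity
#'
#' `u . v / (||u|| ||v||)`: the cosine of the angle between two vectors.
#' Symmetric, and invariant to positive rescaling of either argument.
#'
#' @param u,v numeric vectors of equal length, each with nonzero norm.
#' @return a number in `[-1, 1]`.
#' @examples
#' cosine(c(1, 2, 2), c(2, 1, 2))  # 8/9
#' @export
cosine <- function(u, v) {
  if (length(u) != length(v)) {
    stop_drm("drm_precondition_error",
             "vectors differ in dimension (%d vs %d)", length(u), length(v))
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop_drm("drm_degenerate_error",
             "cosine similarity is undefined for a zero-norm vector")
  }
  s <- sum(u * v) / (nu * nv)
  # clamp floating-point overshoot
  max(-1, min(1, s))
}

#' Similarity of an item to the centroid of a studied set
#'
#' Cosine between a new (unstudied) item's vector and the unweighted mean
#' vector of the studied items, all looked up in one embedding space. This
#' is the per-lure similarity metric that predicts false recognition.
#'
#' @param new_item id of the new item.
#' @param studied character vector of studied item ids (nonempty, not
#'   containing `new_item`).
#' @param space an [embedding_space()] containing all the ids.
#' @return a number in `[-1, 1]`.
#' @export
centroid_similarity <- function(new_item, studied, space) {
  if (length(studied) < 1L) {
    stop_drm("drm_precondition_error", "studied set is empty")
  }
  if (new_item %in% studied) {
    stop_drm("drm_precondition_error",
             "new item '%s' is part of the studied set", new_item)
  }
  missing <- setdiff(c(new_item, studied), rownames(space))
  if (length(missing) > 0L) {
    stop_drm("drm_lookup_error", "item '%s' not found in %s space",
             missing[1L], attr(space, "modality") %||% "the")
  }
  centroid <- colMeans(space[studied, , drop = FALSE])
  cosine(space_vector(space, new_item), centroid)
}

# cosine of every row of `mat` against a single vector; NA for zero rows if
# allow_zero, else error. Internal fast path for list building.
cosine_rows <- function(mat, v) {
  nv <- sqrt(sum(v^2))
  norms <- sqrt(rowSums(mat^2))
  if (nv == 0 || any(norms == 0)) {
    stop_drm("drm_degenerate_error",
             "cosine similarity is undefined for a zero-norm vector")
  }
  s <- as.numeric(mat %*% v) / (norms * nv)
  pmax(-1, pmin(1, s))
}
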