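#' Item catalog filtering
#'
#' Retains catalog items familiar enough for a recognition experiment:
#' Zipf frequency (a log10 scale of occurrences per billion + 3) of at
#' least `min_zipf_us` in the US label frequency norms and `min_zipf_it`
#' in the Italian ones, and at least `min_exemplars` image exemplars so
#' the category prototype is reliable. Items scoring exactly at a Zipf
#' threshold are retained (the exclusion rule is "lower than").
#'
#' @param catalog data frame with columns `item_id`, `zipf_us`, `zipf_it`,
#'   `n_exemplars` (and typically `category`).
#' @param min_zipf_us,min_zipf_it minimum Zipf frequencies (default 2).
#' @param min_exemplars minimum exemplar count (default 100).
#' @param quiet suppress the per-criterion removal counts message.
#' @return the retained rows, original order preserved.
#' @export
filter_catalog <- function(catalog, min_zipf_us = 2, min_zipf_it = 2,
                           min_exemplars = 100, quiet = FALSE) {
  needed <- c("item_id", "zipf_us", "zipf_it", "n_exemplars")
  if (!all(needed %in% names(catalog))) {
    stop_drm("drm_precondition_error", "catalog lacks column(s): %s",
             paste(setdiff(needed, names(catalog)), collapse = ", "))
  }
  if (anyDuplicated(catalog$item_id)) {
    stop_drm("drm_input_error", "duplicate item id in catalog: '%s'",
             catalog$item_id[duplicated(catalog$item_id)][1L])
  }
  keep_us <- catalog$zipf_us >= min_zipf_us
  keep_it <- catalog$zipf_it >= min_zipf_it
  keep_ex <- catalog$n_exemplars >= min_exemplars
  if (!quiet) {
    message(sprintf(
      "filter_catalog: removed %d (zipf_us < %g), %d (zipf_it < %g), %d (< %d exemplars); %d of %d retained",
      sum(!keep_us), min_zipf_us, sum(!keep_it), min_zipf_it,
      sum(!keep_ex), min_exemplars, sum(keep_us & keep_it & keep_ex), nrow(catalog)))
  }
  catalog[keep_us & keep_it & keep_ex, , drop = FALSE]
}

#' Partition an embedding space into k clusters
#'
#' Spherical k-means: ordinary k-means on length-normalised vectors, which
#' on the unit sphere minimises within-cluster cosine dispersion. Runs 10
#' restarts and keeps the best solution; deterministic for a fixed seed.
#'
#' @param space an [embedding_space()] with no zero vectors.
#' @param k number of clusters (`<=` number of items).
#' @param seed integer seed.
#' @param nstart number of random restarts (default 10).
#' @return named integer vector mapping every item id to a cluster in
#'   `1..k`; all clusters nonempty.
#' @export
partition_space <- function(space, k, seed, nstart = 10L) {
  if (!is_count(k)) stop_drm("drm_precondition_error", "k must be a positive integer")
  if (k > nrow(space)) {
    stop_drm("drm_precondition_error",
             "k = %d exceeds the %d items in the space", k, nrow(space))
  }
  norms <- sqrt(rowSums(space^2))
  if (any(norms == 0)) {
    stop_drm("drm_degenerate_error", "zero-norm vector for item '%s'",
             rownames(space)[which(norms == 0)[1L]])
  }
  unit <- space / norms
  if (k == 1L) {
    return(setNames(rep(1L, nrow(space)), rownames(space)))
  }
  fit <- withr::with_seed(seed,
    kmeans(unit, centers = k, nstart = nstart, iter.max = 100L))
  setNames(as.integer(fit$cluster), rownames(space))
}

#' List-construction configuration
#'
#' Parameters of the similarity-driven DRM list generator. Defaults follow
#' the standard design: 12 lists; per list a close pool of the 50 items
#' most similar to the cluster centroid and a far pool of 50 random items
#' from the rest of the space; 30 studied items drawn from the close pool,
#' 10 of them re-presented as targets; 10 close lures (the unassigned
#' close-pool items nearest the studied centroid) and 10 far lures.
#'
#' @param k_lists number of DRM lists (= clusters).
#' @param close_size,far_size candidate pool sizes per list.
#' @param n_studied studied items per list.
#' @param n_targets studied items re-presented at recognition.
#' @param n_lure_close,n_lure_far lure counts per list.
#' @param seed integer seed driving every random draw in [build_lists()].
#' @return a `list_config` list.
#' @export
list_config <- function(k_lists = 12L, close_size = 50L, far_size = 50L,
                        n_studied = 30L, n_targets = 10L,
                        n_lure_close = 10L, n_lure_far = 10L, seed = 1L) {
  cfg <- list(k_lists = as.integer(k_lists), close_size = as.integer(close_size),
              far_size = as.integer(far_size), n_studied = as.integer(n_studied),
              n_targets = as.integer(n_targets),
              n_lure_close = as.integer(n_lure_close),
              n_lure_far = as.integer(n_lure_far), seed = as.integer(seed))
  with(cfg, {
    if (!all(vapply(cfg[-8L], is_count, logical(1L)))) {
      stop_drm("drm_precondition_error", "all list_config counts must be >= 1")
    }
    if (n_studied + n_lure_close > close_size) {
      stop_drm("drm_precondition_error",
               "close pool (%d) cannot supply %d studied + %d close lures",
               close_size, n_studied, n_lure_close)
    }
    if (n_targets > n_studied) {
      stop_drm("drm_precondition_error", "n_targets exceeds n_studied")
    }
  })
  structure(cfg, class = "list_config")
}

#' Build DRM lists from an embedding space
#'
#' Implements the similarity-driven list-construction algorithm. The space
#' is partitioned into `k_lists` clusters ([partition_space()]); lists are
#' then built cluster by cluster over the pool of not-yet-assigned items:
#'
#' 1. *close pool*: the `close_size` unassigned items with the highest
#'    cosine similarity to the cluster centroid (ties broken by item id);
#' 2. *far pool*: `far_size` uniform draws from unassigned items outside
#'    the close pool;
#' 3. *studied*: `n_studied` uniform draws from the close pool, of which
#'    `n_targets` uniform draws become recognition targets;
#' 4. *close lures*: of the close-pool items not studied, the
#'    `n_lure_close` nearest the studied-set centroid (falling back to the
#'    nearest unassigned items space-wide if the pool runs short);
#' 5. *far lures*: `n_lure_far` uniform draws from the far pool.
#'
#' Only assigned items (studied plus lures, 50 per default list) are
#' consumed; unused pool candidates return to the available pool, and no
#' item appears in more than one list, so each stimulus is encountered at
#' most once across blocks. Deterministic for a fixed `config$seed`.
#'
#' @param space an [embedding_space()] (the vision space in the standard
#'   workflow, since lists are constructed in visual similarity space).
#' @param config a [list_config()].
#' @param clusters optional precomputed `item -> cluster` assignment from
#'   [partition_space()]; computed from `config$seed` when omitted.
#' @return list of `drm_list` objects, each with fields `list_id`,
#'   `studied`, `targets`, `lures_close`, `lures_far`.
#' @export
build_lists <- function(space, config = list_config(), clusters = NULL) {
  k <- config$k_lists
  need <- k * (config$close_size + config$far_size)
  if (nrow(space) < need) {
    stop_drm("drm_capacity_error",
             "need at least %d items for %d lists (%d + %d pools); space has %d",
             need, k, config$close_size, config$far_size, nrow(space))
  }
  if (is.null(clusters)) {
    clusters <- partition_space(space, k, seed = derive_seed(config$seed, 1L))
  }
  ids <- rownames(space)
  withr::with_seed(derive_seed(config$seed, 2L), {
    assigned <- character(0)
    lapply(seq_len(k), function(list_id) {
      members <- ids[clusters == list_id]
      centroid <- colMeans(space[members, , drop = FALSE])
      avail <- setdiff(ids, assigned)

      sims <- cosine_rows(space[avail, , drop = FALSE], centroid)
      ord <- order(-sims, avail)  # highest cosine first, ties by item id
      close_pool <- avail[ord][seq_len(config$close_size)]
      far_candidates <- setdiff(avail, close_pool)

      studied <- sort(sample(close_pool, config$n_studied))
      targets <- sort(sample(studied, config$n_targets))

      studied_centroid <- colMeans(space[studied, , drop = FALSE])
      lure_cand <- setdiff(close_pool, studied)
      if (length(lure_cand) < config$n_lure_close) {
        extra <- setdiff(avail, c(close_pool, studied))
        message(sprintf(
          "build_lists: list %d close pool short of lures (%d < %d); falling back to nearest unassigned items",
          list_id, length(lure_cand), config$n_lure_close))
        lure_cand <- c(lure_cand, extra)
      }
      lsims <- cosine_rows(space[lure_cand, , drop = FALSE], studied_centroid)
      lord <- order(-lsims, lure_cand)
      lures_close <- lure_cand[lord][seq_len(config$n_lure_close)]

      far_pool <- sample(setdiff(far_candidates, lures_close), config$far_size)
      lures_far <- sort(sample(far_pool, config$n_lure_far))

      assigned <<- c(assigned, studied, lures_close, lures_far)
      structure(list(list_id = list_id, studied = studied, targets = targets,
                     lures_close = lures_close, lures_far = lures_far),
                class = "drm_list")
    })
  })
}

#' @export
print.drm_list <- function(x, ...) {
  cat(sprintf("<drm_list %d: %d studied (%d targets), %d + %d lures>\n",
              x$list_id, length(x$studied), length(x$targets),
              length(x$lures_close), length(x$lures_far)))
  invisible(x)
}

#' Dual-space lure similarity table
#'
#' For every lure of every list, the cosine similarity between the lure's
#' vector and the centroid of the list's studied items, computed once in
#' the vision space and once in the language space (same studied ids in
#' both). With `include_targets = TRUE`, target rows are appended too
#' (`origin = "target"`), for Table-1-style accounting over all
#' recognition items.
#'
#' @param lists list of `drm_list` objects from [build_lists()].
#' @param vision,language [embedding_space()]s containing every listed id.
#' @param include_targets also compute similarities for target items
#'   (default `FALSE`: lures only).
#' @return tibble with columns `list_id`, `item_id`, `origin`
#'   (`close`/`far`/`target`), `sim_vision`, `sim_language`; one row per
#'   lure (240 under the default design).
#' @export
similarity_table <- function(lists, vision, language, include_targets = FALSE) {
  rows <- lapply(lists, function(l) {
    items <- c(l$lures_close, l$lures_far)
    origin <- rep(c("close", "far"), c(length(l$lures_close), length(l$lures_far)))
    if (include_targets) {
      items <- c(items, l$targets)
      origin <- c(origin, rep("target", length(l$targets)))
    }
    for (sp in list(vision, language)) {
      missing <- setdiff(c(items, l$studied), rownames(sp))
      if (length(missing) > 0L) {
        stop_drm("drm_lookup_error", "item '%s' not found in %s space",
                 missing[1L], attr(sp, "modality") %||% "a")
      }
    }
    cen_v <- colMeans(vision[l$studied, , drop = FALSE])
    cen_l <- colMeans(language[l$studied, , drop = FALSE])
    tibble::tibble(
      list_id = l$list_id, item_id = items, origin = origin,
      sim_vision = cosine_rows(vision[items, , drop = FALSE], cen_v),
      sim_language = cosine_rows(language[items, , drop = FALSE], cen_l))
  })
  do.call(rbind, rows)
}

#' Rank correlation between the two similarity metrics
#'
#' Spearman correlation between vision-based and language-based lure
#' similarities across all lists — the degree to which the two modalities'
#' prior-knowledge spaces agree on which lures resemble the studied sets.
#'
#' @param table a [similarity_table()] (>= 3 rows).
#' @return list with `rho`, `p_value`, `n`.
#' @export
cross_modal_correlation <- function(table) {
  if (nrow(table) < 3L) {
    stop_drm("drm_precondition_error",
             "need >= 3 rows to correlate (got %d)", nrow(table))
  }
  if (sd(table$sim_vision) == 0 || sd(table$sim_language) == 0) {
    stop_drm("drm_degenerate_error",
             "correlation undefined: a similarity column is constant")
  }
  ct <- suppressWarnings(
    cor.test(table$sim_vision, table$sim_language, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(table))
}

#' Min-max rescaling to the unit interval
#'
#' Affine map sending the observed minimum to 0 and maximum to 1; used for
#' plotting similarity values from spaces with incomparable geometries on
#' a common axis. Rank order is preserved; a value of 1 denotes the
#' highest similarity observed, not identity.
#'
#' @param values numeric vector with at least two distinct values.
#' @return numeric vector in `[0, 1]`, same order.
#' @export
rescale_unit <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    stop_drm("drm_precondition_error", "need >= 2 numeric values")
  }
  r <- range(values)
  if (r[1L] == r[2L]) {
    stop_drm("drm_degenerate_error", "all values equal; range is degenerate")
  }
  (values - r[1L]) / (r[2L] - r[1L])
}

#' Serialize and read back DRM lists
#'
#' Tab-delimited dialect with header `list_id  role  item_id`; roles are
#' `studied`, `target`, `lure_close`, `lure_far` (targets appear both as
#' `studied` and `target` rows, since targets are studied items).
#'
#' @param lists list of `drm_list` objects.
#' @param path file path.
#' @return `write_lists()` invisibly returns `path`; `read_lists()` the
#'   reconstructed list of `drm_list` objects.
#' @export
write_lists <- function(lists, path) {
  rows <- do.call(rbind, lapply(lists, function(l) {
    data.frame(
      list_id = l$list_id,
      role = rep(c("studied", "target", "lure_close", "lure_far"),
                 c(length(l$studied), length(l$targets),
                   length(l$lures_close), length(l$lures_far))),
      item_id = c(l$studied, l$targets, l$lures_close, l$lures_far))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lists
#' @export
read_lists <- function(path) {
  if (!file.exists(path)) stop_drm("drm_io_error", "list file not found: %s", path)
  rows <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c("integer", "character", "character"))
  lapply(sort(unique(rows$list_id)), function(id) {
    r <- rows[rows$list_id == id, ]
    structure(list(
      list_id = id,
      studied = r$item_id[r$role == "studied"],
      targets = r$item_id[r$role == "target"],
      lures_close = r$item_id[r$role == "lure_close"],
      lures_far = r$item_id[r$role == "lure_far"]), class = "drm_list")
  })
}
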