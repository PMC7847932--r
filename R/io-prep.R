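#' Construct a labeled multimodal dataset
#'
#' The central data container: one subjects-by-features matrix per modality,
#' aligned with integer class labels and subject identifiers. All modality
#' matrices must share row count and row order.
#'
#' @param modalities named list of numeric matrices (subjects x features).
#' @param labels integer class codes `0..(K-1)`, one per subject; every class
#'   must be present.
#' @param class_names ordered label vocabulary, length `K`.
#' @param subject_ids character identifiers aligned with rows.
#' @param meta optional list of provenance metadata (normalization, flatten
#'   order, generator settings).
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(modalities, labels, class_names,
                            subject_ids = NULL, meta = list()) {
  if (!is.list(modalities) || length(modalities) == 0)
    abort_validation("modalities must be a nonempty list of matrices")
  modalities <- lapply(modalities, as.matrix)
  if (is.null(names(modalities)))
    names(modalities) <- paste0("modality", seq_along(modalities))
  n <- nrow(modalities[[1]])
  if (!all(vapply(modalities, nrow, 0L) == n))
    abort_validation("all modality matrices must share the same row count")
  labels <- as.integer(labels)
  if (length(labels) != n) abort_validation("labels must align with rows")
  k <- length(class_names)
  if (any(labels < 0 | labels >= k))
    abort_validation("labels must take values in 0..(n_classes - 1)")
  if (!setequal(unique(labels), seq_len(k) - 1L))
    abort_validation("every class in class_names must be present")
  subject_ids <- subject_ids %||% sprintf("subj%03d", seq_len(n))
  if (anyDuplicated(subject_ids))
    abort_validation("duplicate subject_id values")
  if (length(subject_ids) != n)
    abort_validation("subject_ids must align with rows")
  structure(list(modalities = modalities, labels = labels,
                 class_names = as.character(class_names),
                 subject_ids = as.character(subject_ids), meta = meta),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  dims <- vapply(x$modalities, ncol, 0L)
  cat(sprintf("<labeled_dataset> %d subjects, %d modalities (%s features), classes: %s\n",
              length(x$labels), length(x$modalities),
              paste(dims, collapse = "/"),
              paste(sprintf("%s=%d", x$class_names,
                            tabulate(x$labels + 1L, length(x$class_names))),
                    collapse = ", ")))
  invisible(x)
}

#' Row-subset a labeled dataset
#'
#' Subsets every modality matrix, the labels, and the subject ids with the
#' same index vector; optionally re-codes to a two-class task.
#'
#' @param dataset a `labeled_dataset`.
#' @param rows integer or logical row index.
#' @param classes optional character vector of class names to keep; labels
#'   are re-coded `0..(length(classes) - 1)` in the given order.
#' @return A `labeled_dataset`.
#' @export
subset_dataset <- function(dataset, rows = NULL, classes = NULL) {
  labels <- dataset$labels
  keep <- seq_along(labels)
  class_names <- dataset$class_names
  if (!is.null(classes)) {
    if (!all(classes %in% class_names))
      abort_validation("unknown class name in task")
    keep <- keep[class_names[labels + 1L] %in% classes]
    class_names <- classes
  }
  if (!is.null(rows)) keep <- keep[rows]
  labeled_dataset(lapply(dataset$modalities,
                         function(M) M[keep, , drop = FALSE]),
                  match(dataset$class_names[dataset$labels[keep] + 1L],
                        class_names) - 1L,
                  class_names, dataset$subject_ids[keep], dataset$meta)
}

#' Read a NIfTI volume
#'
#' @param path path to a NIfTI file (`.nii` or `.nii.gz`).
#' @return List with `data` (numeric 3D array) and `affine` (4x4 spatial
#'   transform). No resampling is performed.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("volume file not found: '%s'", path))
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    abort_io(sprintf("cannot parse '%s' as NIfTI: %s",
                                     path, conditionMessage(e))))
  list(data = array(as.numeric(img), dim = dim(img)),
       affine = structure(RNifti::xform(img), class = "matrix"))
}

#' Flatten masked voxels to a feature vector
#'
#' Voxels are scanned in C order (last axis fastest), the order recorded in
#' dataset metadata so that feature indices map back to voxel coordinates
#' reproducibly.
#'
#' @param volume 3D numeric array.
#' @param mask 3D logical array of the same shape, or `"nonzero"` to select
#'   voxels with nonzero intensity in this volume.
#' @return Numeric vector of masked voxel values.
#' @export
mask_and_flatten <- function(volume, mask = "nonzero") {
  if (identical(mask, "nonzero")) mask <- volume != 0
  if (!identical(dim(mask), dim(volume)))
    abort_validation("mask shape must equal volume shape")
  flat_v <- flatten_c_order(volume)
  flat_m <- flatten_c_order(mask)
  out <- flat_v[as.logical(flat_m)]
  if (length(out) == 0) warning("mask selects no voxels; empty feature vector")
  out
}

## R arrays are column-major; reverse axes before flattening for C order.
flatten_c_order <- function(a) as.vector(aperm(a, rev(seq_along(dim(a)))))

#' Assemble a labeled dataset from a volume manifest
#'
#' Reads a CSV manifest (`subject_id`, `label`, plus one path column per
#' modality), loads every volume, applies a per-modality mask, flattens in C
#' order and optionally rescales each feature column to \[0, 1\].
#'
#' The `"nonzero"` mask keeps voxels nonzero in *any* volume of the manifest
#' (the union support). When a dataset is assembled inside a cross-validation
#' split, pass only training rows here and transform test rows with the
#' fitted normalization (see [fit_pipeline()]).
#'
#' @param manifest path to the manifest CSV (header row required, UTF-8).
#' @param normalization `"minmax"` (default; per-column rescale to \[0, 1\],
#'   constant columns mapped to 0) or `"none"`.
#' @param mask `"nonzero"` or a list of 3D logical arrays, one per modality
#'   column.
#' @return A `labeled_dataset`.
#' @export
build_dataset <- function(manifest, normalization = c("minmax", "none"),
                          mask = "nonzero") {
  normalization <- match.arg(normalization)
  if (!file.exists(manifest))
    abort_io(sprintf("manifest not found: '%s'", manifest))
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% names(df)))
    abort_validation("manifest must have subject_id and label columns")
  mod_cols <- setdiff(names(df), c("subject_id", "label"))
  if (length(mod_cols) == 0)
    abort_validation("manifest needs at least one modality path column")
  if (anyDuplicated(df$subject_id))
    abort_validation("duplicate subject_id in manifest")
  missing <- unlist(lapply(mod_cols, function(mc) which(!file.exists(df[[mc]]))))
  if (length(missing) > 0)
    abort_io(sprintf("manifest references missing files at rows: %s",
                     paste(sort(unique(missing)), collapse = ", ")))
  class_names <- sort(unique(df$label))
  labels <- match(df$label, class_names) - 1L
  modalities <- list()
  for (mi in seq_along(mod_cols)) {
    vols <- lapply(df[[mod_cols[mi]]], function(p) load_volume(p)$data)
    shp <- dim(vols[[1]])
    if (!all(vapply(vols, function(v) identical(dim(v), shp), TRUE)))
      abort_validation(sprintf("inconsistent volume shapes in modality '%s'",
                               mod_cols[mi]))
    m_mask <- if (identical(mask, "nonzero")) {
      Reduce(`|`, lapply(vols, function(v) v != 0))
    } else mask[[mi]]
    X <- do.call(rbind, lapply(vols, mask_and_flatten, mask = m_mask))
    modalities[[mod_cols[mi]]] <- X
  }
  norm_meta <- NULL
  if (normalization == "minmax") {
    fits <- lapply(modalities, minmax_fit)
    modalities <- Map(minmax_apply, fits, modalities)
    norm_meta <- "minmax"
  }
  labeled_dataset(modalities, labels, class_names, df$subject_id,
                  meta = list(normalization = norm_meta,
                              flatten_order = "C", manifest = manifest))
}

## Min-max normalization, fitted on one split and applicable to another.
## Constant columns map to 0; out-of-range values are clipped to [0, 1].
minmax_fit <- function(X) {
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  list(lo = lo, range = pmax(hi - lo, 0))
}

minmax_apply <- function(fit, X) {
  rng <- ifelse(fit$range > 0, fit$range, 1)
  Z <- sweep(sweep(X, 2L, fit$lo), 2L, rng, `/`)
  Z[, fit$range == 0] <- 0
  pmin(pmax(Z, 0), 1)
}

#' Save a labeled dataset as text
#'
#' Writes one tab-separated matrix per modality plus a JSON sidecar holding
#' labels, class names, subject ids and metadata.
#'
#' @param dataset a `labeled_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    abort_io(sprintf("cannot create directory '%s'", dir))
  for (m in names(dataset$modalities))
    utils::write.table(dataset$modalities[[m]],
                       file.path(dir, paste0(m, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  sidecar <- list(modalities = names(dataset$modalities),
                  labels = dataset$labels,
                  class_names = dataset$class_names,
                  subject_ids = dataset$subject_ids, meta = dataset$meta)
  jsonlite::write_json(sidecar, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a labeled dataset written by [save_dataset()]
#'
#' @param dir dataset directory.
#' @return A `labeled_dataset`.
#' @export
load_dataset <- function(dir) {
  sidecar_path <- file.path(dir, "dataset.json")
  if (!file.exists(sidecar_path))
    abort_io(sprintf("no dataset.json in '%s'", dir))
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  modalities <- lapply(sc$modalities, function(m)
    as.matrix(utils::read.table(file.path(dir, paste0(m, ".tsv")),
                                sep = "\t")))
  modalities <- lapply(modalities, unname)
  names(modalities) <- sc$modalities
  labeled_dataset(modalities, sc$labels, sc$class_names, sc$subject_ids,
                  meta = as.list(sc$meta))
}
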