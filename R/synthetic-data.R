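#' Specification for a synthetic multimodal dataset
#'
#' Describes the class-conditional model used by
#' [generate_multimodal_dataset()]: within each modality, every class is a
#' Gaussian low-rank factor model plus isotropic noise, mapped through a
#' logistic squash so all feature values land in (0, 1) — mirroring
#' normalized image intensities. Class means sit on a line, adjacent classes
#' `separation` within-class standard deviations apart (measured along the
#' mean-difference direction), so with three classes the two extreme groups
#' are the easiest to tell apart, as with the NC/MCI/AD continuum.
#'
#' @param n_per_class subjects per class (>= 2).
#' @param n_modalities number of modalities (default 3: e.g. amyloid-PET,
#'   gray matter, white matter).
#' @param dims per-modality feature dimensionality; scalar or length
#'   `n_modalities`.
#' @param separation distance between adjacent class mean vectors in units
#'   of the within-class standard deviation along that direction; 0 means no
#'   signal.
#' @param latent_rank rank of the shared-factor part of the within-class
#'   covariance; `latent_rank <= dims`.
#' @param noise_sd isotropic noise standard deviation.
#' @param seed master integer seed; per-modality and per-class substreams
#'   are derived from it deterministically.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 60L, n_modalities = 3L, dims = 50L,
                           separation = 4.0, latent_rank = 5L,
                           noise_sd = 0.5, seed = 1L) {
  if (!is_count(n_per_class) || n_per_class < 2)
    abort_validation("n_per_class must be an integer >= 2")
  if (!is_count(n_modalities)) abort_validation("n_modalities must be >= 1")
  dims <- as.integer(rep_len(dims, n_modalities))
  if (!is_count(latent_rank) || any(dims < latent_rank))
    abort_validation("need dims >= latent_rank >= 1 for every modality")
  if (separation < 0) abort_validation("separation must be >= 0")
  if (noise_sd < 0) abort_validation("noise_sd must be >= 0")
  structure(list(n_per_class = as.integer(n_per_class),
                 n_modalities = as.integer(n_modalities), dims = dims,
                 separation = separation, latent_rank = as.integer(latent_rank),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

default_class_names <- function(n_classes) {
  if (n_classes == 2) c("NC", "AD")
  else if (n_classes == 3) c("NC", "MCI", "AD")
  else paste0("class", seq_len(n_classes))
}

#' Generate a labeled multimodal dataset
#'
#' Draws `n_classes * n_per_class` subjects. For modality `m` a mixing
#' matrix `F_m` (`dims x latent_rank`, entries `N(0, 1/latent_rank)`) and a
#' unit separation direction `u_m` are drawn once; subject vectors are
#' `mu_class + F_m z + e` with `z ~ N(0, I)` and `e ~ N(0, noise_sd^2 I)`,
#' then squashed elementwise by the logistic function. Modalities share
#' class labels but have independent mixing matrices and directions,
#' emulating partially redundant PET/GM/WM signal.
#'
#' @param spec a [synthetic_spec()].
#' @param n_classes number of classes (default 2).
#' @param class_names optional class vocabulary; defaults to NC/MCI/AD for
#'   up to three classes.
#' @return A [labeled_dataset()] with one feature matrix per modality,
#'   balanced integer labels, and subject identifiers. Identical `spec`
#'   (including seed) gives bit-identical output.
#' @export
generate_multimodal_dataset <- function(spec, n_classes = 2L,
                                        class_names = NULL) {
  if (!inherits(spec, "synthetic_spec"))
    abort_validation("spec must be a synthetic_spec")
  if (!is_count(n_classes) || n_classes < 2)
    abort_validation("n_classes must be an integer >= 2")
  class_names <- class_names %||% default_class_names(n_classes)
  n <- spec$n_per_class * n_classes
  labels <- rep(seq_len(n_classes) - 1L, each = spec$n_per_class)
  modalities <- vector("list", spec$n_modalities)
  names(modalities) <- paste0("modality", seq_len(spec$n_modalities))
  for (m in seq_len(spec$n_modalities)) {
    p <- spec$dims[m]
    set.seed(derive_seed(spec$seed, paste0("mixing_m", m)))
    Fm <- matrix(stats::rnorm(p * spec$latent_rank,
                              sd = sqrt(1 / spec$latent_rank)),
                 p, spec$latent_rank)
    u <- stats::rnorm(p)
    u <- u / sqrt(sum(u^2))
    ## within-class sd along the separation direction u
    sd_u <- sqrt(sum(crossprod(Fm, u)^2) + spec$noise_sd^2)
    X <- matrix(0, n, p)
    for (cl in seq_len(n_classes)) {
      offset <- (cl - (n_classes + 1) / 2) * spec$separation * sd_u
      set.seed(derive_seed(spec$seed, paste0("draw_m", m, "_c", cl)))
      Z <- matrix(stats::rnorm(spec$n_per_class * spec$latent_rank),
                  spec$n_per_class, spec$latent_rank)
      E <- matrix(stats::rnorm(spec$n_per_class * p, sd = spec$noise_sd),
                  spec$n_per_class, p)
      rows <- which(labels == cl - 1L)
      X[rows, ] <- sweep(tcrossprod(Z, Fm) + E, 2L, offset * u, `+`)
    }
    modalities[[m]] <- stats::plogis(X)
  }
  labeled_dataset(modalities, labels, class_names,
                  subject_ids = sprintf("subj%03d", seq_len(n)),
                  meta = list(generator = "synthetic_multimodal",
                              separation = spec$separation,
                              seed = spec$seed))
}

#' Generate toy NIfTI volumes with a synthetic lesion
#'
#' Writes small 3D volumes for each subject and modality plus a CSV
#' manifest. Every volume is a smooth radial base pattern with additive
#' Gaussian noise; subjects in every class after the first have intensities
#' inside a fixed central sphere multiplied by `attenuation` — a cartoon of
#' focal signal loss ("atrophy"). Intended to exercise the NIfTI reading
#' and dataset-assembly path end to end; makes no attempt at realistic
#' anatomy or SUVR distributions.
#'
#' @param n_per_class subjects per class.
#' @param shape integer length-3 grid dimensions (keep small, e.g. <= 16^3).
#' @param n_classes number of classes (default 2).
#' @param modalities modality (column) names; one volume per modality.
#' @param attenuation multiplicative factor inside the sphere for affected
#'   classes; 1 means no class difference.
#' @param noise_sd additive noise level.
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @return Path of the written manifest CSV, with columns `subject_id`,
#'   `label`, and one path column per modality.
#' @export
generate_toy_volumes <- function(n_per_class, shape = c(12L, 12L, 12L),
                                 n_classes = 2L,
                                 modalities = c("pet", "gm", "wm"),
                                 attenuation = 0.5, noise_sd = 0.05,
                                 seed = 1L, out_dir) {
  if (length(shape) != 3 || any(shape < 2))
    abort_validation("shape must be three grid dimensions >= 2")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    abort_io(sprintf("cannot create output directory '%s'", out_dir))
  class_names <- default_class_names(n_classes)
  sphere <- sphere_mask(shape)
  base <- radial_base(shape)
  rows <- list()
  k <- 0L
  for (cl in seq_len(n_classes)) {
    for (s in seq_len(n_per_class)) {
      k <- k + 1L
      sid <- sprintf("subj%03d", k)
      paths <- character(length(modalities))
      for (m in seq_along(modalities)) {
        set.seed(derive_seed(seed, sprintf("vol_c%d_s%d_m%d", cl, s, m)))
        vol <- base * (0.8 + 0.1 * m) +
          array(stats::rnorm(prod(shape), sd = noise_sd), dim = shape)
        if (cl > 1) vol[sphere] <- vol[sphere] * attenuation
        paths[m] <- file.path(out_dir,
                              sprintf("%s_%s.nii.gz", sid, modalities[m]))
        RNifti::writeNifti(RNifti::asNifti(vol), paths[m])
      }
      rows[[k]] <- c(subject_id = sid, label = class_names[cl],
                     stats::setNames(paths, modalities))
    }
  }
  manifest <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  manifest_path
}

sphere_mask <- function(shape, radius = min(shape) / 4) {
  ctr <- (shape + 1) / 2
  idx <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                     k = seq_len(shape[3]))
  d2 <- (idx$i - ctr[1])^2 + (idx$j - ctr[2])^2 + (idx$k - ctr[3])^2
  array(d2 <= radius^2, dim = shape)
}

radial_base <- function(shape) {
  ctr <- (shape + 1) / 2
  idx <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                     k = seq_len(shape[3]))
  d <- sqrt((idx$i - ctr[1])^2 + (idx$j - ctr[2])^2 + (idx$k - ctr[3])^2)
  array(1 - d / max(d), dim = shape)
}

#' Generate a centered matrix of exact low rank
#'
#' Product of an `n x rank` factor (columns centered) and a `rank x p`
#' factor, so the result has column means zero and numerical rank exactly
#' `rank`. Used as a PCA test fixture.
#'
#' @param n,p matrix dimensions.
#' @param rank target rank, `rank <= min(n, p)`.
#' @param seed integer seed.
#' @return An `n x p` matrix.
#' @export
generate_lowrank_matrix <- function(n, p, rank, seed = 1L) {
  if (!is_count(rank) || rank > min(n, p))
    abort_validation("rank must be in 1..min(n, p)")
  set.seed(seed)
  A <- matrix(stats::rnorm(n * rank), n, rank)
  A <- sweep(A, 2L, colMeans(A))
  B <- matrix(stats::rnorm(rank * p), rank, p)
  A %*% B
}
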