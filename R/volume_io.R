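# Study containers, modality normalization, hierarchical label mapping and
# modality-pair splitting.
#
# Label codes follow the BraTS convention by default: 0 background,
# 1 NCR/NET (necrotic + non-enhancing tumor), 2 ED (edema), 4 ET (enhancing
# tumor). The hierarchical regions are nested: ET <= TC <= WT.

MODALITIES <- c("t1", "t1c", "t2", "flair")

#' Default label code map (BraTS convention)
#' @export
default_code_map <- function() {
  list(background = 0L, ncr_net = 1L, ed = 2L, et = 4L)
}

#' Construct a multi-modal study
#'
#' @param t1,t1c,t2,flair 3D numeric arrays on a common grid.
#' @param spacing Voxel size per axis in mm.
#' @param subject_id Subject identifier.
#' @return An object of class `multimodal_study`.
#' @export
multimodal_study <- function(t1, t1c, t2, flair, spacing = c(1, 1, 1),
                             subject_id = "subject") {
  vols <- list(t1 = t1, t1c = t1c, t2 = t2, flair = flair)
  shp <- dim(t1)
  if (length(shp) != 3L) stop("modality volumes must be 3D arrays")
  for (m in MODALITIES) {
    if (!identical(dim(vols[[m]]), shp)) {
      stop("modality grid shape mismatch: ", m)
    }
  }
  structure(
    c(vols, list(spacing = as.double(spacing), subject_id = subject_id)),
    class = "multimodal_study"
  )
}

#' @export
print.multimodal_study <- function(x, ...) {
  cat(
    "<multimodal_study>", x$subject_id, "grid",
    paste(dim(x$t1), collapse = "x"), "spacing",
    paste(x$spacing, collapse = "x"), "mm\n"
  )
  invisible(x)
}

#' Construct hierarchical region masks
#'
#' Validates that all three masks are binary and nested (ET inside TC inside
#' WT) on a common grid.
#'
#' @param wt,tc,et Binary 3D arrays (whole tumor, tumor core, enhancing tumor).
#' @return An object of class `hierarchical_masks`.
#' @export
hierarchical_masks <- function(wt, tc, et) {
  masks <- list(wt = wt, tc = tc, et = et)
  shp <- dim(wt)
  for (m in names(masks)) {
    v <- masks[[m]]
    if (!identical(dim(v), shp)) stop("mask grid shape mismatch: ", m)
    if (!all(v %in% c(0, 1))) stop("mask '", m, "' is not binary")
    storage.mode(masks[[m]]) <- "integer"
  }
  if (any(masks$et > masks$tc)) {
    stop("nesting invariant violated: ET not contained in TC")
  }
  if (any(masks$tc > masks$wt)) {
    stop("nesting invariant violated: TC not contained in WT")
  }
  structure(masks, class = "hierarchical_masks")
}

#' Read a four-modality study from NIfTI files
#'
#' All four volumes must exist, share one grid shape, and agree on the sform
#' affine within `tol`.
#'
#' @param paths Named character vector/list with entries `t1`, `t1c`, `t2`,
#'   `flair`.
#' @param subject_id Subject identifier (default: directory name of `t1`).
#' @param tol Absolute tolerance for affine agreement.
#' @return A [multimodal_study()].
#' @export
read_study <- function(paths, subject_id = NULL, tol = 1e-4) {
  paths <- as.list(paths)
  missing_mod <- setdiff(MODALITIES, names(paths))
  if (length(missing_mod) > 0L) {
    stop("missing modality path(s): ", paste(missing_mod, collapse = ", "))
  }
  for (m in MODALITIES) {
    if (!file.exists(paths[[m]])) {
      stop("missing modality file for '", m, "': ", paths[[m]])
    }
  }
  nii <- lapply(paths[MODALITIES], read_nifti)
  shp <- dim(nii$t1$img)
  for (m in MODALITIES) {
    if (!identical(dim(nii[[m]]$img), shp)) {
      stop(
        "grid shape mismatch across modalities: ", m, " is ",
        paste(dim(nii[[m]]$img), collapse = "x"), ", expected ",
        paste(shp, collapse = "x")
      )
    }
    if (max(abs(nii[[m]]$header$srow - nii$t1$header$srow)) > tol) {
      stop("affine mismatch across modalities: ", m)
    }
  }
  if (is.null(subject_id)) subject_id <- basename(dirname(paths$t1))
  multimodal_study(nii$t1$img, nii$t1c$img, nii$t2$img, nii$flair$img,
    spacing = nii$t1$spacing, subject_id = subject_id
  )
}

#' Normalize one modality to zero mean and unit variance
#'
#' Statistics are computed over `domain_mask` (default: nonzero voxels, i.e.
#' the skull-stripped brain) with the population standard deviation; voxels
#' outside the domain are set to 0.
#'
#' @param volume 3D numeric array.
#' @param domain_mask Logical/binary array of the same shape, or `NULL` for
#'   the nonzero-voxel default.
#' @return Normalized array.
#' @export
normalize_modality <- function(volume, domain_mask = NULL) {
  if (!all(is.finite(volume))) stop("volume contains non-finite values")
  if (is.null(domain_mask)) domain_mask <- volume != 0
  domain_mask <- domain_mask != 0
  if (!any(domain_mask)) stop("normalization domain is empty")
  v <- volume[domain_mask]
  mu <- mean(v)
  sd_pop <- sqrt(mean((v - mu)^2))
  if (sd_pop == 0) {
    stop("constant image: zero variance inside the normalization domain")
  }
  out <- array(0, dim(volume))
  out[domain_mask] <- (v - mu) / sd_pop
  out
}

#' Normalize all four modalities of a study
#'
#' @param study A [multimodal_study()].
#' @param domain_mask Optional shared normalization domain; default nonzero
#'   voxels per modality.
#' @return The study with normalized volumes.
#' @export
normalize_study <- function(study, domain_mask = NULL) {
  for (m in MODALITIES) {
    study[[m]] <- normalize_modality(study[[m]], domain_mask)
  }
  study
}

#' Map sub-compartment labels to hierarchical region masks
#'
#' WT = ED + ET + NCR/NET, TC = ET + NCR/NET, ET = ET.
#'
#' @param labels Integer 3D array of sub-compartment codes.
#' @param code_map Named list of codes, see [default_code_map()].
#' @return A [hierarchical_masks()] object.
#' @export
map_labels <- function(labels, code_map = default_code_map()) {
  known <- unlist(code_map)
  bad <- setdiff(unique(as.vector(labels)), known)
  if (length(bad) > 0L) {
    stop("unknown label code(s): ", paste(sort(bad), collapse = ", "))
  }
  wt <- array(
    as.integer(labels %in% c(code_map$ed, code_map$et, code_map$ncr_net)),
    dim(labels)
  )
  tc <- array(as.integer(labels %in% c(code_map$et, code_map$ncr_net)), dim(labels))
  et <- array(as.integer(labels == code_map$et), dim(labels))
  hierarchical_masks(wt, tc, et)
}

#' Split a study into the two modality pairs
#'
#' Pair `g1` stacks (T1, T1c) and pair `g2` stacks (T2, FLAIR), in that
#' channel order.
#'
#' @param study A [multimodal_study()].
#' @return List with elements `g1` and `g2`, each a `modality_pair` with
#'   fields `pair_id` and `channels` (4D array, channels last).
#' @export
split_modality_pairs <- function(study) {
  shp <- dim(study$t1)
  mk <- function(id, a, b) {
    structure(
      list(pair_id = id, channels = array(c(a, b), c(shp, 2L))),
      class = "modality_pair"
    )
  }
  list(
    g1 = mk("g1", study$t1, study$t1c),
    g2 = mk("g2", study$t2, study$flair)
  )
}

#' Write hierarchical masks as NIfTI files
#'
#' Writes `wt.nii.gz`, `tc.nii.gz` and `et.nii.gz` (uint8) into `path`.
#' Masks violating the nesting invariant are refused.
#'
#' @param masks A [hierarchical_masks()] object (or a plain list, which is
#'   validated first).
#' @param spacing Voxel size per axis in mm.
#' @param path Output directory, created if needed.
#' @return Invisibly, the three file paths.
#' @export
write_masks <- function(masks, spacing = c(1, 1, 1), path) {
  if (!inherits(masks, "hierarchical_masks")) {
    masks <- hierarchical_masks(masks$wt, masks$tc, masks$et)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  out <- character(0)
  for (m in c("wt", "tc", "et")) {
    p <- file.path(path, paste0(m, ".nii.gz"))
    write_nifti(masks[[m]], p, spacing = spacing, datatype = 2L)
    out <- c(out, p)
  }
  invisible(out)
}

#' Read hierarchical masks written by [write_masks()]
#'
#' @param path Directory containing `wt.nii.gz`, `tc.nii.gz`, `et.nii.gz`.
#' @return A [hierarchical_masks()] object.
#' @export
read_masks <- function(path) {
  g <- function(m) read_nifti(file.path(path, paste0(m, ".nii.gz")))$img
  hierarchical_masks(g("wt"), g("tc"), g("et"))
}

#' Write a study (and optional labels) in the per-subject directory layout
#'
#' Produces `<dir>/{t1,t1c,t2,flair}.nii.gz` and, when `labels` is given,
#' `<dir>/seg.nii.gz`.
#'
#' @param study A [multimodal_study()].
#' @param labels Optional integer label volume.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, labels = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in MODALITIES) {
    write_nifti(study[[m]], file.path(dir, paste0(m, ".nii.gz")),
      spacing = study$spacing, datatype = 16L
    )
  }
  if (!is.null(labels)) {
    write_nifti(labels, file.path(dir, "seg.nii.gz"),
      spacing = study$spacing, datatype = 2L
    )
  }
  invisible(dir)
}

#' Read a study from the per-subject directory layout
#'
#' @param dir Directory with `{t1,t1c,t2,flair}.nii.gz` (and optionally
#'   `seg.nii.gz`).
#' @return List with `study` and `labels` (`NULL` when absent).
#' @export
read_subject_dir <- function(dir) {
  paths <- lapply(MODALITIES, function(m) file.path(dir, paste0(m, ".nii.gz")))
  names(paths) <- MODALITIES
  study <- read_study(paths, subject_id = basename(dir))
  segp <- file.path(dir, "seg.nii.gz")
  labels <- if (file.exists(segp)) {
    a <- read_nifti(segp)$img
    storage.mode(a) <- "integer"
    a
  } else {
    NULL
  }
  list(study = study, labels = labels)
}
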