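# Volume and manifest input/output. NIfTI is the primary on-disk format
# (written/read with RNifti); RDS is the lightweight fallback container.
# Slices are kept in canonical inferior-to-superior order; 0-based slice
# indices everywhere in manifests and traces.

#' Write a phantom cohort to disk
#'
#' Serializes every volume and writes a manifest CSV
#' (`patient_id,path,gg_rp,gg_nb,split,n_slices,tumor_flags`) whose
#' `tumor_flags` column is a compact 0/1 string, so a cohort round-trips
#' losslessly through [read_cohort()]. The manifest embeds the hash of the
#' generating spec as a comment line.
#'
#' @param cohort a `phantom_cohort` from [generate_cohort()].
#' @param directory output directory (created if missing).
#' @param format `"nifti"` (`.nii.gz`) or `"rds"`.
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, directory, format = c("nifti", "rds")) {
  format <- match.arg(format)
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    stop_if_not(ok, "cannot create directory '%s'", directory)
  }
  man <- cohort$manifest
  for (i in seq_len(nrow(man))) {
    v <- cohort$volumes[[i]]
    arr <- array(unlist(v$slices),
                 c(dim(v$slices[[1]]), length(v$slices)))
    path <- file.path(directory, sprintf("%s.%s", v$patient_id,
                                         if (format == "nifti") "nii.gz" else "rds"))
    if (format == "nifti") {
      RNifti::writeNifti(RNifti::asNifti(arr, pixdim = v$spacing), path)
    } else {
      saveRDS(list(array = arr, spacing = v$spacing), path)
    }
    man$path[i] <- path
  }
  manifest_path <- file.path(directory, "manifest.csv")
  hash <- config_hash(cohort$spec %||% cohort$manifest)
  con <- file(manifest_path, "w")
  writeLines(sprintf("# gradenav cohort manifest; config_hash=%s", hash), con)
  utils::write.csv(man, con, row.names = FALSE)
  close(con)
  invisible(manifest_path)
}

#' Read a cohort manifest
#'
#' @param manifest_path path to a manifest CSV written by [write_cohort()]
#'   (or hand-built with the same columns).
#' @return data.frame; validates unique patient ids, grades in 1..5 and
#'   splits in train/val/test.
#' @export
read_manifest <- function(manifest_path) {
  stop_if_not(file.exists(manifest_path), "manifest '%s' not found",
              manifest_path)
  man <- utils::read.csv(manifest_path, comment.char = "#",
                         stringsAsFactors = FALSE,
                         colClasses = c(tumor_flags = "character"))
  stop_if_not(!anyDuplicated(man$patient_id), "duplicate patient_id in manifest")
  gg <- c(man$gg_rp, man$gg_nb)
  stop_if_not(all(is.na(gg) | gg %in% 1:5), "grades must lie in 1..5 or be NA")
  stop_if_not(all(man$split %in% c("train", "val", "test")),
              "split must be train, val or test")
  man
}

#' Read one volume from disk
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) and RDS stacks. NIfTI slices are
#' returned in canonical inferior-to-superior order: when the image's xform
#' maps the third voxel axis against the world z axis (negative determinant
#' component), the slice order is reversed on read. DICOM series are not
#' supported by this reader.
#'
#' @param path volume file. To re-attach labels and tumor flags, pass the
#'   matching `manifest_row`.
#' @param manifest_row optional one-row data.frame from [read_manifest()].
#' @return a `volume_stack` (without lesion masks; `gg_rp`, `gg_nb` and
#'   `tumor_flags` are NA-filled unless a manifest row is supplied).
#' @export
read_volume <- function(path, manifest_row = NULL) {
  stop_if_not(is.character(path) && length(path) == 1,
              "path must be a single file path")
  stop_if_not(file.exists(path), "volume '%s' not found", path)
  if (dir.exists(path)) {
    stop(sprintf("'%s' is a directory: DICOM series input is not supported; convert to NIfTI first", path),
         call. = FALSE)
  }
  ext <- tolower(sub("^.*?(\\.nii(\\.gz)?|\\.rds)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    stop_if_not(length(dim(arr)) == 3, "expected a 3D NIfTI volume")
    spacing <- RNifti::pixdim(img)
    xf <- try(RNifti::xform(img), silent = TRUE)
    flipped <- FALSE
    if (!inherits(xf, "try-error") && is.matrix(xf) && xf[3, 3] < 0) {
      arr <- arr[, , rev(seq_len(dim(arr)[3])), drop = FALSE]
      flipped <- TRUE
    }
  } else if (ext == ".rds") {
    obj <- readRDS(path)
    arr <- obj$array
    spacing <- obj$spacing %||% c(1, 1, 1)
    flipped <- FALSE
  } else {
    stop(sprintf("unsupported volume format: '%s'", path), call. = FALSE)
  }
  n <- dim(arr)[3]
  slices <- lapply(seq_len(n), function(k) arr[, , k])
  flags <- rep(NA, n)
  gg_rp <- NA_integer_; gg_nb <- NA_integer_
  pid <- sub("\\.(nii(\\.gz)?|rds)$", "", basename(path))
  if (!is.null(manifest_row)) {
    pid <- manifest_row$patient_id
    gg_rp <- manifest_row$gg_rp
    gg_nb <- manifest_row$gg_nb
    tf <- manifest_row$tumor_flags
    if (!is.na(tf) && nzchar(tf)) {
      bits <- as.integer(strsplit(tf, "")[[1]])
      stop_if_not(length(bits) == n,
                  "manifest tumor_flags length %d does not match %d slices",
                  length(bits), n)
      flags <- bits == 1L
    }
  }
  structure(list(patient_id = pid, slices = slices,
                 tumor_flags = flags, gg_rp = gg_rp, gg_nb = gg_nb,
                 lesion_masks = vector("list", n),
                 slice_order = if (flipped) "inferior-superior (reversed on read)"
                 else "inferior-superior",
                 spacing = spacing[seq_len(min(3, length(spacing)))]),
            class = "volume_stack")
}

#' Read a whole cohort back from a manifest
#'
#' @param manifest_path manifest CSV from [write_cohort()].
#' @return list with `volumes` and `manifest`, shaped like a cohort from
#'   [generate_cohort()].
#' @export
read_cohort <- function(manifest_path) {
  man <- read_manifest(manifest_path)
  volumes <- lapply(seq_len(nrow(man)), function(i)
    read_volume(man$path[i], man[i, ]))
  structure(list(volumes = volumes, manifest = man, spec = NULL),
            class = "phantom_cohort")
}
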