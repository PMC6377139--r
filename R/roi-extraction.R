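# Optional real-data front end: ROI gray-matter volumes from modulated
# gray-matter probability maps plus an integer-labeled parcellation atlas.
#
# No NIfTI reader ships with this R stack, so a minimal NIfTI-1 reader is
# included: 348-byte header, optional gzip (handled transparently by
# gzfile), the common datatypes, scl_slope/scl_inter scaling and the sform
# affine.  It is deliberately strict rather than general.

.nifti_datatypes <- list(
    `2`   = list(what = "integer", size = 1, signed = FALSE),
    `4`   = list(what = "integer", size = 2, signed = TRUE),
    `8`   = list(what = "integer", size = 4, signed = TRUE),
    `16`  = list(what = "numeric", size = 4, signed = TRUE),
    `64`  = list(what = "numeric", size = 8, signed = TRUE),
    `256` = list(what = "integer", size = 1, signed = TRUE),
    `512` = list(what = "integer", size = 2, signed = FALSE))

#' Read a NIfTI-1 image (minimal reader)
#'
#' Supports single-file `.nii` / `.nii.gz`, 3-D (or trailing-singleton 4-D)
#' images in datatypes uint8/int8/int16/uint16/int32/float32/float64, with
#' `scl_slope`/`scl_inter` scaling applied and the sform affine returned
#' when set (otherwise a diagonal affine from `pixdim`).
#'
#' @param path file path.
#' @return list with `data` (3-D array), `dim`, `pixdim` (voxel sizes, mm),
#'   `affine` (4x4), `voxel_volume` (mm^3).
#' @export
read_nifti <- function(path) {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    hdr <- readBin(con, "raw", 348)
    if (length(hdr) < 348) abort_scnet("file too short for a NIfTI-1 header")
    rd <- function(what, n, size, offset, signed = TRUE, endian) {
        readBin(hdr[(offset + 1):length(hdr)], what, n = n, size = size,
                signed = signed, endian = endian)
    }
    endian <- "little"
    sizeof_hdr <- rd("integer", 1, 4, 0, endian = endian)
    if (sizeof_hdr != 348) {
        endian <- "big"
        sizeof_hdr <- rd("integer", 1, 4, 0, endian = endian)
        if (sizeof_hdr != 348) abort_scnet("not a NIfTI-1 file (bad sizeof_hdr)")
    }
    magic <- rawToChar(hdr[345:347])
    if (!magic %in% c("n+1", "ni1"))
        abort_scnet("not a NIfTI-1 file (bad magic)")
    if (magic == "ni1")
        abort_scnet("two-file NIfTI (.hdr/.img) is not supported")
    dims <- rd("integer", 8, 2, 40, endian = endian)
    ndim <- dims[1]
    if (ndim < 3) abort_scnet("expected a 3-D image")
    shape <- dims[2:(ndim + 1)]
    if (ndim > 3) {
        if (any(shape[4:ndim] != 1))
            abort_scnet("4-D NIfTI with multiple volumes is not supported")
        shape <- shape[1:3]
    }
    datatype <- as.character(rd("integer", 1, 2, 70, endian = endian))
    spec <- .nifti_datatypes[[datatype]]
    if (is.null(spec))
        abort_scnet(sprintf("unsupported NIfTI datatype code %s", datatype))
    pixdim <- rd("numeric", 8, 4, 76, endian = endian)[2:4]
    vox_offset <- rd("numeric", 1, 4, 108, endian = endian)
    scl_slope <- rd("numeric", 1, 4, 112, endian = endian)
    scl_inter <- rd("numeric", 1, 4, 116, endian = endian)
    sform_code <- rd("integer", 1, 2, 254, endian = endian)
    affine <- diag(c(abs(pixdim), 1))
    if (sform_code > 0) {
        srow <- matrix(rd("numeric", 12, 4, 280, endian = endian),
                       nrow = 3, byrow = TRUE)
        affine <- rbind(srow, c(0, 0, 0, 1))
    }
    skip <- vox_offset - 348
    if (skip > 0) readBin(con, "raw", skip)
    nvox <- prod(shape)
    vals <- readBin(con, spec$what, n = nvox, size = spec$size,
                    signed = spec$signed, endian = endian)
    if (length(vals) < nvox) abort_scnet("truncated NIfTI data section")
    vals <- as.numeric(vals)
    if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
        vals <- vals * scl_slope + scl_inter
    list(data = array(vals, dim = shape),
         dim = shape,
         pixdim = abs(pixdim),
         affine = affine,
         voxel_volume = prod(abs(pixdim)))
}

#' Load a parcellation atlas
#'
#' @param image a NIfTI path or a 3-D integer-valued array.
#' @param label_table a TSV path or data.frame with columns `id`, `name`
#'   (one row per ROI; 0 is reserved for background and must not appear).
#' @param voxel_volume voxel volume in mm^3; required when `image` is an
#'   array, derived from the header otherwise.
#' @return object of class `atlas_parcellation` with `label_image`,
#'   `label_table`, `voxel_volume`, `affine`.
#' @export
load_parcellation <- function(image, label_table, voxel_volume = NULL) {
    affine <- NULL
    if (is.character(image)) {
        nii <- read_nifti(image)
        arr <- nii$data
        voxel_volume <- voxel_volume %||% nii$voxel_volume
        affine <- nii$affine
    } else {
        arr <- image
        if (is.null(voxel_volume))
            abort_scnet("voxel_volume is required with an in-memory atlas array",
                        "scnet_validation_error")
    }
    if (any(arr != round(arr)))
        abort_scnet("parcellation image must contain integer labels only",
                    "scnet_validation_error")
    arr <- array(as.integer(round(arr)), dim = dim(arr))
    if (is.character(label_table))
        label_table <- read.delim(label_table, stringsAsFactors = FALSE)
    if (!all(c("id", "name") %in% names(label_table)))
        abort_scnet("label table needs columns id and name",
                    "scnet_validation_error")
    if (anyDuplicated(label_table$id))
        abort_scnet("duplicate ids in label table", "scnet_validation_error")
    if (any(label_table$id == 0))
        abort_scnet("label id 0 is reserved for background",
                    "scnet_validation_error")
    ids_in_image <- setdiff(unique(as.vector(arr)), 0L)
    unknown <- setdiff(ids_in_image, label_table$id)
    if (length(unknown))
        abort_scnet(paste0("image labels missing from table: ",
                           paste(unknown, collapse = ", ")),
                    "scnet_validation_error")
    absent <- setdiff(label_table$id, ids_in_image)
    if (length(absent))
        warning(sprintf("label id(s) %s appear in the table but not in the image; their volumes will be 0",
                        paste(absent, collapse = ", ")), call. = FALSE)
    structure(list(label_image = arr,
                   label_table = label_table[order(label_table$id),
                                             c("id", "name")],
                   voxel_volume = voxel_volume,
                   affine = affine),
              class = "atlas_parcellation")
}

#' Extract ROI gray-matter volumes from modulated maps
#'
#' For each subject and ROI, volume = (sum of gray-matter probability values
#' over the ROI's voxels) x voxel volume, in mm^3 — the modulated-map
#' summation convention, under which voxel values are volume-preserving.
#' Maps must share the atlas grid exactly; no resampling is performed.
#'
#' @param gm_maps named list of NIfTI paths or 3-D arrays, one per subject.
#' @param atlas an [load_parcellation()] result.
#' @param group group label(s) for the subjects (recycled).
#' @return a `roi_volume_table`.
#' @export
extract_roi_volumes <- function(gm_maps, atlas, group = "unknown") {
    if (!inherits(atlas, "atlas_parcellation"))
        abort_scnet("atlas must come from load_parcellation()",
                    "scnet_validation_error")
    if (is.null(names(gm_maps)))
        names(gm_maps) <- sprintf("subject_%03d", seq_along(gm_maps))
    ids <- atlas$label_table$id
    lab <- as.vector(atlas$label_image)
    lab_index <- match(lab, ids)           # NA for background / untracked
    rows <- lapply(gm_maps, function(m) {
        affine <- NULL
        if (is.character(m)) {
            nii <- read_nifti(m)
            affine <- nii$affine
            m <- nii$data
        }
        if (!identical(dim(m), dim(atlas$label_image)))
            abort_scnet("gray-matter map grid does not match the atlas; resample upstream",
                        "scnet_validation_error")
        if (!is.null(affine) && !is.null(atlas$affine) &&
            max(abs(affine - atlas$affine)) > 1e-4)
            abort_scnet("gray-matter map affine does not match the atlas; resample upstream",
                        "scnet_validation_error")
        v <- as.vector(m)
        if (any(v < 0))
            abort_scnet("negative values in gray-matter map",
                        "scnet_validation_error")
        keep <- !is.na(lab_index)
        sums <- numeric(length(ids))
        if (any(keep)) {
            agg <- rowsum(v[keep], lab_index[keep])
            sums[as.integer(rownames(agg))] <- agg[, 1]
        }
        sums * atlas$voxel_volume
    })
    vols <- do.call(rbind, rows)
    colnames(vols) <- atlas$label_table$name
    df <- data.frame(subject_id = names(gm_maps),
                     group = rep_len(group, length(gm_maps)),
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(vols))
    roi_volume_table(df, roi_names = atlas$label_table$name)
}
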