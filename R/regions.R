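#' Integer label atlas with homologous-region lookup
#'
#' An AAL-style parcellation: a 3D integer label volume plus a lookup
#' table mapping each label to a region name, hemisphere, and the label of
#' its homologous (mirror) region in the other hemisphere. The package is
#' atlas-agnostic: any integer label volume on the image grid is accepted,
#' and hemisphere is taken from the lookup table, never inferred from
#' voxel coordinates.
#'
#' @param volume 3D integer array (or a NIfTI path / `niftiImage`;
#'   see [read_label_atlas()]).
#' @param lookup data.frame with columns `label_id`, `name`, `hemisphere`
#'   (`"left"`, `"right"` or `"midline"`), `homolog_id` (0 or NA for
#'   unpaired regions).
#' @return An object of class `label_atlas`.
#' @export
label_atlas <- function(volume, lookup) {
  volume <- as.array(volume)
  if (length(dim(volume)) == 4L && dim(volume)[4] == 1L)
    volume <- array(volume, dim(volume)[1:3])
  if (length(dim(volume)) != 3L)
    stop("atlas-consistency error: label volume must be 3D")
  if (any(volume != round(volume)))
    stop("atlas-consistency error: label volume must be integer-valued")
  need <- c("label_id", "name", "hemisphere", "homolog_id")
  if (!all(need %in% names(lookup)))
    stop("atlas-consistency error: lookup table needs columns ",
         paste(need, collapse = ", "))
  lookup <- as.data.frame(lookup)
  present <- setdiff(sort(unique(as.vector(volume))), 0)
  missing <- setdiff(present, lookup$label_id)
  if (length(missing) > 0)
    stop("atlas-consistency error: labels in volume absent from lookup: ",
         paste(missing, collapse = ", "))
  # homolog mapping must be an involution where defined
  hom <- stats::setNames(lookup$homolog_id, lookup$label_id)
  for (id in lookup$label_id) {
    h <- hom[[as.character(id)]]
    if (is.na(h) || h == 0) next
    if (!as.character(h) %in% names(hom) ||
        hom[[as.character(h)]] != id)
      stop("atlas-consistency error: homolog mapping is not an involution at label ", id)
  }
  structure(list(volume = volume, lookup = lookup), class = "label_atlas")
}

#' Read a label atlas from a NIfTI volume and a TSV lookup table
#'
#' @param nifti_path path to an integer label NIfTI volume.
#' @param lookup_path path to a tab-separated table with columns
#'   `label_id`, `name`, `hemisphere`, `homolog_id`.
#' @return A [label_atlas()].
#' @export
read_label_atlas <- function(nifti_path, lookup_path) {
  vol <- RNifti::readNifti(nifti_path)
  lookup <- utils::read.delim(lookup_path, stringsAsFactors = FALSE)
  label_atlas(vol, lookup)
}

atlas_homolog <- function(atlas, id) {
  row <- atlas$lookup[atlas$lookup$label_id == id, ]
  if (nrow(row) != 1L)
    stop("atlas-consistency error: unknown label ", id)
  h <- row$homolog_id
  if (is.na(h) || h == 0)
    stop("atlas-consistency error: label ", id, " has no homolog entry")
  h
}

voxel_index_sets <- function(atlas, ids) {
  lapply(ids, function(idset) {
    idx <- which(atlas$volume %in% idset)
    if (length(idx) == 0L)
      stop("empty-region error: no voxels carry label(s) ",
           paste(idset, collapse = "+"))
    idx
  })
}

#' Extract per-VOI time-activity curves from a dynamic volume
#'
#' Per frame and per VOI, the TAC value is the mean of the dynamic-volume
#' voxels carrying the VOI's label(s). A VOI given as a vector of several
#' label ids is a merged VOI: the mean is pooled over all its voxels
#' (volume-weighted by construction).
#'
#' @param dynamic_volume 4D array (x, y, z, frame), already on the atlas
#'   grid, or a NIfTI path / `niftiImage`.
#' @param atlas a [label_atlas()].
#' @param ids list of VOIs; each element a label id or vector of ids to
#'   merge. Names of the list become `voi_id`s.
#' @param schedule a [frame_schedule()] with as many frames as the volume.
#' @return A named list of [tissue_tac()] objects.
#' @export
extract_voi_tacs <- function(dynamic_volume, atlas, ids, schedule) {
  stopifnot(inherits(atlas, "label_atlas"), inherits(schedule, "frame_schedule"))
  if (is.character(dynamic_volume)) dynamic_volume <- RNifti::readNifti(dynamic_volume)
  dynamic_volume <- as.array(dynamic_volume)
  if (length(dim(dynamic_volume)) != 4L)
    stop("alignment error: dynamic volume must be 4D")
  if (!identical(dim(dynamic_volume)[1:3], dim(atlas$volume)))
    stop("alignment error: dynamic volume and atlas are on different grids")
  nframes <- dim(dynamic_volume)[4]
  if (nframes != schedule$n)
    stop("alignment error: volume has ", nframes, " frames, schedule has ",
         schedule$n)
  if (!is.list(ids)) ids <- as.list(ids)
  if (is.null(names(ids)))
    names(ids) <- vapply(ids, function(i) paste(i, collapse = "+"), character(1))
  vox <- voxel_index_sets(atlas, ids)
  nvox3 <- prod(dim(atlas$volume))
  mat <- matrix(dynamic_volume, nrow = nvox3, ncol = nframes)
  out <- lapply(seq_along(ids), function(k) {
    vals <- colMeans(mat[vox[[k]], , drop = FALSE])
    tissue_tac(schedule, vals, voi_id = names(ids)[k])
  })
  stats::setNames(out, names(ids))
}

#' Extract per-VOI static activity concentrations
#'
#' One-frame analogue of [extract_voi_tacs()]: per VOI, the mean voxel
#' value of a static (3D) volume.
#'
#' @param static_volume 3D array or NIfTI path / `niftiImage` on the
#'   atlas grid.
#' @param atlas a [label_atlas()].
#' @param ids list of VOIs as in [extract_voi_tacs()].
#' @return Named numeric vector of activity concentrations, kBq mL^-1.
#' @export
extract_static_ac <- function(static_volume, atlas, ids) {
  stopifnot(inherits(atlas, "label_atlas"))
  if (is.character(static_volume)) static_volume <- RNifti::readNifti(static_volume)
  static_volume <- as.array(static_volume)
  if (length(dim(static_volume)) == 4L && dim(static_volume)[4] == 1L)
    static_volume <- array(static_volume, dim(static_volume)[1:3])
  if (!identical(dim(static_volume), dim(atlas$volume)))
    stop("alignment error: static volume and atlas are on different grids")
  if (!is.list(ids)) ids <- as.list(ids)
  if (is.null(names(ids)))
    names(ids) <- vapply(ids, function(i) paste(i, collapse = "+"), character(1))
  vox <- voxel_index_sets(atlas, ids)
  vapply(stats::setNames(seq_along(ids), names(ids)),
         function(k) mean(static_volume[vox[[k]]]), numeric(1))
}

#' VOI selection for one subject
#'
#' @param epileptogenic_ids label ids of the subject's epileptogenic
#'   VOI(s) (on the focus side).
#' @param reference_ids label ids of non-epileptogenic reference VOIs,
#'   disjoint from the epileptogenic set.
#' @param focus_side `"left"` or `"right"`.
#' @return An object of class `voi_selection`.
#' @export
voi_selection <- function(epileptogenic_ids, reference_ids = integer(0),
                          focus_side = c("left", "right")) {
  focus_side <- match.arg(focus_side)
  if (length(intersect(epileptogenic_ids, reference_ids)) > 0)
    stop("atlas-consistency error: epileptogenic and reference sets overlap")
  structure(list(epileptogenic_ids = epileptogenic_ids,
                 reference_ids = reference_ids,
                 focus_side = focus_side),
            class = "voi_selection")
}

#' Pair each selected VOI with its contralateral homolog
#'
#' For each epileptogenic and reference label the contralateral partner
#' is the atlas's homologous label; ipsilateral means "on the focus
#' side", so a selected label whose hemisphere is opposite the focus
#' side is swapped with its homolog.
#'
#' @param atlas a [label_atlas()].
#' @param selection a [voi_selection()].
#' @return data.frame with columns `voi_id` (the selected label),
#'   `class` (`"epileptogenic"` / `"non_epileptogenic"`),
#'   `ipsilateral_id`, `contralateral_id`.
#' @export
pair_regions <- function(atlas, selection) {
  stopifnot(inherits(atlas, "label_atlas"), inherits(selection, "voi_selection"))
  one <- function(id, cls) {
    row <- atlas$lookup[atlas$lookup$label_id == id, ]
    if (nrow(row) != 1L)
      stop("atlas-consistency error: unknown label ", id)
    hom <- atlas_homolog(atlas, id)
    if (row$hemisphere == selection$focus_side) {
      ipsi <- id; contra <- hom
    } else {
      ipsi <- hom; contra <- id
    }
    data.frame(voi_id = id, class = cls,
               ipsilateral_id = ipsi, contralateral_id = contra)
  }
  rows <- c(lapply(selection$epileptogenic_ids, one, cls = "epileptogenic"),
            lapply(selection$reference_ids, one, cls = "non_epileptogenic"))
  do.call(rbind, rows)
}
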