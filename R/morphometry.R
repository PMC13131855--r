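#' Per-region perivascular-space morphometry
#'
#' Labels the binary PVS mask into connected components, assigns each
#' component to the atlas region containing the plurality of its voxels
#' (components with more than half their voxels outside every region are
#' dropped, with a message; ties between regions break to the
#' lexicographically smallest region name), and summarizes per region:
#' count, total volume, mean component diameter, and count/volume fractions
#' normalized by the regional white-matter volume.
#'
#' @param pvs_mask binary 3D array (the segmented PVS mask).
#' @param atlas a [region_atlas()] on the same grid.
#' @param connectivity component connectivity (default 26).
#' @return data.frame with one row per atlas region: `region_name`,
#'   `hemisphere`, `lobe`, `count`, `total_volume` (mm^3), `mean_diameter`
#'   (mm, NA when count is 0), `count_fraction` (1/mm^3), `volume_fraction`,
#'   `wm_volume` (mm^3).
#' @export
regional_pvs_metrics <- function(pvs_mask, atlas, connectivity = 26) {
  if (!inherits(atlas, "region_atlas")) stop("`atlas` must be a region_atlas")
  if (!identical(dim(pvs_mask), dim(atlas$masks[[1]])))
    stop("pvs_mask grid differs from atlas")
  if (any(atlas$regions$wm_volume <= 0))
    stop("atlas contains region(s) with zero white-matter volume")
  h <- atlas$voxel_size
  vox_mm3 <- prod(h)
  reg_names <- atlas$regions$name
  # integer region-index volume (masks assumed disjoint; later regions win)
  reg_idx <- array(0L, dim = dim(pvs_mask))
  for (i in seq_along(reg_names)) reg_idx[atlas$masks[[reg_names[i]]] != 0] <- i

  comp <- label_components(pvs_mask, connectivity)
  n_reg <- length(reg_names)
  counts <- integer(n_reg)
  volumes <- numeric(n_reg)
  diam_lists <- vector("list", n_reg)
  dropped <- 0L
  d <- dim(pvs_mask)
  for (k in seq_len(comp$n)) {
    vx <- comp$voxels[[k]]
    lin <- vx[, 1] + (vx[, 2] - 1L) * d[1] + (vx[, 3] - 1L) * d[1] * d[2]
    ri <- reg_idx[lin]
    n_vox <- length(ri)
    inside <- ri[ri > 0L]
    if (length(inside) * 2L < n_vox || length(inside) == 0L) {
      dropped <- dropped + 1L
      next
    }
    tab <- tabulate(inside, nbins = n_reg)
    best <- which(tab == max(tab))
    if (length(best) > 1) best <- best[order(reg_names[best])][1]
    cm <- component_metrics(vx, h)
    counts[best] <- counts[best] + 1L
    volumes[best] <- volumes[best] + cm$volume
    diam_lists[[best]] <- c(diam_lists[[best]], cm$diameter)
  }
  if (dropped > 0)
    message(dropped, " component(s) fell majority-outside all regions and were dropped")
  mean_diam <- vapply(diam_lists, function(x)
    if (is.null(x)) NA_real_ else mean(x), numeric(1))
  out <- data.frame(
    region_name = reg_names,
    hemisphere = atlas$regions$hemisphere,
    lobe = atlas$regions$lobe,
    count = counts,
    total_volume = volumes,
    mean_diameter = mean_diam,
    count_fraction = counts / atlas$regions$wm_volume,
    volume_fraction = volumes / atlas$regions$wm_volume,
    wm_volume = atlas$regions$wm_volume,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Assemble the wide per-subject PVS feature table
#'
#' One row per subject, one column per region x metric with metrics VF
#' (volume fraction), CF (count fraction) and DM (mean diameter). With the
#' full 56-region atlas this yields the 168 PVS variables analyzed per
#' subject. Column order is deterministic: lobe (frontal, parietal,
#' temporal, occipital), region in canonical listing order, hemisphere
#' (L, R), then metric (VF, CF, DM); input region order is irrelevant.
#'
#' @param per_subject_metrics named list (names = subject ids) of
#'   [regional_pvs_metrics()] data.frames covering identical region sets.
#' @return data.frame with `subject_id` plus `3 * n_regions` feature columns
#'   named `<region>_<metric>`, e.g. `L-precuneus_VF`.
#' @export
assemble_feature_table <- function(per_subject_metrics) {
  if (length(per_subject_metrics) == 0) stop("no subjects supplied")
  ids <- names(per_subject_metrics)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("per_subject_metrics must be a named list (subject ids)")
  ref <- per_subject_metrics[[1]]
  known <- wm_lobe_regions()
  ord <- order(match(sub("^[LR]-", "", ref$region_name), known$region),
               match(ref$hemisphere, c("L", "R")))
  regions <- ref$region_name[ord]
  metrics <- c("VF", "CF", "DM")
  col_of <- c(VF = "volume_fraction", CF = "count_fraction",
              DM = "mean_diameter")
  feat_names <- as.vector(t(outer(regions, metrics, paste, sep = "_")))
  rows <- lapply(ids, function(id) {
    m <- per_subject_metrics[[id]]
    miss <- setdiff(regions, m$region_name)
    extra <- setdiff(m$region_name, regions)
    if (length(miss) || length(extra))
      stop(sprintf("subject %s: region set mismatch (missing: %s; extra: %s)",
                   id,
                   if (length(miss)) paste(miss, collapse = ",") else "none",
                   if (length(extra)) paste(extra, collapse = ",") else "none"))
    at <- match(regions, m$region_name)
    vals <- unlist(lapply(seq_along(regions), function(i)
      c(m$volume_fraction[at[i]], m$count_fraction[at[i]],
        m$mean_diameter[at[i]])))
    vals
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- feat_names
  cbind(data.frame(subject_id = ids, stringsAsFactors = FALSE), out)
}
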