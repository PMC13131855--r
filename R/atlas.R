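#' White-matter regions analyzed per lobe
#'
#' The 28 bilateral Desikan-Killiany white-matter regions grouped by
#' anatomical lobe: 11 frontal, 5 parietal, 8 temporal and 4 occipital masks
#' per hemisphere (56 region masks in total). Region order within a lobe is
#' the canonical listing used throughout the package (feature-table column
#' order, tie-breaks).
#'
#' @return A data.frame with columns `region` and `lobe`.
#' @export
wm_lobe_regions <- function() {
  data.frame(
    region = c(
      "superiorfrontal", "rostralmiddlefrontal", "caudalmiddlefrontal",
      "parsopercularis", "parsorbitalis", "parstriangularis",
      "lateralorbitofrontal", "medialorbitofrontal", "precentral",
      "paracentral", "frontalpole",
      "postcentral", "supramarginal", "superiorparietal",
      "inferiorparietal", "precuneus",
      "entorhinal", "parahippocampal", "fusiform", "superiortemporal",
      "middletemporal", "inferiortemporal", "transversetemporal",
      "temporalpole",
      "lingual", "pericalcarine", "cuneus", "lateraloccipital"
    ),
    lobe = rep(c("frontal", "parietal", "temporal", "occipital"),
               times = c(11L, 5L, 8L, 4L)),
    stringsAsFactors = FALSE
  )
}

#' Look up the lobe of a region name
#'
#' Accepts bare region names (`"precuneus"`) or hemisphere-prefixed mask
#' names (`"L-precuneus"`).
#'
#' @param region character vector of region or mask names.
#' @return Character vector of lobes (`NA` for unknown regions).
#' @export
region_lobe <- function(region) {
  tab <- wm_lobe_regions()
  bare <- sub("^[LR]-", "", region)
  tab$lobe[match(bare, tab$region)]
}

#' Construct a named region atlas
#'
#' Bundles binary white-matter region masks with hemisphere and lobe tags and
#' the regional WM volumes used for count/volume-fraction normalization.
#' Masks whose name is outside the 28-region analysis set are dropped with a
#' warning (the segmentation step may use a wider mask set than the analysis).
#'
#' @param masks named list of binary 3D arrays, names like `"L-precuneus"`.
#' @param voxel_size voxel edge length(s), mm.
#' @param require_full if TRUE, all 56 region masks must be present.
#' @return A `region_atlas`: list with `regions` (data.frame: name,
#'   hemisphere, region, lobe, wm_volume), `masks`, `voxel_size`.
#' @export
region_atlas <- function(masks, voxel_size = 1, require_full = FALSE) {
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("all atlas masks must be named, e.g. 'L-precuneus'")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  hemi <- substr(names(masks), 1, 1)
  bare <- sub("^[LR]-", "", names(masks))
  known <- wm_lobe_regions()
  keep <- hemi %in% c("L", "R") & bare %in% known$region
  if (any(!keep)) {
    warning("ignoring ", sum(!keep), " mask(s) outside the 28-region set: ",
            paste(names(masks)[!keep], collapse = ", "))
    masks <- masks[keep]; hemi <- hemi[keep]; bare <- bare[keep]
  }
  if (anyDuplicated(names(masks))) stop("duplicated region mask names")
  if (require_full && length(masks) != 56L)
    stop("expected the full 56-mask atlas, got ", length(masks), " masks")
  vox_mm3 <- prod(voxel_size)
  wm_volume <- vapply(masks, function(m) sum(m != 0) * vox_mm3, numeric(1))
  if (any(wm_volume <= 0))
    stop("empty region mask(s): ",
         paste(names(masks)[wm_volume <= 0], collapse = ", "))
  regions <- data.frame(
    name = names(masks), hemisphere = hemi, region = bare,
    lobe = known$lobe[match(bare, known$region)],
    wm_volume = wm_volume, stringsAsFactors = FALSE
  )
  # canonical order: lobe, region listing order, hemisphere
  ord <- order(match(regions$region, known$region),
               match(regions$hemisphere, c("L", "R")))
  regions <- regions[ord, , drop = FALSE]
  rownames(regions) <- NULL
  structure(list(regions = regions, masks = masks[regions$name],
                 voxel_size = voxel_size),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("<region_atlas> %d masks, voxel %s mm\n",
              nrow(x$regions),
              paste(signif(x$voxel_size, 3), collapse = "x")))
  print(table(lobe = x$regions$lobe, hemisphere = x$regions$hemisphere))
  invisible(x)
}

# union of all region masks as a logical array
atlas_union_mask <- function(atlas, grid_shape = NULL) {
  shp <- dim(atlas$masks[[1]])
  out <- array(FALSE, dim = shp)
  for (m in atlas$masks) out <- out | (m != 0)
  out
}
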