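#' Normalize a structure volume by intracranial volume
#'
#' @param volume structure volume, mm^3 (> 0).
#' @param etiv estimated total intracranial volume, mm^3 (> 0).
#' @return `volume / etiv` (dimensionless). A ratio of 1 or more is allowed
#'   but flagged with a message, as it is anatomically implausible.
#' @export
normalize_volume <- function(volume, etiv) {
  if (any(!is.finite(etiv)) || any(etiv <= 0))
    stop("etiv must be positive")
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("volume must be positive")
  r <- volume / etiv
  if (any(r >= 1))
    message("normalized volume >= 1: structure larger than eTIV is implausible")
  r
}

# canonical structure/hemisphere names from common segmentation-output labels
.aseg_label_map <- c(
  "Left-Lateral-Ventricle"  = "lateral_ventricle/L",
  "Right-Lateral-Ventricle" = "lateral_ventricle/R",
  "Left-choroid-plexus"     = "choroid_plexus/L",
  "Right-choroid-plexus"    = "choroid_plexus/R"
)

required_volumetric_rows <- function() {
  data.frame(structure = rep(c("lateral_ventricle", "choroid_plexus"), each = 2),
             hemi = rep(c("L", "R"), 2), stringsAsFactors = FALSE)
}

#' Read a segmentation-statistics table into volumetric records
#'
#' Accepts two dialects, auto-detected:
#' \describe{
#'   \item{flat}{a delimited table (TSV or CSV) with columns `subject`,
#'     `structure` (`lateral_ventricle`, `choroid_plexus`), `hemi`
#'     (`L`/`R`), `volume_mm3`, `etiv_mm3` — one or many subjects (the
#'     format written by [write_volumetric_table()]).}
#'   \item{aseg.stats}{a single-subject FreeSurfer-style stats file: `#`
#'     header lines including a
#'     `# Measure EstimatedTotalIntraCranialVol, eTIV, ...` record, then
#'     whitespace-delimited rows with `Volume_mm3` and `StructName` columns
#'     (`Left-Lateral-Ventricle`, `Right-choroid-plexus`, ...). Unknown
#'     structures are ignored.}
#' }
#'
#' @param path path to the table.
#' @param subject subject id for the aseg.stats dialect (default: file stem).
#' @return data.frame with one record per structure per hemisphere per
#'   subject: `subject`, `structure`, `hemi`, `volume_mm3`, `etiv_mm3`,
#'   `normalized_volume`. Errors name the subject and the missing field,
#'   e.g. `choroid_plexus/R`.
#' @export
read_aseg_table <- function(path, subject = NULL) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    recs <- read_aseg_stats_file(path, subject)
  } else {
    sep <- if (grepl("\t", first)) "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    need <- c("subject", "structure", "hemi", "volume_mm3", "etiv_mm3")
    if (!all(need %in% names(tab)))
      stop("flat volumetric table must have columns: ",
           paste(need, collapse = ", "))
    recs <- tab[, need]
  }
  req <- required_volumetric_rows()
  for (s in unique(recs$subject)) {
    sub <- recs[recs$subject == s, ]
    for (i in seq_len(nrow(req))) {
      hit <- sub$structure == req$structure[i] & sub$hemi == req$hemi[i]
      if (!any(hit))
        stop(sprintf("subject %s: missing %s/%s row",
                     s, req$structure[i], req$hemi[i]))
    }
    if (any(!is.finite(sub$etiv_mm3)) || any(sub$etiv_mm3 <= 0))
      stop(sprintf("subject %s: missing or non-positive eTIV", s))
  }
  known <- recs$structure %in% c("lateral_ventricle", "choroid_plexus")
  recs <- recs[known, , drop = FALSE]
  recs$normalized_volume <- normalize_volume(recs$volume_mm3, recs$etiv_mm3)
  rownames(recs) <- NULL
  recs
}

read_aseg_stats_file <- function(path, subject = NULL) {
  if (is.null(subject))
    subject <- sub("\\.stats$", "", basename(path))
  lines <- readLines(path)
  etiv <- NA_real_
  m <- grep("^# Measure EstimatedTotalIntraCranialVol", lines, value = TRUE)
  if (length(m)) {
    parts <- strsplit(m[1], ",")[[1]]
    if (length(parts) >= 4) etiv <- as.numeric(trimws(parts[4]))
  }
  if (!is.finite(etiv))
    stop(sprintf("subject %s: missing eTIV measure line", subject))
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  rows <- list()
  for (ln in body) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 5) next
    label <- f[5]  # Index SegId NVoxels Volume_mm3 StructName ...
    canon <- .aseg_label_map[label]
    if (is.na(canon)) next
    sh <- strsplit(canon, "/")[[1]]
    rows[[length(rows) + 1]] <- data.frame(
      subject = subject, structure = sh[1], hemi = sh[2],
      volume_mm3 = as.numeric(f[4]), etiv_mm3 = etiv,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop(sprintf("subject %s: no recognizable structure rows", subject))
  do.call(rbind, rows)
}

#' Write volumetric records as a flat TSV
#'
#' @param tbl data.frame as from [generate_volumetric_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volumetric_table <- function(tbl, path) {
  need <- c("subject", "structure", "hemi", "volume_mm3", "etiv_mm3")
  if (!all(need %in% names(tbl)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  utils::write.table(tbl[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Wide eTIV-normalized volume outcomes per subject
#'
#' Reshapes volumetric records to one row per subject with the four
#' normalized outcome columns used in cohort models.
#'
#' @param records data.frame from [read_aseg_table()] (or any table with
#'   `subject`, `structure`, `hemi`, `volume_mm3`, `etiv_mm3`).
#' @return data.frame: `subject_id`, `lateral_ventricle_L`,
#'   `lateral_ventricle_R`, `choroid_plexus_L`, `choroid_plexus_R`
#'   (all volume / eTIV).
#' @export
volumetric_outcomes <- function(records) {
  if (!"normalized_volume" %in% names(records))
    records$normalized_volume <-
      normalize_volume(records$volume_mm3, records$etiv_mm3)
  key <- paste(records$structure, records$hemi, sep = "_")
  subs <- unique(records$subject)
  cols <- c("lateral_ventricle_L", "lateral_ventricle_R",
            "choroid_plexus_L", "choroid_plexus_R")
  out <- data.frame(subject_id = subs, stringsAsFactors = FALSE)
  for (cl in cols) {
    v <- rep(NA_real_, length(subs))
    hit <- key == cl
    v[match(records$subject[hit], subs)] <- records$normalized_volume[hit]
    out[[cl]] <- v
  }
  out
}
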