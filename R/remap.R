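#' Label-code constants of the edited segmentation
#'
#' The edited segmentation uses a fixed integer scheme: 1-76 are the
#' remapped FreeSurfer ROIs, 77 is superior cerebellar gray (filled by the
#' cerebellar split), 78 is the inferior cerebellar gray reference region,
#' 79/80 are high/low choroid plexus, 81/82 low/high CSF, 83/84 low/high
#' bone+meninges, and extra-cortical hotspots start at 85 and count up.
#' Reference-region hotspots, when found, continue after the highest
#' hotspot label. FreeSurfer cerebellar-gray codes (8, 47) are carried
#' under a reserved internal code until the split assigns them to 77/78.
#'
#' @name label_codes
#' @export
taupvc_labels <- list(
  superior_cerebellar  = 77L,
  inferior_cerebellar  = 78L,
  choroid_high         = 79L,
  choroid_low          = 80L,
  csf_low              = 81L,
  csf_high             = 82L,
  bone_low             = 83L,
  bone_high            = 84L,
  ech_first            = 85L,
  whole_choroid        = 200L,  # config 1 only: unsplit choroid plexus
  reserved_cereb_gray  = 999L   # pre-split pass-through of FreeSurfer 8/47
)

# FreeSurfer aseg codes for choroid plexus; the pipeline takes the choroid
# mask from the raw segmentation, not the remapped one.
CHOROID_FS_CODES <- c(31L, 63L)
CEREB_GRAY_FS_CODES <- c(8L, 47L)
VENTRICLE_FS_CODES <- c(4L, 5L, 14L, 15L, 24L, 43L, 44L, 72L)

#' Default FreeSurfer-to-edited remap table
#'
#' Returns the built-in mapping from FreeSurfer aparc+aseg codes to the 77
#' edited ROI indices, including the multi-source entries (frontal
#' composites, hemispherical white matter, the grab-bag "Other" ROI) and
#' the ventricle codes mapped to 0 (ventricles are unassigned and assumed
#' to have zero activity under the GTM). Entry 77 (superior cerebellar
#' gray) has no FreeSurfer sources of its own: it is carved out of the
#' cerebellar gray codes 8/47 by the SUIT-based split.
#'
#' @return A data frame with columns `edited_index` (integer 0-77),
#'   `freesurfer_indices` (list of integer vectors) and `name`.
#' @seealso [remap_labels()], [load_remap_table()]
#' @export
default_remap_table <- function() {
  e <- function(idx, fs, name) list(edited_index = idx, fs = as.integer(fs),
                                    name = name)
  rows <- list(
    e(1L, 1006, "L Entorhinal Cortex"),
    e(2L, 2006, "R Entorhinal Cortex"),
    e(3L, 17, "L Hippocampus"),
    e(4L, 53, "R Hippocampus"),
    e(5L, 1016, "L Parahippocampal"),
    e(6L, 1007, "L Fusiform"),
    e(7L, 1013, "L Lingual"),
    e(8L, 18, "L Amygdala"),
    e(9L, 2016, "R Parahippocampal"),
    e(10L, 2007, "R Fusiform"),
    e(11L, 2013, "R Lingual"),
    e(12L, 54, "R Amygdala"),
    e(13L, 1015, "L Middle Temporal"),
    e(14L, 10, "L Thalamus"),
    e(15L, 1002, "L CaudAnt Cingulate"),
    e(16L, 1026, "L RostAnt Cingulate"),
    e(17L, 1023, "L Post Cingulate"),
    e(18L, 1010, "L Isthmus Cingulate"),
    e(19L, 1035, "L Insula"),
    e(20L, 1009, "L Inferior Temporal"),
    e(21L, 1033, "L Temporal Pole"),
    e(22L, 2015, "R Middle Temporal"),
    e(23L, 49, "R Thalamus"),
    e(24L, 2002, "R CaudAnt Cingulate"),
    e(25L, 2026, "R RostAnt Cingulate"),
    e(26L, 2023, "R Post Cingulate"),
    e(27L, 2010, "R Isthmus Cingulate"),
    e(28L, 2035, "R Insula"),
    e(29L, 2009, "R Inferior Temporal"),
    e(30L, 2033, "R Temporal Pole"),
    e(31L, 1028, "L Frontal SUPFR"),
    e(32L, c(1012, 1014, 1032), "L Frontal FPORB"),
    e(33L, c(1003, 1027), "L Frontal MIDFR"),
    e(34L, c(1018, 1019, 1020), "L Frontal PARSFR"),
    e(35L, 11, "L Caudate"),
    e(36L, 12, "L Putamen"),
    e(37L, 1011, "L Lateral Occipital"),
    e(38L, 1031, "L Parietal Supramarginal"),
    e(39L, 1008, "L Parietal Inferior"),
    e(40L, 1030, "L Superior Temporal"),
    e(41L, 13, "L Pallidum"),
    e(42L, 1029, "L Parietal Superior"),
    e(43L, 1025, "L Precuneus"),
    e(44L, 1001, "L BankSTS"),
    e(45L, 26, "L Accumbens"),
    e(46L, 1034, "L Tranv Temporal"),
    e(47L, 2028, "R Frontal SUPFR"),
    e(48L, c(2012, 2014, 2032), "R Frontal FPORB"),
    e(49L, c(2003, 2027), "R Frontal MIDFR"),
    e(50L, c(2018, 2019, 2020), "R Frontal PARSFR"),
    e(51L, 50, "R Caudate"),
    e(52L, 51, "R Putamen"),
    e(53L, 2011, "R Lateral Occipital"),
    e(54L, 2031, "R Parietal Supramarginal"),
    e(55L, 2008, "R Parietal Inferior"),
    e(56L, 2030, "R Superior Temporal"),
    e(57L, 52, "R Pallidum"),
    e(58L, 2029, "R Parietal Superior"),
    e(59L, 2025, "R Precuneus"),
    e(60L, 2001, "R BankSTS"),
    e(61L, 58, "R Accumbens"),
    e(62L, 2034, "R Tranv Temporal"),
    e(63L, 1021, "L Pericalcarine"),
    e(64L, 1022, "L Postcentral"),
    e(65L, 1005, "L Cuneus"),
    e(66L, 1024, "L Precentral"),
    e(67L, 1017, "L Paracentral"),
    e(68L, 2021, "R Pericalcarine"),
    e(69L, 2022, "R Postcentral"),
    e(70L, 2005, "R Cuneus"),
    e(71L, 2024, "R Precentral"),
    e(72L, 2017, "R Paracentral"),
    e(73L, c(2, 41, 251:255), "Hemispherical White"),
    e(74L, c(7, 46), "Cerebellar White"),
    e(75L, 16, "Brainstem"),
    e(76L, c(28, 30, 60, 62, 77, 80, 85, 1000, 1004, 2000, 2004), "Other"),
    e(77L, integer(0), "Superior Cerebellar Gray")
  )
  tbl <- data.frame(
    edited_index = vapply(rows, `[[`, integer(1), "edited_index"),
    name = vapply(rows, `[[`, character(1), "name"),
    stringsAsFactors = FALSE)
  tbl$freesurfer_indices <- lapply(rows, `[[`, "fs")
  validate_remap_table(tbl)
  tbl
}

validate_remap_table <- function(tbl) {
  if (!setequal(tbl$edited_index, 1:77) || anyDuplicated(tbl$edited_index))
    stop("remap table must cover edited indices 1..77 exactly once")
  fs_all <- unlist(tbl$freesurfer_indices)
  if (anyDuplicated(fs_all))
    stop("a FreeSurfer index appears in more than one remap entry: ",
         paste(unique(fs_all[duplicated(fs_all)]), collapse = ", "))
  bad <- intersect(fs_all, VENTRICLE_FS_CODES)
  if (length(bad))
    stop("ventricle codes cannot be remapped: ", paste(bad, collapse = ", "))
  invisible(tbl)
}

#' Load a remap table from TSV
#'
#' Reads a custom remap table with columns `edited_index`,
#' `freesurfer_indices` (comma-separated integers; may be empty) and
#' `name`, so that dialect drift across FreeSurfer versions can be handled
#' without code changes. The same validity rules as the built-in table
#' apply.
#'
#' @param path TSV file path.
#' @return A remap table data frame (see [default_remap_table()]).
#' @export
load_remap_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("integer", "character", "character"))
  tbl <- data.frame(edited_index = raw$edited_index, name = raw$name,
                    stringsAsFactors = FALSE)
  tbl$freesurfer_indices <- lapply(strsplit(raw$freesurfer_indices, ","), function(s) {
    s <- trimws(s[nzchar(trimws(s))])
    as.integer(s)
  })
  validate_remap_table(tbl)
  tbl
}

#' Remap a FreeSurfer segmentation into the edited ROI scheme
#'
#' Applies the remap table to an aparc+aseg-style label volume: every
#' recognized FreeSurfer code gets its edited index, ventricle codes go to
#' 0 (unassigned, zero activity), cerebellar gray codes 8/47 are carried
#' under the reserved internal code for the SUIT split to resolve, and any
#' other unrecognized nonzero code goes to 0 (real segmentations contain
#' codes outside the scheme; excluding them matches the zero-activity
#' assumption for undefined voxels). The count of dropped voxels is
#' reported as a message.
#'
#' @param aparc a `taupvc_label` volume holding FreeSurfer codes.
#' @param table remap table; defaults to [default_remap_table()].
#' @param ignore_codes codes silently mapped to 0 because a later stage
#'   handles them (default: the choroid plexus codes, which the choroid
#'   split takes from the raw segmentation).
#' @return A `taupvc_label` volume in the edited scheme.
#' @export
remap_labels <- function(aparc, table = default_remap_table(),
                         ignore_codes = CHOROID_FS_CODES) {
  stopifnot(inherits(aparc, "taupvc_label"))
  src <- aparc$data
  codes <- sort(unique(as.vector(src)))
  codes <- codes[codes != 0L]

  lut_from <- unlist(table$freesurfer_indices)
  lut_to <- rep.int(table$edited_index,
                    lengths(table$freesurfer_indices))
  lut_from <- c(lut_from, VENTRICLE_FS_CODES, CEREB_GRAY_FS_CODES,
                ignore_codes)
  lut_to <- c(lut_to, rep.int(0L, length(VENTRICLE_FS_CODES)),
              rep.int(taupvc_labels$reserved_cereb_gray, 2L),
              rep.int(0L, length(ignore_codes)))

  unknown <- setdiff(codes, lut_from)
  out <- array(0L, dim = dim(src))
  known <- src %in% setdiff(lut_from, unknown) & src != 0L
  out[known] <- lut_to[match(src[known], lut_from)]
  n_dropped <- sum(src %in% unknown)
  if (n_dropped > 0L)
    message(sprintf("remap_labels: %d voxels with %d unrecognized codes set to 0",
                    n_dropped, length(unknown)))
  with_data(aparc, out)
}

#' Braak-stage composite ROI sets
#'
#' Returns the three composite groupings of edited indices used for
#' Braak-stage summary values: I/II = indices 1-4; III/IV = 5-30 excluding
#' thalamus (14, 23); V/VI = 31-72 excluding striatum, pallidum and
#' accumbens (35, 36, 41, 45, 51, 52, 57, 61). The excluded structures are
#' the known off-target-binding basal ganglia / thalamus ROIs.
#'
#' @return Named list of integer vectors `braak_12`, `braak_34`,
#'   `braak_56`.
#' @export
braak_composites <- function() {
  list(braak_12 = 1:4,
       braak_34 = setdiff(5:30, c(14L, 23L)),
       braak_56 = setdiff(31:72, c(35L, 36L, 41L, 45L, 51L, 52L, 57L, 61L)))
}

#' Braak composite means
#'
#' Aggregates per-ROI values into the three Braak composites. By default
#' the aggregate is voxel-count-weighted (a composite is treated as the
#' union of its member voxels); an unweighted mean of ROI means is
#' available. Members absent from `roi_means` are skipped with a warning;
#' a composite with no members present is an error.
#'
#' @param roi_means named numeric vector, names = edited indices.
#' @param roi_voxel_counts named integer vector of voxel counts per edited
#'   index (required when `weighted = TRUE`).
#' @param composites list as returned by [braak_composites()].
#' @param weighted voxel-count weighting flag.
#' @return Named numeric vector of length 3.
#' @export
braak_means <- function(roi_means, roi_voxel_counts = NULL,
                        composites = braak_composites(), weighted = TRUE) {
  if (weighted && is.null(roi_voxel_counts))
    stop("roi_voxel_counts is required for the voxel-weighted composite mean")
  have <- as.integer(names(roi_means))
  vapply(composites, function(members) {
    present <- intersect(members, have)
    if (length(present) == 0L)
      stop("no member ROIs present for a Braak composite")
    if (length(present) < length(members))
      warning("Braak composite missing ", length(members) - length(present),
              " member ROI(s); skipped")
    v <- roi_means[as.character(present)]
    if (weighted) {
      w <- roi_voxel_counts[as.character(present)]
      sum(v * w) / sum(w)
    } else mean(v)
  }, numeric(1))
}
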