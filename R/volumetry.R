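#' Dice Similarity Coefficient between two binary masks
#'
#' `DSC = 2 V(M ∩ S) / (V(M) + V(S))`, with volumes measured in mm^3 (voxel
#' count times physical voxel size; with identical grids this reduces to voxel
#' counts). Two empty masks agree perfectly (DSC 1); an empty versus a
#' non-empty mask gives 0.
#'
#' @param m,s [segmentation_mask()] objects on the same grid.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(m, s) {
  stopifnot(inherits(m, "segmentation_mask"), inherits(s, "segmentation_mask"))
  if (!identical(dim(m$grid), dim(s$grid)) ||
      any(abs(m$spacing - s$spacing) > 1e-9)) {
    stop("geometry error: masks differ in grid shape or spacing",
         call. = FALSE)
  }
  denom <- m$volume_mm3 + s$volume_mm3
  if (denom == 0) return(1)
  vox <- prod(m$spacing)
  2 * sum(m$grid & s$grid) * vox / denom
}

#' Volume of a binary mask in mm^3
#'
#' Counts the voxels and multiplies by the physical voxel size.
#'
#' @param mask A [segmentation_mask()].
#' @return Volume in mm^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  mask$voxel_count * prod(mask$spacing)
}

#' Per-case evaluation record
#'
#' One row of the per-case report: manual and automatic volumes (mm^3), voxel
#' counts and the Dice Similarity Coefficient in percent.
#'
#' @param case Case identifier.
#' @param manual,auto [segmentation_mask()] objects on the same grid.
#' @return A one-row `data.frame` with columns `case`, `volume_manual_mm3`,
#'   `volume_auto_mm3`, `voxels_manual`, `voxels_auto`, `dsc_percent`.
#' @export
evaluation_record <- function(case, manual, auto) {
  data.frame(
    case = case,
    volume_manual_mm3 = mask_volume(manual),
    volume_auto_mm3 = mask_volume(auto),
    voxels_manual = manual$voxel_count,
    voxels_auto = auto$voxel_count,
    dsc_percent = 100 * dice(manual, auto),
    stringsAsFactors = FALSE)
}

#' Summarize evaluation records
#'
#' Min, max, mean and standard deviation (sample formula, `n - 1`) of the
#' volume and DSC columns, mirroring the usual per-cohort summary table. With
#' a single record the standard deviation is reported as 0 and flagged.
#'
#' @param records A `data.frame` of [evaluation_record()] rows (or a list of
#'   them).
#' @return A `data.frame` with rows `min`, `max`, `mean`, `sd`, plus an
#'   attribute `sd_defined` (`FALSE` when only one record was supplied).
#' @export
summarize_evaluations <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, records)
  }
  if (!is.data.frame(records) || nrow(records) < 1L) {
    stop("empty input: at least one evaluation record is required",
         call. = FALSE)
  }
  cols <- c("volume_manual_mm3", "volume_auto_mm3",
            "voxels_manual", "voxels_auto", "dsc_percent")
  n <- nrow(records)
  stat <- function(f) vapply(cols, function(cl) f(records[[cl]]), numeric(1))
  sds <- if (n == 1L) stat(function(v) 0) else stat(sd)
  out <- rbind(min = stat(min), max = stat(max), mean = stat(mean), sd = sds)
  out <- as.data.frame(out)
  attr(out, "sd_defined") <- n > 1L
  out
}

#' Write a per-case evaluation report
#'
#' CSV mirrors the per-case table layout (volume mm^3 / voxel count / DSC %);
#' JSON holds the same records plus the summary.
#'
#' @param records Evaluation records (`data.frame`).
#' @param csv,json Output paths; `NULL` to skip either.
#' @return The records, invisibly.
#' @export
write_evaluation_report <- function(records, csv = NULL, json = NULL) {
  if (!is.null(csv)) {
    write.csv(records, csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(records = records, summary = summarize_evaluations(records)),
      json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(records)
}
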